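[
  {
    "canonical_start": 200,
    "input_start": 200,
    "mh_len": 3,
    "mh_dist": 0,
    "config": "OUTER_RIGHT",
    "cut_pos": 203,
    "strand": "+",
    "expect_valid_guide": true,
    "expect_unique": true,
    "expect_nested": false
  },
  {
    "canonical_start": 600,
    "input_start": 600,
    "mh_len": 4,
    "mh_dist": 0,
    "config": "OUTER_RIGHT",
    "cut_pos": 604,
    "strand": "+",
    "expect_valid_guide": true,
    "expect_unique": true,
    "expect_nested": false
  },
  {
    "canonical_start": 1000,
    "input_start": 1000,
    "mh_len": 4,
    "mh_dist": 2,
    "config": "OUTER_RIGHT",
    "cut_pos": 1006,
    "strand": "+",
    "expect_valid_guide": true,
    "expect_unique": true,
    "expect_nested": false
  },
  {
    "canonical_start": 1400,
    "input_start": 1405,
    "mh_len": 5,
    "mh_dist": 1,
    "config": "OUTER_LEFT",
    "cut_pos": 1403,
    "strand": "-",
    "expect_valid_guide": true,
    "expect_unique": true,
    "expect_nested": false
  },
  {
    "canonical_start": 1800,
    "input_start": 1800,
    "mh_len": 3,
    "mh_dist": 7,
    "config": "OUTER_RIGHT",
    "cut_pos": 1810,
    "strand": "+",
    "expect_valid_guide": true,
    "expect_unique": true,
    "expect_nested": false
  },
  {
    "canonical_start": 2200,
    "input_start": 2200,
    "mh_len": 6,
    "mh_dist": 12,
    "config": "OUTER_RIGHT",
    "cut_pos": 2211,
    "strand": "+",
    "expect_valid_guide": true,
    "expect_unique": true,
    "expect_nested": true
  },
  {
    "canonical_start": 2600,
    "input_start": 2600,
    "mh_len": 4,
    "mh_dist": 3,
    "config": "OUTER_RIGHT",
    "cut_pos": 2607,
    "strand": "+",
    "expect_valid_guide": true,
    "expect_unique": false,
    "expect_nested": false
  },
  {
    "canonical_start": 3000,
    "input_start": 3000,
    "mh_len": 2,
    "mh_dist": 2,
    "config": "OUTER_RIGHT",
    "cut_pos": "NA",
    "strand": null,
    "expect_valid_guide": false,
    "expect_unique": false,
    "expect_nested": false
  },
  {
    "canonical_start": 3400,
    "input_start": 3400,
    "mh_len": 5,
    "mh_dist": 0,
    "config": "OUTER_RIGHT",
    "cut_pos": 3403,
    "strand": "-",
    "expect_valid_guide": true,
    "expect_unique": true,
    "expect_nested": false
  },
  {
    "canonical_start": 3800,
    "input_start": 3803,
    "mh_len": 3,
    "mh_dist": 1,
    "config": "OUTER_LEFT",
    "cut_pos": 3804,
    "strand": "+",
    "expect_valid_guide": true,
    "expect_unique": true,
    "expect_nested": false
  }
]
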