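Package: delmh
Title: Microhomology Detection and CRISPR Guide Design for Deletion Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects microhomologies (short identical sequences) flanking
    deletion variants against a reference genome, canonicalizes equivalent
    deletion representations by coordinate shifting, designs CRISPR-Cas9
    guides whose blunt cut falls between the two microhomology copies so
    that microhomology-mediated end joining (MMEJ) can recreate the exact
    annotated deletion, tests guide uniqueness by exact genome-wide
    matching, detects and scores competing microhomologies nested inside
    the deletion, and emits filterable variant-level and guide-level
    reports. Includes a synthetic genome and variant generator with
    planted ground truth and Monte Carlo estimation of background
    microhomology frequencies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
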