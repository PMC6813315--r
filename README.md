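# delmh — microhomology detection and CRISPR guide design for deletion variants

Deletions flanked by a microhomology (µH) — a short identical sequence
with one copy just inside the deleted segment and one in the retained
flank — can be recreated precisely, without a repair template, by placing
a CRISPR-Cas9 double-strand break between the two copies and letting
microhomology-mediated end joining (MMEJ) anneal them. `delmh` finds such
deletions and designs the guides: it is aimed at genome engineers who
want to install naturally occurring deletion alleles (e.g. pathogenic
ClinVar deletions) in cell lines, and at anyone surveying how often
annotated deletions are µH-flanked.

For a deletion of length *n* at position *s* (0-based, half-open), both
flanking configurations are tested — the deletion's 5′ end against the 3′
flank, and its 3′ end against the 5′ flank — extending base by base with
at most one mismatch (configurable), keeping the full µH length `mhL`,
the first exact stretch `mh1L`, and the score

    score = matches + mh1L,

with the stronger configuration selected and the heterology distance
`dist = n − mhL`. Equivalent coordinate representations (deletions in
repeats can be shifted) are canonicalized to the representation with the
longest µH, ties to the leftmost. SpCas9 guides (PAM `NGG`, blunt cut
3 bp upstream of the PAM; xCas9's `NG`/`GAA`/`GAT` supported) are kept
when the cut falls inside the deletion, spares the junction-proximal
3 bp of the inner µH copy, and lies within 50 bp of the nearer µH copy.
Each guide's protospacer+PAM word is tested for exact (0-mismatch)
genome-wide uniqueness over both strands, and the deletion's interior is
searched for nested µHs — competing exact repeat pairs straddling the cut
with a smaller gap than the target — scored with the classic pattern
score `100·exp(−del/20)·(2·nGC + nAT)`. Reports come out as two TSVs
(variant level and guide level) plus a JSON run summary, with a filter
cascade (deletion ≥ 3 bp, µH ≥ 3 bp, unique guide, no nested µH, genic
context, clinical category) and its survivor funnel.

A synthetic-data module (`make_genome`, `plant_spec`, `plant_variant`,
`plant_cohort`) writes loci with machine-checkable planted ground truth,
and `background_fraction` reproduces the analytic background µH
frequencies (0.25^k for length-k deletions: 25%, 6.25%, 1.56%) by Monte
Carlo; `pam_availability` gives the 12.5% `GG` availability for
abutted-µH deletions.

## Worked example

Using the bundled synthetic fixture set (a 4.4 kb genome with ten planted
deletions, a VCF with ClinVar-style `CLNSIG` labels, and a small gene
model):

```r
library(delmh)
genome <- load_fasta(system.file("extdata", "synthetic-genome.fa", package = "delmh"))
dels   <- parse_deletions_vcf(system.file("extdata", "synthetic-deletions.vcf",
                                          package = "delmh"), genome, source = "demo")
ann    <- load_annotation(system.file("extdata", "synthetic-genes.gff3",
                                      package = "delmh"))
res <- delmh_run(genome, dels, ann)
res
#> delmh_result: 10 variant(s), 12 valid guide(s)
#> filter funnel:
#>   input                        10
#>   del_len >= 3                 10
#>   mhL >= 3                     9
#>   unique guide available       9
#>   unique guide without nested MH 8
```

Ten deletions enter; one is dropped for having a µH shorter than 3 bp,
none lack a unique guide, and one more falls because its only guides
face a nested µH. The variant table carries the µH metrics and context:

```r
res$variants[1:2, c("id", "start", "del_len", "mhL", "dist", "flank_config",
                    "gene_context", "clin_category", "n_unique_guides")]
#>                 id start del_len mhL dist flank_config gene_context clin_category n_unique_guides
#> 1 planted_chr1_200   200       3   3    0  OUTER_RIGHT       exonic    pathogenic               2
#> 2 planted_chr1_600   600       4   4    0  OUTER_RIGHT       exonic          none               1
```

The first variant is a 3-bp exonic deletion with an abutted (`dist = 0`)
3-bp µH, classified pathogenic from its label, with two unique guides.
Its best guide:

```r
res$guides[res$guides$variant_id == "planted_chr1_200", ][1, ]
#>                guide_id strand          protospacer pam cut_pos dist_left dist_right is_unique nested_count
#>  planted_chr1_200_c203-      - TTTAGAGGGTTCCTCTACTA GGG     203         0          0      TRUE            0
```

— a minus-strand guide cutting at inter-base position 203, adjacent to
both µH copies (`dist 0/0`), genome-wide unique, with no competing
nested µH. `write_reports(res, "out/mmej")` writes
`out/mmej-variants.tsv`, `out/mmej-guides.tsv` and
`out/mmej-summary.json`, byte-identical across reruns.

A thin command-line wrapper covers the same pipeline plus fixture
generation and the background simulation:

```sh
Rscript inst/cli/delmh.R run --ref ref.fa --variants dels.vcf \
    --annotation genes.gff3 --pam NGG --out results/run1
Rscript inst/cli/delmh.R simulate --n 20 --out sim --seed 1
Rscript inst/cli/delmh.R background --del-len 3 --min-mh 3 --seed 1
```

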