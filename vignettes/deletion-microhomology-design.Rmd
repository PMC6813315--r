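---
title: "Microhomology-aware deletion analysis and CRISPR guide design with delmh"
author: "delmh authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microhomology-aware deletion analysis and CRISPR guide design with delmh}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delmh)
```

## The problem

When a double-strand break (DSB) is repaired by microhomology-mediated end
joining (MMEJ), the cell resects the broken ends, anneals a pair of short
identical sequences (microhomologies, µH) that flank the break, and removes
the intervening DNA. The outcome is a deletion of predictable size and
sequence: everything between the two µH copies plus one of the copies is
lost. Reading this process backwards, a deletion variant that is *flanked*
by a µH — one copy just inside the deleted segment, an identical copy in
the retained flank — is a candidate for precise re-creation with a single
CRISPR-Cas9 cut and no repair template: cut between the copies, let MMEJ
anneal them, and the annotated allele appears.

`delmh` implements this reverse reading end to end: it detects and scores
flanking µHs for deletion variants against a reference genome,
canonicalizes equivalent coordinate representations, enumerates Cas9
guides whose blunt cut falls between the µH copies under positional
constraints, tests each guide for exact genome-wide uniqueness, detects
competing µHs nested inside the deletion, annotates genic context and
clinical labels, and emits filterable variant-level and guide-level
tables. A synthetic-data module generates genomes with planted ground
truth so that every step is testable without external downloads.

## Microhomology detection and scoring

For a deletion of length $n$ at 0-based position $s$ (interval
$[s, s+n)$), two flanking configurations are tested:

* **OUTER_RIGHT** — the 5′ end of the deleted sequence aligned with the
  right (3′) flank, both read left to right from the junction;
* **OUTER_LEFT** — the 3′ end of the deleted sequence aligned with the
  left (5′) flank, both read right to left.

The alignment is extended base by base. Up to `max_mismatch` (default 1)
mismatches are absorbed, each requiring at least
`anchor_before_mismatch` consecutive matches immediately before it and at
least one match after it; a trailing mismatch is always trimmed, so a
non-empty µH ends in a match. Two lengths are kept: the full µH length
`mhL` and the first exact stretch `mh1L`. The configuration score is

$$\mathrm{score} = \mathrm{matches} + \mathrm{mh1L},$$

which rewards long perfect stretches twice and is the quantity used to
select between the two configurations (ties go to the longer `mh1L`, then
deterministically to OUTER_LEFT). Reported metrics per variant are `mhL`,
`mh1L`, match/mismatch counts, homology fraction, GC content of the
retained flank copy, and the heterology distance $\mathrm{dist} = n -
\mathrm{mhL}$ (0 means the copies are directly abutted). `dist_exact`
$= n - \mathrm{mh1L}$ is emitted alongside, since a mismatch-free MMEJ
junction can only use the exact stretch.

The full µH length is capped at $n$ so the two copies never overlap; an
overlapping pair would not describe a realizable MMEJ junction.
`anchor_before_mismatch = 1` is the default; a strict mode
(`anchor_before_mismatch = 3`) only absorbs a mismatch after a perfect
stretch of at least 3 bp. `N` never matches anything, and variants whose
deleted sequence contains `N` are excluded at parse time.

## Canonicalization, and why exact µHs always read as OUTER_RIGHT

A deletion inside repeated sequence has several equivalent coordinate
representations: shifting the interval left is possible while the base
before it equals the last deleted base, and right while the first deleted
base equals the base after it. All reachable representations are scored
and the highest-scoring one wins, ties going to the leftmost start.

One consequence deserves emphasis because it shapes both the output and
the test design: a deletion with an **exact** flanking µH of length $m$
always has exactly $m$ extra representations reachable by shifting through
the µH copy itself. At the leftmost of these the inner copy sits at the
deletion's 5′ end and the configuration reads OUTER_RIGHT; at the
rightmost it reads OUTER_LEFT. Both describe the same physical allele. The
leftmost tie-break therefore means every exact µH is *reported* in the
OUTER_RIGHT configuration at the leftmost start. The OUTER_LEFT label
appears in canonical output only when a mismatch inside the µH blocks the
shift (mismatched µHs are not freely shiftable), or in the optional
both-configuration report. The synthetic generator mirrors this: planting
"OUTER_LEFT" hands the variant to the caller at the rightmost equivalent
representation — where local analysis genuinely reads OUTER_LEFT — and the
recovery tests assert that canonicalization shifts it back by exactly
$-m$.

## Guide enumeration

PAM motifs (IUPAC, default `NGG`; `NG`/`GAA`/`GAT` reproduce the relaxed
xCas9 set) are scanned on both strands around the deletion, and every
motif is modeled as a blunt cut 3 bp upstream of the PAM — between the
17th and 18th protospacer bases for the default 20-nt protospacer. Cut
coordinates are inter-base: cut $c$ falls between genomic bases $c-1$ and
$c$. A candidate's cut must fall within the deletion interval ($[s, s+n]$
inclusive of both junctions). It is *valid* when additionally:

1. it spares the junction-proximal $\min(3, \mathrm{mhL})$ bp of the inner
   µH copy, so at least 3 bp of µH survives on either side of the break
   (for OUTER_RIGHT: $c \in [s+3, s+n]$; mirrored for OUTER_LEFT);
2. the number of intervening bases between the cut and the *nearer* µH
   copy is at most `max_cut_dist` (default 50). Measuring to the nearer
   copy — rather than both — deliberately keeps single cuts near either
   end of a large deletion, which is what a two-cut design for large
   deletions needs; `require_both_within = TRUE` switches to the stricter
   reading. Distance 0 means the cut is inside or adjacent to the copy.
3. the protospacer lies on the contig and contains no `N`.

A cut exactly at the distal junction ($c = s+n$ for OUTER_RIGHT) is
allowed: it sits between the two copies and retains both fully. For an
abutted 3-bp µH on a 3-bp deletion this is the *only* valid cut, and it
requires a `GG` dinucleotide at fixed offsets next to the deletion — the
geometry behind the 12.5% PAM-availability figure below.

## Off-target uniqueness

Each valid guide's protospacer+PAM word is counted genome-wide at 0
mismatches over both strands, using an exact $L$-mer index built once per
run ($L$ = protospacer length + motif length; plus-strand words are
indexed, and a word's two-strand count is `plus(w) + plus(revcomp(w))`,
so palindromic words count once per strand occurrence; words containing
`N` are never indexed). With `expand_pam = TRUE` (default) the count sums
over every concrete instantiation of the ambiguous motif positions —
biologically, any `NGG` licenses cleavage — while `expand_pam = FALSE`
counts only the literal observed word. A guide is unique when its total
count is exactly 1 (its own site). Mismatch-tolerant off-target scoring
is out of scope by design; users wanting CFD-style scores should export
the guide table to a dedicated tool.

## Nested microhomologies

At each valid cut the heterology region between the proximal edges of the
two target µH copies is searched for *maximal* exact repeat pairs of at
least `nested_min_len` (default 3) bp with one copy ending at or before
the cut, the other starting at or after it, and an inter-copy gap
strictly smaller than the target µH distance. Such a pair is a competing
MMEJ outcome: with a shorter gap it is expected to be used preferentially
and would produce a different deletion. Restricting the enumeration to
maximal pairs (not extendable on either end within the region) avoids
counting every sub-repeat of a longer repeat. Each pair is scored with
the classic deletion-pattern score

$$100 \times e^{-\mathrm{del}/20} \times (2\,n_{GC} + n_{AT}),$$

where del is the deletion the pair would realize (gap + length) and
$n_{GC}$/$n_{AT}$ count its G/C and A/T bases; the per-guide "strength"
is the maximum pattern score (the strongest competitor), with the sum
emitted as an auxiliary column since the aggregation choice is a design
decision, not a derived fact. An abutted target µH (distance 0) can have
no nested pairs — there is no room for a smaller gap — so filtering on
"no nested µH" never removes abutted-µH variants.

## Annotation, classification, filters

Genic context uses any-overlap with precedence coding exon (CDS) → UTR →
non-coding exon (reported as exonic) → gene body (intronic) → intergenic.
A deletion is frameshifting when it is exonic and its length is not a
multiple of 3. Clinical-significance labels are classified by a
case-insensitive word-boundary match: any label containing the word
"pathogenic" makes the variant pathogenic ("Likely pathogenic" counts;
"Conflicting interpretations of pathogenicity" does not, because
"pathogenicity" is a different token — a deliberate tightening of the
looser substring reading, which remains available as
`clinsig_substring = TRUE`); "benign" labels are classed benign, empty
label sets `none`, everything else `VUS/other`.

`apply_filters()` applies the conjunctive cascade — minimum deletion
length (default 3), minimum µH length (default 3), maximum distance,
unique guide available, unique guide without nested µH, genic context,
clinical category — and records the survivor count after each step, so
the variant-level counts are non-increasing along the cascade by
construction.

## The synthetic-data generator

`make_genome()` draws i.i.d. bases at a chosen GC content (default 0.5,
uniform — matching the closed-form expectations below). `plant_spec()` /
`plant_variant()` write a locus with exact planted structure — µH length
and distance, reporting representation, an NGG guide with a valid cut, a
nested 3-bp repeat straddling that cut, off-target duplicates of the
guide word — and then *verify by re-analysis*, resampling the random
parts until the analysis recovers exactly the planted values. This
rejection step is what makes the ground truth machine-checkable: without
it, random flanks occasionally extend a µH past its planted length or
create an accidental second repeat.

Planted guide geometry: for µH copies of ≤ 4 bp the PAM is planted on the
plus strand with the cut at the distal junction (the `GG` lands just past
the flank copy); for longer copies it is planted on the minus strand with
the cut 3 bp inside the proximal copy; when a nested repeat is requested
(distance ≥ 10) the cut and PAM move into the heterology. These are the
three feasible placements that never overwrite planted structure.

What the generator deliberately does **not** emulate: human base
composition and repeat structure (loci are i.i.d. uniform), sequencing
error, and clustered variants. Passing the recovery tests therefore shows
the *algorithms* are correct on well-posed loci; it says nothing about,
for example, µH frequencies in real genomes, which are strongly enriched
over the random expectation precisely because real genomes are not
i.i.d.

`background_fraction()` estimates the probability that a random deletion
locus carries a µH by chance. In `single_config_exact` mode (one
configuration, exact matching) the closed form for a length-$k$ deletion
with a $\geq k$ bp µH is $0.25^k$ — 25%, 6.25%, 1.56% for $k = 1, 2, 3$
— and the Monte Carlo estimate at $2 \times 10^5$ loci lands within three
binomial standard errors of it. The per-alignment probability is the
quantity with a clean closed form, which is why the single-configuration
mode exists; testing both configurations, or allowing a mismatch, raises
the empirical rate and is reported separately. `pam_availability()`
returns the abutted-µH `GG` availability: $(1/4)^2$ per side, $2 \times
(1/4)^2 = 12.5\%$ as the additive two-side approximation, and the
inclusion–exclusion value $1-(15/16)^2 \approx 12.1\%$ as a labeled
alternative.

## Numerical and design choices

* **Coordinates** are 0-based half-open everywhere internally; VCF and
  GFF3 conversion happens only at the format boundary. Cut positions are
  inter-base.
* **VCF normalization** trims the shared prefix (anchor) first, then any
  shared suffix; a record is a pure deletion iff the ALT is fully
  absorbed. Multi-allelic records are decomposed and non-deletion ALTs
  skipped with counted reasons; REF/genome mismatches are rejected, not
  repaired.
* **Deduplication** keys on (contig, canonical start, deletion length),
  so equivalent representations of one allele collapse; the record with
  the richest clinical annotation wins and sources merge to `"merged"`.
* **Tie-breaks** (configuration selection, canonical shift) are fixed and
  documented above, making all outputs byte-reproducible; report rows are
  sorted (variants by contig/start/id, guides by variant/cut/strand).
* **Deletions longer than `max_del_len`** (default 10,000 bp) keep their
  µH metrics but skip guide search.
* **Problem sizes** used in the shipped checks: oracle-equivalence fuzzing
  at 1,000 instances per operation on sequences ≤ 80 bp; parameter
  recovery on 500 planted loci in one ~220 kb genome; background
  frequencies at $2\times10^5$ loci. These sizes give sub-percent Monte
  Carlo error and exhaust the combinatorics of the small operations.

## A short tour

```{r tour, eval = FALSE}
library(delmh)
genome <- load_fasta(system.file("extdata", "synthetic-genome.fa",
                                 package = "delmh"))
dels <- parse_deletions_vcf(system.file("extdata", "synthetic-deletions.vcf",
                                        package = "delmh"), genome)
ann <- load_annotation(system.file("extdata", "synthetic-genes.gff3",
                                   package = "delmh"))
res <- delmh_run(genome, dels, ann)
res$variants          # one row per deletion: microhomology metrics, counts
res$guides            # one row per valid guide: cut, distances, uniqueness
apply_filters(res$variants,
              list(min_mh_len = 3, require_unique_guide = TRUE,
                   clin_category = "pathogenic"))
write_reports(res, "mmej-candidates")
```

## Known limitations

* Only blunt +3 cuts are modeled; Cas12a-style staggered cuts and paired
  nickases are not.
* Guide efficiency is not predicted; the tool ranks by design constraints
  and uniqueness only, and repair-outcome prevalence columns are accepted
  as pass-through input rather than computed.
* Two-cut designs for large deletions are supported only to the extent
  that single cuts near each µH copy are emitted; pairing them is left to
  the user.
* The exact off-target test is 0-mismatch by construction; near-matches
  that differ by one base are invisible to it.
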