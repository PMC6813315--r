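#' Extend a microhomology from the deletion junction outward
#'
#' Walks position by position comparing the deleted sequence (`inner_seq`)
#' with the flanking sequence (`flank_seq`); both strings are read
#' junction-outward, i.e. position 1 is adjacent to the junction in both.
#' Up to `max_mismatch` mismatches are absorbed, each only if at least
#' `anchor_before_mismatch` consecutive matches immediately precede it and at
#' least one match follows; a trailing mismatch is always trimmed, so the
#' last aligned base of a non-empty microhomology is a match. The full
#' microhomology length is capped at `nchar(inner_seq)` so the two copies can
#' never overlap. `N` never matches anything.
#'
#' The score is the sum of matching bases in the full microhomology and the
#' length of the first exact stretch, so a perfect run is rewarded twice.
#'
#' @param inner_seq Deleted-side copy, junction-outward.
#' @param flank_seq Flanking-side copy, junction-outward (may be shorter or
#'   longer than `inner_seq`; only `min(nchar(inner_seq), nchar(flank_seq))`
#'   positions are considered).
#' @param max_mismatch Maximum mismatches absorbed (default 1).
#' @param anchor_before_mismatch Consecutive matches required immediately
#'   before an absorbed mismatch (default 1).
#' @return List with `mhL` (full length), `mh1L` (first exact stretch),
#'   `matches`, `mismatches`, and `score = matches + mh1L`.
#' @export
#' @examples
#' extend_microhomology("TAGCA", "TAGTACC")  # mhL 5, mh1L 3, score 7
extend_microhomology <- function(inner_seq, flank_seq,
                                 max_mismatch = 1L,
                                 anchor_before_mismatch = 1L) {
  n <- nchar(inner_seq)
  lim <- min(n, nchar(flank_seq))
  zero <- list(mhL = 0L, mh1L = 0L, matches = 0L, mismatches = 0L, score = 0L)
  if (lim == 0L) return(zero)
  a <- strsplit(inner_seq, "", fixed = TRUE)[[1L]]
  b <- strsplit(flank_seq, "", fixed = TRUE)[[1L]]
  ai <- a[seq_len(lim)]
  bi <- b[seq_len(lim)]
  eq <- ai == bi & ai != "N" & bi != "N"
  first_mm <- which(!eq)[1L]
  mh1L <- if (is.na(first_mm)) lim else first_mm - 1L
  # greedy walk: `end` tracks the last kept (matching) position
  i <- 1L; used <- 0L; run <- 0L; end <- 0L
  while (i <= lim) {
    if (eq[i]) {
      run <- run + 1L; end <- i; i <- i + 1L
    } else if (used < max_mismatch && run >= anchor_before_mismatch &&
               i < lim && eq[i + 1L]) {
      used <- used + 1L; run <- 0L; i <- i + 1L
    } else break
  }
  mhL <- end
  if (mhL == 0L) return(zero)
  mm <- sum(!eq[seq_len(mhL)])
  matches <- mhL - mm
  list(mhL = mhL, mh1L = min(mh1L, mhL), matches = matches,
       mismatches = mm, score = matches + min(mh1L, mhL))
}

gc_fraction <- function(s) {
  if (nchar(s) == 0L) return(0)
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  sum(ch %in% c("G", "C")) / length(ch)
}

# Assemble the full per-configuration result from a raw extension.
mh_result <- function(config, ext, variant, genome) {
  s <- variant$start; n <- nchar(variant$deleted_seq)
  chrom <- variant$chrom
  mhL <- ext$mhL
  if (config == "OUTER_RIGHT") {
    inner_span <- c(s, s + mhL)           # 5' end of deletion
    outer_span <- c(s + n, s + n + mhL)   # start of right flank
  } else {
    inner_span <- c(s + n - mhL, s + n)   # 3' end of deletion
    outer_span <- c(s - mhL, s)           # end of left flank
  }
  mh_seq <- if (mhL > 0L) genome_fetch(genome, chrom, outer_span[1L], outer_span[2L]) else ""
  # left/right = genomic order of the two copies
  if (outer_span[1L] <= inner_span[1L]) {
    left_span <- outer_span; right_span <- inner_span
  } else {
    left_span <- inner_span; right_span <- outer_span
  }
  list(config = config,
       mhL = mhL, mh1L = ext$mh1L, matches = ext$matches,
       mismatches = ext$mismatches, score = ext$score,
       hom = if (mhL > 0L) ext$matches / mhL else 0,
       gc = gc_fraction(mh_seq),
       dist = n - mhL,
       dist_exact = n - ext$mh1L,
       mh_seq = mh_seq,
       inner_span = inner_span, outer_span = outer_span,
       left_span = left_span, right_span = right_span)
}

#' Detect flanking microhomology in both configurations
#'
#' Tests the two flanking configurations of a deletion: `OUTER_RIGHT` aligns
#' the 3' flanking region with the 5' end of the deleted sequence (both read
#' left to right from the junction at the deletion end), and `OUTER_LEFT`
#' aligns the 5' flanking region with the 3' end of the deleted sequence
#' (both read right to left from the junction at the deletion start). Flank
#' sequence is truncated at contig edges.
#'
#' @param genome A `delmh_genome`.
#' @param variant A deletion variant (list/row with `chrom`, `start`,
#'   `deleted_seq`).
#' @param params A [delmh_params()] list.
#' @return List with elements `OUTER_LEFT` and `OUTER_RIGHT`, each a full
#'   microhomology result (see [extend_microhomology()] plus genomic copy
#'   spans, GC of the retained flank copy, and `dist = n - mhL`).
#' @export
find_flanking_mh <- function(genome, variant, params = delmh_params()) {
  s <- variant$start
  del <- variant$deleted_seq
  n <- nchar(del)
  chrom <- variant$chrom
  right_flank <- genome_fetch_clip(genome, chrom, s + n, s + 2L * n)
  left_flank <- genome_fetch_clip(genome, chrom, s - n, s)
  er <- extend_microhomology(del, right_flank,
                             params$max_mismatch, params$anchor_before_mismatch)
  el <- extend_microhomology(rev_str(del), rev_str(left_flank),
                             params$max_mismatch, params$anchor_before_mismatch)
  list(OUTER_LEFT = mh_result("OUTER_LEFT", el, variant, genome),
       OUTER_RIGHT = mh_result("OUTER_RIGHT", er, variant, genome))
}

#' Select the stronger flanking configuration
#'
#' Higher score wins; ties are broken by the longer first exact stretch,
#' then deterministically in favor of `OUTER_LEFT`. A result with `mhL == 0`
#' on both sides is returned (from `OUTER_LEFT`) with `no_mh = TRUE`.
#'
#' @param left_result,right_result Results from [find_flanking_mh()].
#' @return The selected configuration's result, with a `no_mh` flag added.
#' @export
select_configuration <- function(left_result, right_result) {
  pick <- if (right_result$score > left_result$score) right_result
          else if (right_result$score < left_result$score) left_result
          else if (right_result$mh1L > left_result$mh1L) right_result
          else left_result
  pick$no_mh <- pick$mhL == 0L
  pick
}

#' Canonicalize a deletion by coordinate shifting
#'
#' The same deletion can be represented at different coordinates when it
#' abuts repeated sequence: shifting left is possible while the base before
#' the deletion equals the last deleted base, and shifting right while the
#' first deleted base equals the base after the deletion (every reachable
#' representation removes the same sequence from the chromosome). All
#' reachable representations are enumerated and scored with
#' [find_flanking_mh()] + [select_configuration()]; the representation with
#' the highest selected score wins, ties going to the leftmost start.
#'
#' @param genome A `delmh_genome`.
#' @param variant Deletion variant (list/row with `chrom`, `start`,
#'   `deleted_seq`, and optionally `id`, `source`, `clin_sig`).
#' @param params A [delmh_params()] list.
#' @return List with `variant` (at canonical coordinates), `shift_offset`
#'   (canonical start minus input start), `mh` (selected microhomology
#'   result), and `both` (both configurations at the canonical coordinates).
#' @export
canonicalize_deletion <- function(genome, variant, params = delmh_params()) {
  reps <- enumerate_shifts(genome, variant)
  best <- NULL
  for (r in reps) {  # reps are ordered by start, so ties keep the leftmost
    v <- variant
    v$start <- r$start
    v$deleted_seq <- r$deleted_seq
    both <- find_flanking_mh(genome, v, params)
    sel <- select_configuration(both$OUTER_LEFT, both$OUTER_RIGHT)
    if (is.null(best) || sel$score > best$mh$score) {
      best <- list(variant = v, shift_offset = r$start - variant$start,
                   mh = sel, both = both)
    }
  }
  best
}

# All coordinate representations of a deletion reachable by shifting,
# ordered by increasing start.
enumerate_shifts <- function(genome, variant, max_shift = 100000L) {
  chrom <- variant$chrom
  len <- contig_length(genome, chrom)
  s <- variant$start
  del <- variant$deleted_seq
  n <- nchar(del)
  reps <- list(list(start = s, deleted_seq = del))
  # left shifts
  cs <- s; cd <- del; k <- 0L
  while (cs > 0L && k < max_shift) {
    prev <- genome_fetch(genome, chrom, cs - 1L, cs)
    if (prev != substr(cd, n, n) || prev == "N") break
    cd <- paste0(prev, substr(cd, 1L, n - 1L))
    cs <- cs - 1L; k <- k + 1L
    reps <- c(list(list(start = cs, deleted_seq = cd)), reps)
  }
  # right shifts
  cs <- s; cd <- del; k <- 0L
  while (cs + n < len && k < max_shift) {
    nxt <- genome_fetch(genome, chrom, cs + n, cs + n + 1L)
    if (nxt != substr(cd, 1L, 1L) || nxt == "N") break
    cd <- paste0(substr(cd, 2L, n), nxt)
    cs <- cs + 1L; k <- k + 1L
    reps <- c(reps, list(list(start = cs, deleted_seq = cd)))
  }
  reps
}
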