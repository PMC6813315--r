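# Independent brute-force oracles. These deliberately avoid the package's
# incremental algorithms: each one enumerates or scans exhaustively.

BASES <- c("A", "C", "G", "T")

random_seq <- function(n, alphabet = BASES) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Microhomology extension by exhaustive search over all prefix lengths:
# the longest prefix ending in a match whose mismatches are all absorbable
# (>= anchor consecutive matches immediately before, a match immediately
# after, at most max_mismatch in total).
oracle_extend <- function(inner, flank, max_mismatch = 1L, anchor = 1L) {
  n <- nchar(inner)
  lim <- min(n, nchar(flank))
  zero <- list(mhL = 0L, mh1L = 0L, matches = 0L, mismatches = 0L, score = 0L)
  if (lim == 0L) return(zero)
  a <- strsplit(inner, "", fixed = TRUE)[[1L]][seq_len(lim)]
  b <- strsplit(flank, "", fixed = TRUE)[[1L]][seq_len(lim)]
  eq <- a == b & a != "N" & b != "N"
  best <- 0L
  for (l in seq_len(lim)) {
    if (!eq[l]) next
    mmpos <- which(!eq[seq_len(l)])
    if (length(mmpos) > max_mismatch) next
    ok <- TRUE
    for (p in mmpos) {
      run <- 0L
      q <- p - 1L
      while (q >= 1L && eq[q]) { run <- run + 1L; q <- q - 1L }
      if (run < anchor || p + 1L > l || !eq[p + 1L]) { ok <- FALSE; break }
    }
    if (ok) best <- l
  }
  if (best == 0L) return(zero)
  mm <- sum(!eq[seq_len(best)])
  first <- which(!eq)
  mh1 <- min(if (length(first)) first[1L] - 1L else lim, best)
  list(mhL = best, mh1L = mh1, matches = best - mm, mismatches = mm,
       score = best - mm + mh1)
}

iupac_table <- list(A = "A", C = "C", G = "G", T = "T",
                    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                    W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                    B = c("C", "G", "T"), D = c("A", "G", "T"),
                    H = c("A", "C", "T"), V = c("A", "C", "G"),
                    N = c("A", "C", "G", "T"))

# Position-by-position IUPAC scan (plus strand of `win` only).
oracle_motif_starts <- function(win, motif) {
  wc <- strsplit(win, "", fixed = TRUE)[[1L]]
  mc <- strsplit(motif, "", fixed = TRUE)[[1L]]
  L <- length(wc); k <- length(mc)
  hits <- integer(0)
  if (L < k) return(hits)
  for (i in 0:(L - k)) {
    ok <- TRUE
    for (j in seq_len(k)) {
      if (!(wc[i + j] %in% iupac_table[[mc[j]]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, i)
  }
  hits
}

# Exact occurrences of `word` in one string (overlapping allowed).
oracle_count_in <- function(s, word) {
  n <- nchar(s); L <- nchar(word)
  if (n < L) return(0L)
  sum(substring(s, seq_len(n - L + 1L), seq_len(n - L + 1L) + L - 1L) == word)
}

# Two-strand exact occurrence count over all contigs.
oracle_word_count <- function(genome, word) {
  sum(vapply(genome$seq, function(sq) {
    oracle_count_in(sq, word) + oracle_count_in(revcomp(sq), word)
  }, integer(1L)))
}

# Nested-microhomology enumeration by triple loop over (i, j, len):
# all maximal exact repeat pairs >= min_len in `region` (1-based indices),
# left copy ending at or before the inter-base cut `cut_rel` (0-based,
# region-relative), right copy starting at or after it, gap < target_dist.
oracle_nested <- function(region, cut_rel, min_len, target_dist) {
  ch <- strsplit(region, "", fixed = TRUE)[[1L]]
  Lr <- length(ch)
  out <- list()
  for (len in min_len:Lr) {
    for (i in seq_len(Lr - len)) {
      for (j in (i + 1L):(Lr - len + 1L)) {
        sub1 <- ch[i:(i + len - 1L)]
        sub2 <- ch[j:(j + len - 1L)]
        if (any(sub1 == "N") || !all(sub1 == sub2)) next
        left_ext <- i > 1L && j > 1L && ch[i - 1L] == ch[j - 1L] &&
          ch[i - 1L] != "N"
        right_ext <- (i + len) <= Lr && (j + len) <= Lr &&
          ch[i + len] == ch[j + len] && ch[i + len] != "N"
        if (left_ext || right_ext) next            # not maximal
        if ((i - 1L) + len > cut_rel) next         # left copy past the cut
        if ((j - 1L) < cut_rel) next               # right copy before it
        gap <- j - i - len
        if (gap >= target_dist) next
        out[[length(out) + 1L]] <-
          data.frame(i0 = i - 1L, j0 = j - 1L, length = len, gap = gap)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(i0 = integer(0), j0 = integer(0),
                      length = integer(0), gap = integer(0)))
  }
  o <- do.call(rbind, out)
  o[order(o$i0, o$j0, o$length), , drop = FALSE]
}

# Per-base overlap check used against classify_context.
oracle_overlaps <- function(v_start, v_end, f_start, f_end) {
  any(seq(v_start, v_end - 1L) %in% seq(f_start, length.out = f_end - f_start))
}
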