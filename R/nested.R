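#' Microhomology pattern score
#'
#' Deletion-pattern score of a microhomology: `100 * exp(-del_len / 20) *
#' (2 * nGC + nAT)`, where `del_len` is the deletion the microhomology would
#' realize (gap + microhomology length) and `nGC`/`nAT` count G/C and A/T
#' bases of the microhomology sequence. Longer resulting deletions decay the
#' score; GC pairs weigh double.
#'
#' @param mh_seq Microhomology sequence.
#' @param resulting_del_len Length of the deletion realized through this
#'   microhomology (bp).
#' @return Numeric score.
#' @export
#' @examples
#' mh_pattern_score("TGA", 5)  # 311.52
mh_pattern_score <- function(mh_seq, resulting_del_len) {
  ch <- strsplit(mh_seq, "", fixed = TRUE)[[1L]]
  ngc <- sum(ch %in% c("G", "C"))
  nat <- sum(ch %in% c("A", "T"))
  100 * exp(-resulting_del_len / 20) * (2 * ngc + nat)
}

#' Find microhomologies nested inside a deletion at a candidate cut
#'
#' Searches the heterology region between the proximal edges of the two
#' target microhomology copies for maximal exact repeat pairs of length at
#' least `min_len`, with one copy ending at or before the cut and the other
#' starting at or after it, and with an inter-copy gap strictly smaller than
#' the target microhomology distance. Such a pair is a competing MMEJ
#' outcome at that cut: repair through it would produce a deletion different
#' from the annotated one. A pair is maximal when it cannot be extended on
#' either end within the search region.
#'
#' @param genome A `delmh_genome`.
#' @param canonical Result of [canonicalize_deletion()].
#' @param cut_pos Inter-base cut coordinate (see [cut_position()]).
#' @param min_len Minimum nested microhomology length (default 3).
#' @return data.frame with one row per nested pair: `left_start`,
#'   `left_end`, `right_start`, `right_end` (genomic, 0-based half-open),
#'   `length`, `gap`, `seq`, `pattern_score`.
#' @export
find_nested <- function(genome, canonical, cut_pos, min_len = 3L) {
  empty <- data.frame(left_start = integer(0), left_end = integer(0),
                      right_start = integer(0), right_end = integer(0),
                      length = integer(0), gap = integer(0),
                      seq = character(0), pattern_score = numeric(0))
  mh <- canonical$mh
  v <- canonical$variant
  target_dist <- mh$dist
  if (target_dist <= 0L) return(empty)
  # heterology region between the proximal edges of the two copies
  a <- mh$left_span[2L]
  b <- mh$right_span[1L]
  if (b - a < 2L * min_len) return(empty)
  region <- genome_fetch(genome, v$chrom, a, b)
  ch <- strsplit(region, "", fixed = TRUE)[[1L]]
  Lr <- length(ch)
  cut_rel <- cut_pos - a
  rows <- list()
  for (i in seq_len(Lr - 1L)) {               # 1-based left copy start
    for (j in (i + 1L):Lr) {                  # 1-based right copy start
      if (ch[i] != ch[j] || ch[i] == "N") next
      # left-maximality: not the interior of a pair starting one base earlier
      if (i > 1L && ch[i - 1L] == ch[j - 1L] && ch[i - 1L] != "N") next
      k <- 1L
      while (j + k <= Lr && ch[i + k] == ch[j + k] && ch[i + k] != "N") k <- k + 1L
      len <- k
      if (len < min_len) next
      # cut must separate the copies: left ends at/before it, right starts at/after
      if ((i - 1L) + len > cut_rel) next
      if ((j - 1L) < cut_rel) next
      gap <- j - i - len
      if (gap >= target_dist) next
      sq <- paste(ch[i:(i + len - 1L)], collapse = "")
      rows[[length(rows) + 1L]] <- data.frame(
        left_start = a + i - 1L, left_end = a + i - 1L + len,
        right_start = a + j - 1L, right_end = a + j - 1L + len,
        length = len, gap = gap, seq = sq,
        pattern_score = mh_pattern_score(sq, gap + len))
    }
  }
  if (length(rows) == 0L) return(empty)
  do.call(rbind, rows)
}

#' Summarize nested microhomologies for one guide
#'
#' @param nested data.frame from [find_nested()].
#' @return List with `nested_count`, `nested_strength` (maximum pattern
#'   score, 0 when none) and `nested_strength_sum` (sum of pattern scores).
#' @export
summarize_nested <- function(nested) {
  if (nrow(nested) == 0L) {
    return(list(nested_count = 0L, nested_strength = 0,
                nested_strength_sum = 0))
  }
  list(nested_count = nrow(nested),
       nested_strength = max(nested$pattern_score),
       nested_strength_sum = sum(nested$pattern_score))
}
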