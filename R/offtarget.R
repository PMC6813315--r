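#' Build an exact k-mer occurrence index over a genome
#'
#' Indexes every plus-strand word of length `L`; a word's two-strand count
#' is recovered as `plus(word) + plus(revcomp(word))`, so every position on
#' both strands contributes one word and a palindromic word is counted once
#' per strand occurrence. Words containing `N` are never indexed.
#'
#' @param genome A `delmh_genome`.
#' @param L Word length (protospacer length + PAM length for guide
#'   uniqueness testing).
#' @return A `kmer_index` object.
#' @export
build_kmer_index <- function(genome, L) {
  L <- as.integer(L)
  stopifnot(L >= 1L)
  words <- unlist(lapply(genome$seq, function(sq) {
    n <- nchar(sq)
    if (n < L) return(character(0))
    substring(sq, seq_len(n - L + 1L), seq_len(n - L + 1L) + L - 1L)
  }), use.names = FALSE)
  if (length(words)) words <- words[!grepl("N", words, fixed = TRUE)]
  counts <- integer(0)
  if (length(words)) {
    tab <- table(words)
    counts <- stats::setNames(as.integer(tab), names(tab))
  }
  structure(list(counts = counts, L = L), class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat("kmer_index: L =", x$L, "-", length(x$counts), "distinct words,",
      sum(x$counts), "plus-strand positions\n")
  invisible(x)
}

# Two-strand count of one concrete word.
kmer_count <- function(index, word) {
  if (nchar(word) != index$L) stop("word length != index L")
  c1 <- index$counts[word]
  c2 <- index$counts[revcomp(word)]
  sum(c1, c2, na.rm = TRUE)
}

# All concrete instantiations of an IUPAC motif (guarded against blow-up).
expand_motif <- function(motif, max_words = 1024L) {
  sets <- iupac_sets()
  parts <- lapply(strsplit(motif, "", fixed = TRUE)[[1L]], function(ch) sets[[ch]])
  n <- prod(vapply(parts, length, integer(1L)))
  if (n > max_words) stop("motif expands to too many words: ", motif)
  grid <- do.call(expand.grid, c(rev(parts), stringsAsFactors = FALSE))
  apply(grid[, rev(seq_along(parts)), drop = FALSE], 1L, paste, collapse = "")
}

#' Count exact genome-wide occurrences of a guide
#'
#' Counts 0-mismatch occurrences of the protospacer+PAM word over both
#' genome strands. With `expand_pam = TRUE` (default) the count sums over
#' every concrete instantiation of the ambiguous PAM motif positions (e.g.
#' `NGG` licenses `AGG`, `CGG`, `GGG`, `TGG`), since any such site can be
#' cleaved; with `expand_pam = FALSE` only the literal observed word is
#' counted. A guide is unique when the total equals 1 (its own site).
#'
#' @param index A `kmer_index` built with `L = nchar(protospacer) +
#'   nchar(motif)`.
#' @param protospacer Protospacer sequence (strand-oriented).
#' @param pam PAM as observed at the site.
#' @param motif IUPAC motif the PAM matched.
#' @param expand_pam Sum over all motif instantiations (default `TRUE`).
#' @return Integer occurrence count.
#' @export
count_occurrences <- function(index, protospacer, pam, motif,
                              expand_pam = TRUE) {
  if (nchar(protospacer) + nchar(motif) != index$L)
    stop("protospacer+PAM length does not match index L")
  if (nchar(pam) != nchar(motif)) stop("PAM/motif length mismatch")
  pams <- if (expand_pam) expand_motif(motif) else pam
  sum(vapply(paste0(protospacer, pams), function(w) kmer_count(index, w),
             numeric(1L)))
}
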