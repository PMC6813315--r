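#' Analysis parameters
#'
#' Collects the tunable parameters of the deletion/microhomology/guide
#' pipeline in one validated list.
#'
#' @param min_del_len Minimum deletion length (bp) for the microhomology
#'   filter cascade. Default 3.
#' @param min_mh_len Minimum full microhomology length (bp) for a variant to
#'   count as microhomology-flanked and for guide design. Default 3.
#' @param max_mismatch Maximum number of mismatches absorbed while extending
#'   the microhomology. Default 1; set 0 for exact-only matching.
#' @param anchor_before_mismatch Number of consecutive matches that must
#'   immediately precede an absorbed mismatch. Default 1; a strict mode uses
#'   3 (a mismatch is only absorbed after a perfect stretch of at least 3 bp).
#' @param pams Character vector of PAM motifs in IUPAC code (e.g. `"NGG"` for
#'   SpCas9; `c("NG", "GAA", "GAT")` for xCas9). All are treated as
#'   blunt-cutting 3 bp upstream of the PAM.
#' @param protospacer_len Protospacer length in bp. Default 20 (SpCas9).
#' @param max_cut_dist Maximum distance (intervening bases) between the cut
#'   and the nearer microhomology copy. Default 50.
#' @param require_both_within If `TRUE`, both microhomology copies must lie
#'   within `max_cut_dist` of the cut (single-cut designs only); default
#'   `FALSE` (nearer copy only, which keeps candidates usable for two-cut
#'   designs on large deletions).
#' @param expand_pam For the off-target uniqueness test, count every concrete
#'   instantiation of the ambiguous PAM positions (default `TRUE`); `FALSE`
#'   counts only the literal protospacer+PAM word as observed.
#' @param nested_min_len Minimum length (bp) of a nested microhomology.
#'   Default 3.
#' @param max_del_len Deletions longer than this (bp) are passed through with
#'   microhomology metrics but no guide search. Default 10000.
#' @param both_configs If `TRUE`, variant reports carry metrics for both
#'   flanking configurations, not only the selected one.
#' @param clinsig_substring If `TRUE`, clinical-significance classification
#'   uses plain substring containment of "pathogenic"/"benign" instead of the
#'   default word-boundary match.
#' @return A named list of class `delmh_params`.
#' @export
delmh_params <- function(min_del_len = 3L,
                         min_mh_len = 3L,
                         max_mismatch = 1L,
                         anchor_before_mismatch = 1L,
                         pams = "NGG",
                         protospacer_len = 20L,
                         max_cut_dist = 50L,
                         require_both_within = FALSE,
                         expand_pam = TRUE,
                         nested_min_len = 3L,
                         max_del_len = 10000L,
                         both_configs = FALSE,
                         clinsig_substring = FALSE) {
  stopifnot(min_del_len >= 1L, min_mh_len >= 1L, max_mismatch >= 0L,
            anchor_before_mismatch >= 1L, protospacer_len >= 1L,
            max_cut_dist >= 0L, nested_min_len >= 1L, max_del_len >= 1L)
  pams <- toupper(pams)
  ok <- grepl("^[ACGTRYSWKMBDHVN]+$", pams)
  if (!all(ok)) stop("invalid PAM motif(s): ", paste(pams[!ok], collapse = ", "))
  structure(list(
    min_del_len = as.integer(min_del_len),
    min_mh_len = as.integer(min_mh_len),
    max_mismatch = as.integer(max_mismatch),
    anchor_before_mismatch = as.integer(anchor_before_mismatch),
    pams = pams,
    protospacer_len = as.integer(protospacer_len),
    max_cut_dist = as.integer(max_cut_dist),
    require_both_within = isTRUE(require_both_within),
    expand_pam = isTRUE(expand_pam),
    nested_min_len = as.integer(nested_min_len),
    max_del_len = as.integer(max_del_len),
    both_configs = isTRUE(both_configs),
    clinsig_substring = isTRUE(clinsig_substring)
  ), class = "delmh_params")
}
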