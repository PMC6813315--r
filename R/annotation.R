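#' Load a gene annotation into an overlap index
#'
#' Accepts GFF3 (feature types `gene`, `exon`, `CDS`, and the UTR types,
#' which are collapsed to `UTR`) or a 7-column BED-like table (chrom, start,
#' end, name, score, strand, type; 0-based half-open, no header). Unknown
#' feature types are dropped with a warning. Coordinates are stored as a
#' `GRanges` (1-based closed internally, converted exactly from either
#' input convention).
#'
#' @param path Path to a `.gff`/`.gff3` or `.bed` file.
#' @return A `GRanges` with a `type` metadata column in
#'   `{gene, exon, CDS, UTR}`.
#' @export
load_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) {
    tb <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                            comment.char = "#")
    if (ncol(tb) < 7L) stop("BED annotation needs 7 columns (type in column 7)")
    gr <- GenomicRanges::GRanges(
      seqnames = tb[[1L]],
      ranges = IRanges::IRanges(start = tb[[2L]] + 1L, end = tb[[3L]]),
      type = tb[[7L]])
  } else {
    g <- rtracklayer::import(path)
    gr <- GenomicRanges::GRanges(seqnames = GenomicRanges::seqnames(g),
                                 ranges = IRanges::ranges(g),
                                 type = as.character(g$type))
  }
  ty <- S4Vectors::mcols(gr)$type
  ty[ty %in% c("five_prime_UTR", "three_prime_UTR", "5UTR", "3UTR",
               "five_prime_utr", "three_prime_utr")] <- "UTR"
  known <- ty %in% c("gene", "exon", "CDS", "UTR")
  if (any(!known)) {
    warning("ignoring ", sum(!known), " feature(s) of unknown type: ",
            paste(unique(ty[!known]), collapse = ", "))
  }
  S4Vectors::mcols(gr)$type <- ty
  gr[known]
}

#' Classify the genic context of a deletion
#'
#' Any overlap counts; precedence is coding exon (`CDS`) first, then `UTR`,
#' then non-coding `exon` (still exonic), then `gene` without exon overlap
#' (intronic), otherwise intergenic.
#'
#' @param variant Variant (list/row with `chrom`, `start`, `del_len`).
#' @param annotation A `GRanges` from [load_annotation()], or `NULL`
#'   (everything intergenic).
#' @return One of `"exonic"`, `"UTR"`, `"intronic"`, `"intergenic"`.
#' @export
classify_context <- function(variant, annotation) {
  if (is.null(annotation) || length(annotation) == 0L) return("intergenic")
  if (!variant$chrom %in% GenomicRanges::seqnames(GenomicRanges::seqinfo(annotation)))
    return("intergenic")
  q <- GenomicRanges::GRanges(
    seqnames = variant$chrom,
    ranges = IRanges::IRanges(start = variant$start + 1L,
                              end = variant$start + variant$del_len))
  hits <- IRanges::subsetByOverlaps(annotation, q)
  ty <- unique(S4Vectors::mcols(hits)$type)
  if ("CDS" %in% ty) "exonic"
  else if ("UTR" %in% ty) "UTR"
  else if ("exon" %in% ty) "exonic"
  else if ("gene" %in% ty) "intronic"
  else "intergenic"
}

#' Frameshift flag for a deletion
#'
#' A deletion is frameshifting when it overlaps coding sequence and its
#' length is not a multiple of 3.
#'
#' @param del_len Deletion length in bp.
#' @param gene_context Result of [classify_context()].
#' @return Logical.
#' @export
is_frameshift <- function(del_len, gene_context) {
  gene_context == "exonic" && (del_len %% 3L) != 0L
}

#' Classify clinical significance labels
#'
#' A variant is `pathogenic` when any of its labels contains the word
#' "pathogenic" (case-insensitive, word-boundary match, so "Likely
#' pathogenic" qualifies but "Conflicting interpretations of pathogenicity"
#' does not), `benign` when any label contains the word "benign", `none`
#' when no labels are present, and `VUS/other` otherwise. `substring = TRUE`
#' switches to plain substring containment.
#'
#' @param labels Character vector of labels, or a single `;`-separated
#'   string.
#' @param substring Use substring containment instead of word-boundary
#'   matching (default `FALSE`).
#' @return One of `"pathogenic"`, `"benign"`, `"VUS/other"`, `"none"`.
#' @export
clin_category <- function(labels, substring = FALSE) {
  if (length(labels) == 1L && grepl(";", labels, fixed = TRUE))
    labels <- strsplit(labels, ";", fixed = TRUE)[[1L]]
  labels <- labels[!is.na(labels) & nzchar(labels)]
  if (length(labels) == 0L) return("none")
  has <- function(word) {
    rx <- if (substring) word else paste0("\\b", word, "\\b")
    any(grepl(rx, labels, ignore.case = TRUE, perl = TRUE))
  }
  if (has("pathogenic")) "pathogenic"
  else if (has("benign")) "benign"
  else "VUS/other"
}
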