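#' Load a reference genome from FASTA
#'
#' Reads a (multi-)FASTA file into an in-memory genome object. Sequences are
#' uppercased and any letter outside `A`, `C`, `G`, `T`, `N` is mapped to `N`.
#' Contig names are taken as the first whitespace-delimited token of each
#' FASTA header and must be unique.
#'
#' All genome coordinates in this package are 0-based, half-open
#' (`[start, end)`); conversion to and from the 1-based conventions of VCF and
#' GFF3 happens only at the format boundary.
#'
#' @param path Path to a FASTA file (a `.fai` index is not required).
#' @return A `delmh_genome` object: a list with `seq` (named character vector
#'   of contig sequences) and `lengths` (named integer vector).
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "acgtACGT"), fa)
#' g <- load_fasta(fa)
#' genome_fetch(g, "c1", 0, 4)  # "ACGT"
load_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA: ", path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) stop("duplicate contig names in FASTA: ", path)
  seqs <- toupper(as.character(ss))
  seqs <- gsub("[^ACGTN]", "N", seqs)
  names(seqs) <- nm
  new_genome(seqs)
}

#' Construct a genome object from named sequences
#'
#' @param seqs Named character vector of contig sequences (uppercase ACGTN).
#' @return A `delmh_genome` object.
#' @export
new_genome <- function(seqs) {
  stopifnot(is.character(seqs), length(seqs) >= 1L, !is.null(names(seqs)))
  structure(list(seq = seqs, lengths = stats::setNames(nchar(seqs), names(seqs))),
            class = "delmh_genome")
}

#' @export
print.delmh_genome <- function(x, ...) {
  cat("delmh_genome:", length(x$seq), "contig(s),",
      format(sum(as.numeric(x$lengths)), big.mark = ","), "bp total\n")
  invisible(x)
}

#' Fetch an interval from a genome
#'
#' 0-based half-open coordinates: `genome_fetch(g, c, i, j)` returns the
#' `j - i` bases at offsets `i .. j-1` of contig `c`.
#'
#' @param genome A `delmh_genome`.
#' @param chrom Contig name.
#' @param start,end 0-based half-open interval bounds.
#' @return Character scalar of length `end - start`.
#' @export
genome_fetch <- function(genome, chrom, start, end) {
  len <- contig_length(genome, chrom)
  if (start < 0 || end > len || start > end)
    stop(sprintf("interval [%d,%d) out of bounds for contig %s (length %d)",
                 start, end, chrom, len))
  substr(genome$seq[[chrom]], start + 1L, end)
}

# Length of one contig; NA-safe error for unknown names.
contig_length <- function(genome, chrom) {
  len <- unname(genome$lengths[chrom])
  if (length(len) != 1L || is.na(len)) stop("unknown contig: ", chrom)
  len
}

# TRUE when the contig exists in the genome.
has_contig <- function(genome, chrom) {
  !is.na(match(chrom, names(genome$lengths)))
}

# Clipped fetch: returns the in-bounds part of [start, end).
genome_fetch_clip <- function(genome, chrom, start, end) {
  len <- contig_length(genome, chrom)
  genome_fetch(genome, chrom, max(0L, start), min(len, end))
}

#' Reverse complement of DNA strings
#'
#' Vectorized; `N` maps to `N`.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  vapply(chartr("ACGTN", "TGCAN", x), function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

# Plain string reversal (no complement).
rev_str <- function(s) {
  paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
}

#' Reverse complement a whole genome
#'
#' Every contig is reverse-complemented in place. An interval `[s, e)` on the
#' original maps to `[L - e, L - s)` on the result, where `L` is the contig
#' length. Used by the strand-symmetry checks.
#'
#' @param genome A `delmh_genome`.
#' @return A `delmh_genome` with reverse-complemented contigs.
#' @export
revcomp_genome <- function(genome) {
  new_genome(stats::setNames(revcomp(genome$seq), names(genome$seq)))
}

#' Write a genome to FASTA
#'
#' @param genome A `delmh_genome`.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(genome$seq)) {
    writeLines(paste0(">", nm), con)
    sq <- genome$seq[[nm]]
    n <- nchar(sq)
    starts <- seq(1L, n, by = width)
    writeLines(substring(sq, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}
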