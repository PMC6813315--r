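iupac_sets <- function() {
  list(A = "A", C = "C", G = "G", T = "T",
       R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
       K = c("G", "T"), M = c("A", "C"),
       B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
       V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
}

iupac_regex <- function(motif) {
  sets <- iupac_sets()
  paste(vapply(strsplit(motif, "", fixed = TRUE)[[1L]], function(ch) {
    s <- sets[[ch]]
    if (is.null(s)) stop("invalid IUPAC code: ", ch)
    if (length(s) == 1L) s else paste0("[", paste(s, collapse = ""), "]")
  }, character(1L)), collapse = "")
}

# 0-based start offsets of all (overlapping) IUPAC motif matches in `seq`.
# `N` in the subject never matches (it is outside every base class).
iupac_match_starts <- function(seq, motif) {
  if (nchar(seq) < nchar(motif)) return(integer(0))
  m <- gregexpr(paste0("(?=", iupac_regex(motif), ")"), seq, perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m) - 1L
}

#' Scan a genomic window for PAM motifs on both strands
#'
#' Plus-strand matches are reported directly; minus-strand matches are
#' reported through the plus-strand coordinates of the reverse-complemented
#' motif (i.e. `pam_start` is always the 0-based plus-strand offset of the
#' leftmost base of the matched segment).
#'
#' @param genome A `delmh_genome`.
#' @param chrom Contig name.
#' @param win_start,win_end 0-based half-open window (clipped to the contig).
#' @param motifs Character vector of IUPAC PAM motifs.
#' @return data.frame with columns `motif`, `strand` (`+`/`-`), `pam_start`.
#' @export
scan_pams <- function(genome, chrom, win_start, win_end, motifs) {
  len <- contig_length(genome, chrom)
  ws <- max(0L, as.integer(win_start))
  we <- min(len, as.integer(win_end))
  if (we <= ws) {
    return(data.frame(motif = character(0), strand = character(0),
                      pam_start = integer(0)))
  }
  win <- genome_fetch(genome, chrom, ws, we)
  out <- lapply(motifs, function(mo) {
    plus <- iupac_match_starts(win, mo)
    minus <- iupac_match_starts(win, revcomp(mo))
    data.frame(
      motif = rep(mo, length(plus) + length(minus)),
      strand = c(rep("+", length(plus)), rep("-", length(minus))),
      pam_start = c(plus, minus) + ws)
  })
  res <- do.call(rbind, out)
  res[order(res$pam_start, res$strand, res$motif), , drop = FALSE]
}

#' Cut position of a blunt-cutting Cas nuclease
#'
#' The cut is modeled 3 bp upstream of the PAM (SpCas9 geometry, applied to
#' every supported motif), expressed as a 0-based inter-base coordinate: the
#' cut falls between genomic bases `cut_pos - 1` and `cut_pos`.
#'
#' @param motif PAM motif (used for its length on the minus strand).
#' @param strand `"+"` or `"-"`.
#' @param pam_start 0-based plus-strand offset of the matched PAM segment
#'   (for minus-strand guides, of the reverse-complement motif match).
#' @return Integer inter-base cut coordinate.
#' @export
#' @examples
#' cut_position("NGG", "+", 100)  # 97
#' cut_position("NGG", "-", 100)  # 106
cut_position <- function(motif, strand, pam_start) {
  if (strand == "+") as.integer(pam_start) - 3L
  else as.integer(pam_start) + nchar(motif) + 3L
}

# Intervening bases between an inter-base cut coordinate and a span [a, b):
# 0 when the cut is inside or adjacent to the span.
span_cut_dist <- function(cut, span) {
  if (cut <= span[1L]) span[1L] - cut
  else if (cut >= span[2L]) cut - span[2L]
  else 0L
}

#' Enumerate CRISPR guide candidates for a canonical deletion
#'
#' Finds every PAM (both strands, all motifs) whose blunt cut falls within
#' the deletion interval `[s, s+n]` (inter-base coordinates), then flags as
#' valid the cuts that (i) spare the junction-proximal `min(3, mhL)` bp of
#' the inner microhomology copy — so at least 3 bp of microhomology is
#' retained on either side of the break — and (ii) lie within `max_cut_dist`
#' intervening bases of the nearer microhomology copy (or of both copies
#' with `require_both_within`). Candidates whose protospacer would run off
#' the contig or contain `N` are invalid.
#'
#' @param genome A `delmh_genome`.
#' @param canonical Result of [canonicalize_deletion()].
#' @param params A [delmh_params()] list (`pams`, `protospacer_len`,
#'   `max_cut_dist`, `require_both_within`, `min_mh_len`).
#' @return data.frame of candidates (one row per PAM with an in-variant
#'   cut): `variant_id`, `chrom`, `motif`, `strand`, `pam_start`, `cut_pos`,
#'   `protospacer`, `pam`, `dist_left`, `dist_right`, `valid`. Zero rows when
#'   the selected microhomology is shorter than `min_mh_len`.
#' @export
enumerate_guides <- function(genome, canonical, params = delmh_params()) {
  empty <- data.frame(variant_id = character(0), chrom = character(0),
                      motif = character(0), strand = character(0),
                      pam_start = integer(0), cut_pos = integer(0),
                      protospacer = character(0), pam = character(0),
                      dist_left = integer(0), dist_right = integer(0),
                      valid = logical(0))
  v <- canonical$variant
  mh <- canonical$mh
  n <- nchar(v$deleted_seq)
  if (mh$mhL < params$min_mh_len || n > params$max_del_len) return(empty)
  s <- v$start
  chrom <- v$chrom
  len <- contig_length(genome, chrom)
  plen <- params$protospacer_len
  maxmot <- max(nchar(params$pams))
  pad <- plen + maxmot + 4L
  pams <- scan_pams(genome, chrom, s - pad, s + n + pad, params$pams)
  if (nrow(pams) == 0L) return(empty)
  prot <- min(3L, mh$mhL)
  lo <- if (mh$config == "OUTER_RIGHT") s + prot else s
  hi <- if (mh$config == "OUTER_RIGHT") s + n else s + n - prot
  rows <- vector("list", nrow(pams))
  for (i in seq_len(nrow(pams))) {
    mo <- pams$motif[i]; str <- pams$strand[i]; ps <- pams$pam_start[i]
    ml <- nchar(mo)
    cut <- cut_position(mo, str, ps)
    if (cut < s || cut > s + n) next
    if (str == "+") {
      sp_span <- c(ps - plen, ps)
      pam_txt <- genome_fetch_clip(genome, chrom, ps, ps + ml)
      sp_txt <- if (sp_span[1L] >= 0L) genome_fetch(genome, chrom, sp_span[1L], sp_span[2L]) else ""
    } else {
      sp_span <- c(ps + ml, ps + ml + plen)
      pam_txt <- revcomp(genome_fetch_clip(genome, chrom, ps, ps + ml))
      sp_txt <- if (sp_span[2L] <= len) revcomp(genome_fetch(genome, chrom, sp_span[1L], sp_span[2L])) else ""
    }
    seq_ok <- nchar(sp_txt) == plen && !grepl("N", sp_txt, fixed = TRUE) &&
      !grepl("N", pam_txt, fixed = TRUE)
    dl <- span_cut_dist(cut, mh$left_span)
    dr <- span_cut_dist(cut, mh$right_span)
    dist_ok <- if (params$require_both_within) {
      max(dl, dr) <= params$max_cut_dist
    } else {
      min(dl, dr) <= params$max_cut_dist
    }
    in_protected <- cut < lo || cut > hi
    rows[[i]] <- data.frame(
      variant_id = if (!is.null(v$id)) v$id else NA_character_,
      chrom = chrom, motif = mo, strand = str,
      pam_start = ps, cut_pos = cut,
      protospacer = sp_txt, pam = pam_txt,
      dist_left = dl, dist_right = dr,
      valid = seq_ok && dist_ok && !in_protected)
  }
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$cut_pos, out$strand, out$motif, out$pam_start), , drop = FALSE]
}
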