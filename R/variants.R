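new_variant_table <- function(id = character(0), chrom = character(0),
                              start = integer(0), deleted_seq = character(0),
                              source = character(0), clin_sig = character(0)) {
  data.frame(id = id, chrom = chrom, start = as.integer(start),
             deleted_seq = deleted_seq, del_len = nchar(deleted_seq),
             source = source, clin_sig = clin_sig)
}

# Reduce a (REF, ALT) pair to a pure deletion, if it is one.
# Trims the longest shared prefix (the anchor) first, then any shared
# suffix of the remainders; the pair is a pure deletion iff the ALT is
# fully absorbed while REF retains sequence. Returns NULL otherwise.
# offset = number of anchor bases trimmed from the left.
normalize_indel <- function(ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  if (na >= nr) return(NULL)
  kp <- 0L
  while (kp < na && kp < nr &&
         substr(ref, kp + 1L, kp + 1L) == substr(alt, kp + 1L, kp + 1L)) {
    kp <- kp + 1L
  }
  r2 <- substr(ref, kp + 1L, nr); a2 <- substr(alt, kp + 1L, na)
  ks <- 0L
  while (ks < nchar(a2) &&
         substr(r2, nchar(r2) - ks, nchar(r2) - ks) ==
         substr(a2, nchar(a2) - ks, nchar(a2) - ks)) {
    ks <- ks + 1L
  }
  if (ks < nchar(a2)) return(NULL)        # ALT not absorbed: not a pure deletion
  deleted <- substr(r2, 1L, nchar(r2) - ks)
  if (nchar(deleted) == 0L) return(NULL)
  list(offset = kp, deleted_seq = deleted)
}

split_clnsig <- function(x) {
  if (is.na(x) || x == "") return("")
  labs <- unlist(strsplit(x, "[,|]"))
  labs <- gsub("_", " ", trimws(labs))
  paste(labs[labs != ""], collapse = ";")
}

#' Parse deletion variants from a VCF file
#'
#' Extracts pure deletions from a VCF (dbSNP/ClinVar dialect): records whose
#' ALT allele, after trimming the shared anchor bases, is empty while REF
#' retains deleted sequence. Multi-allelic records are decomposed and only
#' deletion ALT alleles kept. Symbolic ALTs (`<DEL>` etc.), insertions,
#' SNVs, and records whose REF disagrees with the genome are skipped and
#' counted. Clinical significance is read from the `CLNSIG` INFO field when
#' present (multi-valued labels split on `,` and `|`).
#'
#' @param path Path to a VCF (plain or bgzipped).
#' @param genome A `delmh_genome` for REF validation.
#' @param source Source label recorded on each variant (default "VCF").
#' @return data.frame of deletion variants (`id`, `chrom`, `start` 0-based,
#'   `deleted_seq`, `del_len`, `source`, `clin_sig`), with an attribute
#'   `skipped` (named integer: reasons x counts).
#' @export
parse_deletions_vcf <- function(path, genome, source = "VCF") {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  skipped <- c(symbolic_alt = 0L, not_deletion = 0L, ref_mismatch = 0L,
               unknown_contig = 0L, n_in_deleted = 0L)
  rows <- list()
  for (r in seq_len(nrow(fix))) {
    chrom <- fix[r, "CHROM"]; pos1 <- as.integer(fix[r, "POS"])
    ref <- toupper(fix[r, "REF"])
    alts <- fix[r, "ALT"]
    id <- fix[r, "ID"]
    info <- if ("INFO" %in% colnames(fix)) fix[r, "INFO"] else NA_character_
    clnsig <- ""
    if (!is.na(info)) {
      m <- regmatches(info, regexpr("(?:^|;)CLNSIG=([^;]*)", info))
      if (length(m)) clnsig <- split_clnsig(sub("^;?CLNSIG=", "", m))
    }
    if (is.na(alts) || alts == ".") { skipped["not_deletion"] <- skipped["not_deletion"] + 1L; next }
    if (!has_contig(genome, chrom)) { skipped["unknown_contig"] <- skipped["unknown_contig"] + 1L; next }
    for (alt in strsplit(toupper(alts), ",", fixed = TRUE)[[1L]]) {
      if (grepl("^<.*>$", alt) || alt == "*") {
        skipped["symbolic_alt"] <- skipped["symbolic_alt"] + 1L; next
      }
      nd <- normalize_indel(ref, alt)
      if (is.null(nd)) { skipped["not_deletion"] <- skipped["not_deletion"] + 1L; next }
      start0 <- (pos1 - 1L) + nd$offset
      n <- nchar(nd$deleted_seq)
      if (start0 + n > contig_length(genome, chrom)) {
        skipped["ref_mismatch"] <- skipped["ref_mismatch"] + 1L; next
      }
      gseq <- genome_fetch(genome, chrom, start0, start0 + n)
      if (gseq != nd$deleted_seq) {
        skipped["ref_mismatch"] <- skipped["ref_mismatch"] + 1L; next
      }
      if (grepl("N", nd$deleted_seq, fixed = TRUE)) {
        skipped["n_in_deleted"] <- skipped["n_in_deleted"] + 1L; next
      }
      rows[[length(rows) + 1L]] <- new_variant_table(
        id = if (is.na(id) || id == ".") sprintf("%s_%d_%d", chrom, start0, n) else id,
        chrom = chrom, start = start0, deleted_seq = nd$deleted_seq,
        source = source, clin_sig = clnsig)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else new_variant_table()
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Parse deletion variants from a plain tab-delimited table
#'
#' Expects a header and columns `chrom`, `start` (0-based first deleted
#' base), `deleted_seq`, `id`, and optionally `clin_sig` (`;`-separated
#' labels) and `source`.
#'
#' @param path Path to a TSV file.
#' @param genome A `delmh_genome`; each record's `deleted_seq` is validated
#'   against the genome slice, mismatches are dropped and counted.
#' @param source Default source label when the table has no `source` column.
#' @return data.frame of deletion variants, `skipped` attribute as in
#'   [parse_deletions_vcf()].
#' @export
parse_deletions_table <- function(path, genome, source = "table") {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "deleted_seq", "id")
  if (!all(need %in% names(tb)))
    stop("variant table must have columns: ", paste(need, collapse = ", "))
  skipped <- c(ref_mismatch = 0L, unknown_contig = 0L, n_in_deleted = 0L)
  keep <- logical(nrow(tb))
  tb$deleted_seq <- toupper(tb$deleted_seq)
  for (r in seq_len(nrow(tb))) {
    chrom <- tb$chrom[r]; s <- as.integer(tb$start[r])
    n <- nchar(tb$deleted_seq[r])
    if (!has_contig(genome, chrom)) { skipped["unknown_contig"] <- skipped["unknown_contig"] + 1L; next }
    if (s < 0L || s + n > contig_length(genome, chrom) ||
        genome_fetch(genome, chrom, s, s + n) != tb$deleted_seq[r]) {
      skipped["ref_mismatch"] <- skipped["ref_mismatch"] + 1L; next
    }
    if (grepl("N", tb$deleted_seq[r], fixed = TRUE)) {
      skipped["n_in_deleted"] <- skipped["n_in_deleted"] + 1L; next
    }
    keep[r] <- TRUE
  }
  tb <- tb[keep, , drop = FALSE]
  out <- new_variant_table(
    id = as.character(tb$id), chrom = tb$chrom, start = as.integer(tb$start),
    deleted_seq = tb$deleted_seq,
    source = if ("source" %in% names(tb)) tb$source else rep(source, nrow(tb)),
    clin_sig = if ("clin_sig" %in% names(tb)) ifelse(is.na(tb$clin_sig), "", tb$clin_sig)
               else rep("", nrow(tb)))
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Write a variant table to TSV
#'
#' Round-trips with [parse_deletions_table()].
#'
#' @param variants Variant data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Remove duplicate deletion records
#'
#' Two records are duplicates when they represent the same deletion after
#' canonicalization (same contig, same canonical start, same deletion
#' length). Among duplicates the record with the richest clinical
#' annotation wins (most labels, ties to the first); when duplicates come
#' from different sources the merged record's source is `"merged"` and
#' clinical labels are united.
#'
#' @param variants Variant data.frame.
#' @param genome A `delmh_genome` (needed to canonicalize).
#' @param params A [delmh_params()] list.
#' @return Deduplicated variant data.frame (original, non-canonicalized
#'   coordinates of the winning record are retained).
#' @export
deduplicate_variants <- function(variants, genome, params = delmh_params()) {
  if (nrow(variants) == 0L) return(variants)
  keys <- character(nrow(variants))
  for (r in seq_len(nrow(variants))) {
    cv <- canonicalize_deletion(genome, as.list(variants[r, ]), params)
    keys[r] <- sprintf("%s:%d:%d", variants$chrom[r], cv$variant$start,
                       variants$del_len[r])
  }
  out <- lapply(split(seq_len(nrow(variants)), keys), function(idx) {
    grp <- variants[idx, , drop = FALSE]
    nlab <- vapply(strsplit(grp$clin_sig, ";", fixed = TRUE),
                   function(x) sum(nzchar(x)), integer(1L))
    win <- grp[which.max(nlab), , drop = FALSE]
    all_labs <- unique(unlist(strsplit(grp$clin_sig, ";", fixed = TRUE)))
    all_labs <- all_labs[nzchar(all_labs)]
    win$clin_sig <- paste(all_labs, collapse = ";")
    if (length(unique(grp$source)) > 1L) win$source <- "merged"
    win
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start, out$del_len, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a variant table as a minimal VCF
#'
#' Emits VCF v4.2 deletion records in the shared-anchor convention (REF =
#' anchor base + deleted sequence, ALT = anchor base), with optional CLNSIG
#' INFO labels. Round-trips through [parse_deletions_vcf()].
#'
#' @param genome A `delmh_genome` (for contig headers and anchor bases).
#' @param variants Variant data.frame; every `start` must be >= 1.
#' @param path Output path.
#' @param clnsig Optional character vector of CLNSIG values (`,`/`|`
#'   separated labels; `""` for none), recycled over rows.
#' @return `path`, invisibly.
#' @export
write_deletions_vcf <- function(genome, variants, path, clnsig = NULL) {
  lines <- c("##fileformat=VCFv4.2",
             paste0("##contig=<ID=", names(genome$seq), ",length=",
                    genome$lengths, ">"),
             "##INFO=<ID=CLNSIG,Number=.,Type=String,Description=\"Clinical significance\">",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  if (!is.null(clnsig)) clnsig <- rep_len(clnsig, nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    anchor <- genome_fetch(genome, v$chrom, v$start - 1L, v$start)
    info <- if (!is.null(clnsig) && nzchar(clnsig[i])) {
      paste0("CLNSIG=", gsub(" ", "_", clnsig[i]))
    } else "."
    lines <- c(lines, paste(v$chrom, v$start, v$id,
                            paste0(anchor, v$deleted_seq), anchor,
                            ".", ".", info, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
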