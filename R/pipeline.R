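#' Analyze a single deletion variant
#'
#' Runs the per-variant core: canonicalization, microhomology selection,
#' guide enumeration, optional off-target counting and nested-microhomology
#' scoring of the valid guides.
#'
#' @param genome A `delmh_genome`.
#' @param variant Variant (list/row with `id`, `chrom`, `start`,
#'   `deleted_seq`).
#' @param params A [delmh_params()] list.
#' @param kmer_indexes Named list of `kmer_index` objects keyed by word
#'   length (as character), or `NULL` to skip the uniqueness test.
#' @return List with `canonical`, `candidates` (all in-variant PAM
#'   candidates), and `guides` (valid guides with `offtarget_count`,
#'   `is_unique`, `nested_count`, `nested_strength`, `nested_strength_sum`).
#' @export
analyze_variant <- function(genome, variant, params = delmh_params(),
                            kmer_indexes = NULL) {
  cv <- canonicalize_deletion(genome, as.list(variant), params)
  cands <- enumerate_guides(genome, cv, params)
  guides <- cands[cands$valid, , drop = FALSE]
  ng <- nrow(guides)
  guides$offtarget_count <- rep(NA_integer_, ng)
  guides$is_unique <- rep(NA, ng)
  guides$nested_count <- rep(NA_integer_, ng)
  guides$nested_strength <- rep(NA_real_, ng)
  guides$nested_strength_sum <- rep(NA_real_, ng)
  if (ng > 0L) {
    for (i in seq_len(ng)) {
      if (!is.null(kmer_indexes)) {
        L <- nchar(guides$protospacer[i]) + nchar(guides$motif[i])
        idx <- kmer_indexes[[as.character(L)]]
        if (!is.null(idx)) {
          oc <- count_occurrences(idx, guides$protospacer[i], guides$pam[i],
                                  guides$motif[i], params$expand_pam)
          guides$offtarget_count[i] <- as.integer(oc)
          guides$is_unique[i] <- oc == 1L
        }
      }
      nn <- find_nested(genome, cv, guides$cut_pos[i], params$nested_min_len)
      sm <- summarize_nested(nn)
      guides$nested_count[i] <- sm$nested_count
      guides$nested_strength[i] <- sm$nested_strength
      guides$nested_strength_sum[i] <- sm$nested_strength_sum
    }
  }
  list(canonical = cv, candidates = cands, guides = guides)
}

guide_id <- function(variant_id, cut_pos, strand) {
  sprintf("%s_c%d%s", variant_id, cut_pos, strand)
}

#' Run the full deletion/microhomology/guide pipeline
#'
#' For every input deletion: canonicalize, detect and select the flanking
#' microhomology, enumerate guide candidates, test guide uniqueness by
#' exact genome-wide matching, score nested microhomologies, annotate genic
#' context, frameshift and clinical category, and assemble variant-level
#' and guide-level report tables plus the filter funnel.
#'
#' @param genome A `delmh_genome`.
#' @param variants Variant data.frame (see [parse_deletions_vcf()]).
#' @param annotation Optional `GRanges` from [load_annotation()].
#' @param params A [delmh_params()] list.
#' @return List of class `delmh_result`: `variants` (one row per input
#'   variant), `guides` (one row per valid guide), `funnel` (survivor
#'   counts along the default filter cascade), `params`.
#' @export
delmh_run <- function(genome, variants, annotation = NULL,
                      params = delmh_params()) {
  stopifnot(is.data.frame(variants))
  # one exact-match index per distinct protospacer+PAM word length
  Ls <- unique(params$protospacer_len + nchar(params$pams))
  kmer_indexes <- stats::setNames(
    lapply(Ls, function(L) build_kmer_index(genome, L)), as.character(Ls))
  vrows <- vector("list", nrow(variants))
  grows <- vector("list", nrow(variants))
  for (r in seq_len(nrow(variants))) {
    v <- as.list(variants[r, ])
    an <- analyze_variant(genome, v, params, kmer_indexes)
    mh <- an$canonical$mh
    cands <- an$candidates
    g <- an$guides
    if (nrow(g) > 0L) {
      g$guide_id <- guide_id(v$id, g$cut_pos, g$strand)
      # deterministic preference: unique first, then fewer nested, then cut
      ord <- order(!g$is_unique, g$nested_count, g$cut_pos, g$strand)
      g <- g[ord, , drop = FALSE]
    }
    n_valid <- nrow(g)
    n_unique <- if (n_valid) sum(g$is_unique, na.rm = TRUE) else 0L
    n_nonested <- if (n_valid) {
      sum(g$is_unique & g$nested_count == 0L, na.rm = TRUE)
    } else 0L
    best <- if (n_valid) g$guide_id[1L] else NA_character_
    vn_count <- if (n_valid) g$nested_count[1L] else NA_integer_
    vn_strength <- if (n_valid) g$nested_strength[1L] else NA_real_
    ctx <- classify_context(list(chrom = v$chrom,
                                 start = an$canonical$variant$start,
                                 del_len = nchar(v$deleted_seq)), annotation)
    clin <- clin_category(if (is.null(v$clin_sig)) "" else v$clin_sig,
                          substring = params$clinsig_substring)
    vrows[[r]] <- data.frame(
      id = v$id, chrom = v$chrom,
      start = an$canonical$variant$start,
      end = an$canonical$variant$start + nchar(v$deleted_seq),
      del_len = nchar(v$deleted_seq),
      source = if (is.null(v$source)) NA_character_ else v$source,
      clin_sig_raw = if (is.null(v$clin_sig)) "" else v$clin_sig,
      clin_category = clin, gene_context = ctx,
      frameshift = is_frameshift(nchar(v$deleted_seq), ctx),
      shift_offset = an$canonical$shift_offset,
      flank_config = mh$config, no_mh = mh$no_mh,
      mhL = mh$mhL, mh1L = mh$mh1L, matches = mh$matches,
      mismatches = mh$mismatches, score = mh$score,
      hom = mh$hom, gc = mh$gc, dist = mh$dist, dist_exact = mh$dist_exact,
      mh_seq = mh$mh_seq,
      n_pam_candidates = nrow(cands), n_valid_guides = n_valid,
      n_unique_guides = n_unique, n_guides_no_nested = n_nonested,
      nested_count = vn_count, nested_strength = vn_strength,
      best_guide_id = best)
    grows[[r]] <- g
  }
  vr <- if (length(vrows)) do.call(rbind, vrows) else data.frame()
  gr <- do.call(rbind, grows[vapply(grows, function(x) !is.null(x) && nrow(x) > 0L, logical(1L))])
  if (is.null(gr)) {
    gr <- data.frame(variant_id = character(0), guide_id = character(0),
                     chrom = character(0), motif = character(0),
                     strand = character(0), pam_start = integer(0),
                     cut_pos = integer(0), protospacer = character(0),
                     pam = character(0), dist_left = integer(0),
                     dist_right = integer(0), valid = logical(0),
                     offtarget_count = integer(0), is_unique = logical(0),
                     nested_count = integer(0), nested_strength = numeric(0),
                     nested_strength_sum = numeric(0))
  }
  if (nrow(vr)) {
    vr <- vr[order(vr$chrom, vr$start, vr$id), , drop = FALSE]
    rownames(vr) <- NULL
  }
  if (nrow(gr)) {
    gr <- gr[order(gr$variant_id, gr$cut_pos, gr$strand), , drop = FALSE]
    rownames(gr) <- NULL
  }
  flt <- apply_filters(vr, list(min_del_len = params$min_del_len,
                                min_mh_len = params$min_mh_len,
                                require_unique_guide = TRUE,
                                require_no_nested = TRUE))
  structure(list(variants = vr, guides = gr,
                 funnel = attr(flt, "funnel"), params = params),
            class = "delmh_result")
}

#' @export
print.delmh_result <- function(x, ...) {
  cat("delmh_result:", nrow(x$variants), "variant(s),",
      nrow(x$guides), "valid guide(s)\n")
  if (!is.null(x$funnel)) {
    cat("filter funnel:\n")
    for (i in seq_len(nrow(x$funnel)))
      cat(sprintf("  %-28s %d\n", x$funnel$step[i], x$funnel$n[i]))
  }
  invisible(x)
}

#' Apply the filter cascade to a variant report
#'
#' Conjunctive filters in a fixed order; the survivor count after each
#' applied step is recorded in the `funnel` attribute. An empty criteria
#' list is the identity.
#'
#' @param reports Variant report data.frame (from [delmh_run()]).
#' @param criteria Named list; recognized entries: `min_del_len`,
#'   `min_mh_len`, `require_unique_guide` (logical), `require_no_nested`
#'   (logical; keeps variants with at least one unique guide free of nested
#'   microhomologies), `gene_context` (character vector), `clin_category`
#'   (character vector), `max_dist`.
#' @return Filtered data.frame with attribute `funnel` (data.frame of
#'   `step`, `n`).
#' @export
apply_filters <- function(reports, criteria = list()) {
  steps <- data.frame(step = "input", n = nrow(reports))
  keep <- reports
  note <- function(lab) {
    steps <<- rbind(steps, data.frame(step = lab, n = nrow(keep)))
  }
  if (!is.null(criteria$min_del_len)) {
    keep <- keep[keep$del_len >= criteria$min_del_len, , drop = FALSE]
    note(sprintf("del_len >= %d", criteria$min_del_len))
  }
  if (!is.null(criteria$min_mh_len)) {
    keep <- keep[keep$mhL >= criteria$min_mh_len, , drop = FALSE]
    note(sprintf("mhL >= %d", criteria$min_mh_len))
  }
  if (!is.null(criteria$max_dist)) {
    keep <- keep[keep$dist <= criteria$max_dist, , drop = FALSE]
    note(sprintf("dist <= %d", criteria$max_dist))
  }
  if (isTRUE(criteria$require_unique_guide)) {
    keep <- keep[keep$n_unique_guides > 0L, , drop = FALSE]
    note("unique guide available")
  }
  if (isTRUE(criteria$require_no_nested)) {
    keep <- keep[keep$n_guides_no_nested > 0L, , drop = FALSE]
    note("unique guide without nested MH")
  }
  if (!is.null(criteria$gene_context)) {
    keep <- keep[keep$gene_context %in% criteria$gene_context, , drop = FALSE]
    note(paste("gene context:", paste(criteria$gene_context, collapse = "/")))
  }
  if (!is.null(criteria$clin_category)) {
    keep <- keep[keep$clin_category %in% criteria$clin_category, , drop = FALSE]
    note(paste("clinical:", paste(criteria$clin_category, collapse = "/")))
  }
  rownames(keep) <- NULL
  attr(keep, "funnel") <- steps
  keep
}

#' Write variant-level and guide-level reports
#'
#' Writes `<prefix>-variants.tsv` and `<prefix>-guides.tsv` (tab-separated,
#' headers, deterministic row order: variants by chrom/start/id, guides by
#' variant, cut position, strand) and `<prefix>-summary.json` with the
#' parameter echo and filter-funnel counts. Output is byte-identical across
#' reruns on identical input.
#'
#' @param result A `delmh_result` from [delmh_run()].
#' @param prefix Output path prefix.
#' @return Character vector of the three file paths, invisibly.
#' @export
write_reports <- function(result, prefix) {
  vr <- result$variants
  gr <- result$guides
  if (nrow(vr)) vr <- vr[order(vr$chrom, vr$start, vr$id), , drop = FALSE]
  if (nrow(gr)) gr <- gr[order(gr$variant_id, gr$cut_pos, gr$strand), , drop = FALSE]
  fv <- paste0(prefix, "-variants.tsv")
  fg <- paste0(prefix, "-guides.tsv")
  fs <- paste0(prefix, "-summary.json")
  utils::write.table(vr, fv, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(gr, fg, sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(
    n_variants = nrow(vr),
    n_guides = nrow(gr),
    params = unclass(result$params),
    funnel = result$funnel)
  jsonlite::write_json(summary, fs, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(fv, fg, fs))
}
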