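rand_dna <- function(n, gc = 0.5) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

other_base <- function(exclude) {
  sample(setdiff(c("A", "C", "G", "T"), exclude), 1L)
}

#' Generate a random genome
#'
#' I.i.d. bases with the requested GC content, reproducible under `seed`.
#'
#' @param length Contig length in bp (recycled over `n_contigs`).
#' @param gc GC fraction in (0, 1). Default 0.5 (uniform base composition).
#' @param seed Optional integer seed.
#' @param n_contigs Number of contigs (named `chr1`, `chr2`, ...).
#' @return A `delmh_genome`.
#' @export
make_genome <- function(length, gc = 0.5, seed = NULL, n_contigs = 1L) {
  stopifnot(gc > 0, gc < 1, length >= 1L)
  if (!is.null(seed)) set.seed(seed)
  lens <- rep_len(as.integer(length), n_contigs)
  seqs <- vapply(lens, rand_dna, character(1L), gc = gc)
  names(seqs) <- paste0("chr", seq_len(n_contigs))
  new_genome(seqs)
}

#' Specification of a planted deletion locus
#'
#' Describes the ground truth to write into a synthetic genome: a deletion
#' of length `mh_len + mh_dist` flanked by a perfect microhomology of
#' `mh_len` bp at `mh_dist` bp heterology distance, in the requested
#' flanking configuration, optionally with an NGG PAM whose cut is valid
#' for the locus, a nested 3-bp microhomology straddling that cut
#' (requires `mh_dist >= 10` and `pam = TRUE`), and exact off-target
#' duplicates of the guide word.
#'
#' A deletion with an exact flanking microhomology of length `m` always has
#' `m + 1` equivalent coordinate representations reachable by shifting
#' through the microhomology copy; at the leftmost the inner copy sits at
#' the deletion's 5' end (`OUTER_RIGHT`) and at the rightmost at its 3' end
#' (`OUTER_LEFT`). Canonicalization (maximum score, ties to the leftmost
#' start) therefore always selects the `OUTER_RIGHT` reading for exact
#' microhomologies. `config` here chooses the representation at which the
#' planted variant is *reported* to the caller: `OUTER_RIGHT` hands it over
#' at canonical coordinates, `OUTER_LEFT` at the rightmost equivalent
#' representation, where local analysis reads the same microhomology in the
#' `OUTER_LEFT` configuration and canonicalization must shift it back.
#'
#' @param mh_len Microhomology length `m` (>= 1).
#' @param mh_dist Heterology distance `d` (>= 0).
#' @param config Representation handed to the caller: `"OUTER_RIGHT"`
#'   (canonical) or `"OUTER_LEFT"` (rightmost equivalent).
#' @param pam Plant a valid NGG guide (default `FALSE`).
#' @param nested Plant a nested microhomology at the planted cut.
#' @param offtarget_copies Number of extra exact copies of the guide word
#'   to plant elsewhere (makes the guide non-unique).
#' @return A `plant_spec` list.
#' @export
plant_spec <- function(mh_len, mh_dist, config = "OUTER_RIGHT",
                       pam = FALSE, nested = FALSE, offtarget_copies = 0L) {
  stopifnot(mh_len >= 1L, mh_dist >= 0L,
            config %in% c("OUTER_RIGHT", "OUTER_LEFT"))
  if (nested && (!pam || mh_dist < 10L))
    stop("nested planting requires pam = TRUE and mh_dist >= 10")
  if ((pam || offtarget_copies > 0L) && mh_len < 3L)
    stop("guide planting requires mh_len >= 3")
  structure(list(mh_len = as.integer(mh_len), mh_dist = as.integer(mh_dist),
                 config = config, pam = isTRUE(pam), nested = isTRUE(nested),
                 offtarget_copies = as.integer(offtarget_copies)),
            class = "plant_spec")
}

# Build one OUTER_RIGHT locus string with locus-relative truth; the caller
# reverse-complements it for OUTER_LEFT. Layout:
#   [left flank, llen bp] [M H] [M rest]
# with M the microhomology copy (m bp) and H the heterology (d bp).
# Junction constraints written last so planted structures cannot undo them.
build_locus_right <- function(spec) {
  m <- spec$mh_len; d <- spec$mh_dist; n <- m + d
  llen <- max(n, 30L); rlen <- max(n, 30L)
  M <- strsplit(rand_dna(m), "", fixed = TRUE)[[1L]]
  H <- if (d > 0L) strsplit(rand_dna(d), "", fixed = TRUE)[[1L]] else character(0)
  rest <- strsplit(rand_dna(rlen - m), "", fixed = TRUE)[[1L]]
  L <- strsplit(rand_dna(llen), "", fixed = TRUE)[[1L]]
  cut_rel <- NA_integer_; strand <- NA_character_
  s_rel <- llen
  gg_forces_rest1 <- FALSE
  if (spec$pam) {
    if (spec$nested) {
      # cut between H[t] and H[t+1], a 3-bp repeat pair straddling it, and
      # the PAM GG further inside the heterology (needs 4 <= t <= d - 6)
      t <- if (d == 10L) 4L else sample(4L:(d - 6L), 1L)
      cut_rel <- s_rel + m + t
      strand <- "+"
      R <- strsplit(rand_dna(3L), "", fixed = TRUE)[[1L]]
      H[(t - 2L):t] <- R                 # left copy, ends at the cut
      H[(t + 1L):(t + 3L)] <- R          # right copy, starts at the cut
      H[t - 3L] <- other_base(R[3L])     # block leftward extension
      H[t + 4L] <- other_base(R[1L])     # block rightward extension
      H[t + 5L] <- "G"; H[t + 6L] <- "G" # NGG with cut 3 bp upstream
    } else if (m <= 4L) {
      # plus strand, cut at the distal deletion edge; GG lands just past
      # the flank microhomology copy (flank offsets 5 and 6, 1-based)
      cut_rel <- s_rel + n
      strand <- "+"
      rest[5L - m] <- "G"; rest[6L - m] <- "G"
      gg_forces_rest1 <- m == 4L
    } else {
      # minus strand, cut 3 bp inside the proximal copy; the PAM's CC sits
      # in the left flank clear of the junction base
      cut_rel <- s_rel + 3L
      strand <- "-"
      L[llen - 2L] <- "C"; L[llen - 1L] <- "C"
    }
  }
  # stop microhomology extension exactly at m: flank base m+1 must differ
  # from the heterology's first base (or, for abutted copies, from the
  # copy's first base, so the rightmost equivalent representation is clean)
  if (d > 0L) {
    if (gg_forces_rest1) {
      if (H[1L] == "G") H[1L] <- other_base("G")
    } else {
      rest[1L] <- other_base(H[1L])
    }
  } else {
    if (gg_forces_rest1) {
      if (M[1L] == "G") M[1L] <- other_base("G")
    } else {
      rest[1L] <- other_base(M[1L])
    }
  }
  # block the other configuration and left-shifting
  del_last <- if (d > 0L) H[d] else M[m]
  L[llen] <- other_base(del_last)
  list(locus = paste(c(L, M, H, M, rest), collapse = ""),
       llen = llen, rlen = rlen, n = n,
       s_rel = s_rel, cut_rel = cut_rel, strand = strand)
}

#' Plant a deletion locus with known ground truth into a genome
#'
#' Writes a synthetic locus realizing `spec` into the genome (overwriting
#' existing sequence), then re-analyzes it with exact matching and verifies
#' that the analysis recovers exactly the planted microhomology length,
#' distance, configuration and (when planted) guide cut and nested
#' microhomology; on failure the locus is resampled. This rejection step
#' guards against accidentally longer microhomologies or extra structure
#' created by the random sequence.
#'
#' @param genome A `delmh_genome`.
#' @param spec A [plant_spec()].
#' @param chrom Target contig (default first).
#' @param pos 0-based canonical start of the deletion in the contig; `NULL`
#'   picks a random feasible position. The locus occupies
#'   `[pos - max(n,30), pos + n + max(n,30))`.
#' @param dup_pos Optional 0-based positions at which to write the
#'   off-target duplicate guide words (one per `offtarget_copies`); random
#'   non-overlapping far positions when `NULL`.
#' @param max_tries Resampling budget (default 200).
#' @return List with `genome` (modified), `variant` (one-row variant
#'   data.frame at the representation chosen by `spec$config`), and
#'   `truth`: `canonical_start`, `input_start`, `mh_len`, `mh_dist`,
#'   `config` (local configuration at the input representation),
#'   `cut_pos`, `strand`, `expect_valid_guide`, `expect_unique`,
#'   `expect_nested`.
#' @export
plant_variant <- function(genome, spec, chrom = names(genome$seq)[1L],
                          pos = NULL, dup_pos = NULL, max_tries = 200L) {
  clen <- contig_length(genome, chrom)
  m <- spec$mh_len
  n <- m + spec$mh_dist
  pad <- max(n + m, 30L)
  if (is.null(pos)) pos <- sample(seq(pad, clen - n - pad - 1L), 1L)
  if (pos < pad || pos + n + pad > clen)
    stop("pos leaves no room for the locus")
  exact <- delmh_params(max_mismatch = 0L, min_mh_len = min(3L, m))
  input_start <- if (spec$config == "OUTER_LEFT") pos + m else pos
  for (try in seq_len(max_tries)) {
    bl <- build_locus_right(spec)
    locus <- bl$locus
    Ltot <- nchar(locus)
    o <- pos - bl$s_rel
    cut_abs <- if (is.na(bl$cut_rel)) NA_integer_ else o + bl$cut_rel
    strand <- bl$strand
    sq <- genome$seq[[chrom]]
    substr(sq, o + 1L, o + Ltot) <- locus
    g2 <- genome
    g2$seq[[chrom]] <- sq
    v <- list(id = sprintf("planted_%s_%d", chrom, pos), chrom = chrom,
              start = input_start,
              deleted_seq = genome_fetch(g2, chrom, input_start, input_start + n),
              source = "synthetic", clin_sig = "")
    cv <- canonicalize_deletion(g2, v, exact)
    ok <- cv$variant$start == pos &&
      cv$shift_offset == pos - input_start &&
      cv$mh$mhL == m && cv$mh$dist == spec$mh_dist &&
      cv$mh$mismatches == 0L && cv$mh$config == "OUTER_RIGHT"
    if (ok && spec$config == "OUTER_LEFT") {
      # at the handed-over representation the same microhomology must read
      # in the OUTER_LEFT configuration
      both <- find_flanking_mh(g2, v, exact)
      sel <- select_configuration(both$OUTER_LEFT, both$OUTER_RIGHT)
      ok <- sel$config == "OUTER_LEFT" && sel$mhL == m &&
        sel$dist == spec$mh_dist
    }
    if (ok && spec$pam) {
      gd <- enumerate_guides(g2, cv, exact)
      hit <- gd[gd$cut_pos == cut_abs & gd$strand == strand & gd$valid, , drop = FALSE]
      ok <- nrow(hit) == 1L
      if (ok) {
        nn <- find_nested(g2, cv, cut_abs, 3L)
        ok <- if (spec$nested) nrow(nn) >= 1L else nrow(nn) == 0L
      }
    }
    if (!ok) next
    if (spec$offtarget_copies > 0L) {
      gd <- enumerate_guides(g2, cv, exact)
      hit <- gd[gd$cut_pos == cut_abs & gd$strand == strand, , drop = FALSE]
      word_span <- if (strand == "+") {
        c(hit$pam_start - nchar(hit$protospacer), hit$pam_start + nchar(hit$motif))
      } else {
        c(hit$pam_start, hit$pam_start + nchar(hit$motif) + nchar(hit$protospacer))
      }
      word <- genome_fetch(g2, chrom, word_span[1L], word_span[2L])
      wl <- nchar(word)
      if (is.null(dup_pos)) {
        grid <- seq(0L, clen - wl, by = wl + 7L)    # non-overlapping slots
        grid <- grid[grid + wl <= pos - pad | grid >= pos + n + pad]
        dup_pos <- sample(grid, spec$offtarget_copies)
      }
      sq2 <- g2$seq[[chrom]]
      for (dp in dup_pos) substr(sq2, dp + 1L, dp + wl) <- word
      g2$seq[[chrom]] <- sq2
      # duplicates must not disturb the planted locus itself
      cv2 <- canonicalize_deletion(g2, v, exact)
      if (!(cv2$variant$start == pos && cv2$mh$mhL == m &&
            cv2$mh$dist == spec$mh_dist)) next
    }
    truth <- list(canonical_start = pos, input_start = input_start,
                  mh_len = m, mh_dist = spec$mh_dist,
                  config = spec$config,
                  cut_pos = cut_abs, strand = strand,
                  expect_valid_guide = spec$pam,
                  expect_unique = spec$pam && spec$offtarget_copies == 0L,
                  expect_nested = spec$nested)
    vt <- new_variant_table(id = v$id, chrom = v$chrom, start = v$start,
                            deleted_seq = v$deleted_seq, source = v$source,
                            clin_sig = v$clin_sig)
    return(list(genome = g2, variant = vt, truth = truth))
  }
  stop("failed to plant spec after ", max_tries, " tries")
}

#' Monte Carlo background frequency of flanking microhomology
#'
#' Samples random deletion loci of length `del_len` from a uniform-base
#' random sequence and reports the fraction whose detected microhomology
#' reaches `min_mh` bp. Modes: `single_config_exact` tests one flanking
#' configuration with exact matching (the per-alignment probability, which
#' for `min_mh = del_len = k` has closed form `0.25^k`);
#' `both_config_exact` tests both configurations and selects the stronger;
#' `with_mismatch` additionally allows one absorbed mismatch.
#'
#' @param n_loci Number of simulated loci.
#' @param del_len Deletion length `k` (bp).
#' @param min_mh Minimum microhomology length to count a hit.
#' @param mode One of `"single_config_exact"`, `"both_config_exact"`,
#'   `"with_mismatch"`.
#' @param seed Optional integer seed.
#' @return List with `fraction`, `ci` (95% Clopper-Pearson), `hits`,
#'   `n_loci`.
#' @export
background_fraction <- function(n_loci, del_len, min_mh,
                                mode = c("single_config_exact",
                                         "both_config_exact",
                                         "with_mismatch"),
                                seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  k <- as.integer(del_len)
  block <- 3L * k
  S <- rand_dna(n_loci * block, gc = 0.5)
  offs <- (seq_len(n_loci) - 1L) * block
  inner <- substring(S, offs + 1L, offs + k)
  rflank <- substring(S, offs + k + 1L, offs + 2L * k)
  lflank <- substring(S, offs + 2L * k + 1L, offs + 3L * k)
  mm <- if (mode == "with_mismatch") 1L else 0L
  hits <- 0L
  for (i in seq_len(n_loci)) {
    r <- extend_microhomology(inner[i], rflank[i], max_mismatch = mm)
    mhL <- r$mhL
    if (mode != "single_config_exact") {
      l <- extend_microhomology(rev_str(inner[i]), rev_str(lflank[i]),
                                max_mismatch = mm)
      if (l$score > r$score || (l$score == r$score && l$mh1L >= r$mh1L))
        mhL <- l$mhL
    }
    if (mhL >= min_mh) hits <- hits + 1L
  }
  ci <- as.numeric(stats::binom.test(hits, n_loci)$conf.int)
  list(fraction = hits / n_loci, ci = ci, hits = hits, n_loci = n_loci)
}

#' PAM availability for abutted microhomology deletions
#'
#' For a deletion with directly abutted microhomology copies, a single cut
#' position is permissive per side and requires `GG` at two fixed offsets
#' next to the deletion. Under uniform base composition the per-side
#' probability is `(1/4)^2`; the additive two-side approximation doubles
#' it; inclusion-exclusion gives the exact at-least-one-side probability.
#'
#' @return List with `per_side` (0.0625), `additive` (0.125), and
#'   `at_least_one_side` (`1 - (15/16)^2`).
#' @export
pam_availability <- function() {
  p_side <- (1 / 4)^2
  list(per_side = p_side,
       additive = 2 * p_side,
       at_least_one_side = 1 - (1 - p_side)^2)
}

#' Plant a cohort of specifications into one genome
#'
#' Each specification gets its own block of the genome; off-target
#' duplicate guide words are written into a reserved tail region so loci
#' never interfere with one another.
#'
#' @param specs List of [plant_spec()] objects.
#' @param block Block size per locus in bp (default 400).
#' @param tail_per_dup Reserved bp per off-target duplicate (default 40).
#' @param seed Optional integer seed.
#' @return List with `genome`, `variants` (data.frame, one row per spec)
#'   and `truths` (list of truth records).
#' @export
plant_cohort <- function(specs, block = 400L, tail_per_dup = 40L,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(specs)
  ndup <- sum(vapply(specs, function(s) s$offtarget_copies, integer(1L)))
  glen <- n * block + ndup * tail_per_dup + 400L
  g <- make_genome(glen)
  variants <- vector("list", n)
  truths <- vector("list", n)
  dup_cursor <- n * block + 200L
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    pos <- (i - 1L) * block + 200L
    dp <- NULL
    if (sp$offtarget_copies > 0L) {
      dp <- dup_cursor + (seq_len(sp$offtarget_copies) - 1L) * tail_per_dup
      dup_cursor <- dup_cursor + sp$offtarget_copies * tail_per_dup
    }
    pv <- plant_variant(g, sp, pos = pos, dup_pos = dp)
    g <- pv$genome
    variants[[i]] <- pv$variant
    truths[[i]] <- pv$truth
  }
  list(genome = g, variants = do.call(rbind, variants), truths = truths)
}

#' Draw random plant specifications
#'
#' Covers both reporting representations, microhomology lengths 3-7,
#' heterology distances 0-15, planted NGG guides everywhere, nested
#' microhomologies on half of the wide-heterology loci, and off-target
#' duplicated guide words on ~15% of loci.
#'
#' @param n Number of specifications.
#' @return List of [plant_spec()] objects.
#' @export
random_plant_specs <- function(n) {
  lapply(seq_len(n), function(i) {
    m <- sample(3:7, 1L)
    d <- sample(c(0L, 1L, 2L, 3L, 5L, 8L, 10L, 12L, 15L), 1L)
    config <- if (d > 0L && stats::runif(1) < 0.5) "OUTER_LEFT" else "OUTER_RIGHT"
    nested <- d >= 10L && stats::runif(1) < 0.5
    dup <- if (stats::runif(1) < 0.15) sample(1:2, 1L) else 0L
    plant_spec(m, d, config, pam = TRUE, nested = nested,
               offtarget_copies = dup)
  })
}
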