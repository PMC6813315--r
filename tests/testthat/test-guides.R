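test_that("PAM scanning matches exhaustive IUPAC scan on both strands", {
  g <- new_genome(c(c1 = "AAGGT"))
  hits <- scan_pams(g, "c1", 0, 5, "NGG")
  plus <- hits[hits$strand == "+", ]
  expect_equal(plus$pam_start, 1L)          # AGG only; GGT fails
  # CCA on the plus strand is an NGG match on the minus strand
  g2 <- new_genome(c(c1 = "TCCAT"))
  hits2 <- scan_pams(g2, "c1", 0, 5, "NGG")
  expect_equal(hits2[hits2$strand == "-", ]$pam_start, 1L)
  # literal motifs match only themselves
  g3 <- new_genome(c(c1 = "GATGAAGGT"))
  expect_equal(scan_pams(g3, "c1", 0, 9, "GAT")[, "strand"] == "+",
               c(TRUE))
})

test_that("PAM scanning equals the position-by-position oracle on fuzzed windows", {
  set.seed(41)
  motifs <- c("NGG", "NG", "GAA", "GAT", "NGN", "NRG")
  for (i in 1:300) {
    win <- random_seq(sample(5:60, 1L), c(BASES, "N"))
    g <- new_genome(c(w = win))
    mo <- sample(motifs, 1L)
    got <- scan_pams(g, "w", 0, nchar(win), mo)
    expect_equal(sort(got[got$strand == "+", "pam_start"]),
                 sort(oracle_motif_starts(win, mo)),
                 info = paste(win, mo))
    expect_equal(sort(got[got$strand == "-", "pam_start"]),
                 sort(oracle_motif_starts(win, revcomp(mo))),
                 info = paste(win, mo, "minus"))
  }
})

test_that("blunt cut sits 3 bp upstream of the PAM on either strand", {
  expect_equal(cut_position("NGG", "+", 100L), 97L)
  expect_equal(cut_position("NGG", "-", 100L), 106L)
  expect_equal(cut_position("NG", "-", 100L), 105L)
  expect_equal(cut_position("GAA", "+", 50L), 47L)
})

test_that("guide enumeration applies the positional constraints on a hand fixture", {
  # deletion [30,35)="ATCGG" with identical right flank and a CGG PAM at
  # [37,40): cut at 34, inside the valid window [33, 35]
  set.seed(42)
  g <- make_genome(200)
  sq <- g$seq[["chr1"]]
  substr(sq, 31, 45) <- "ATCGGATCGGTTTTT"
  substr(sq, 26, 30) <- "CCACC"   # left flank: blocks OUTER_LEFT/left shift
  g$seq[["chr1"]] <- sq
  v <- list(id = "fx", chrom = "chr1", start = 30L, deleted_seq = "ATCGG")
  cv <- canonicalize_deletion(g, v)
  expect_equal(cv$mh$mhL, 5L)
  expect_equal(cv$mh$config, "OUTER_RIGHT")
  gd <- enumerate_guides(g, cv)
  plus <- gd[gd$strand == "+" & gd$pam_start == 37L, ]
  expect_equal(plus$cut_pos, 34L)
  expect_true(plus$valid)
  expect_equal(plus$pam, "CGG")
  expect_equal(plus$dist_left, 0L)   # cut inside the inner copy
  expect_equal(plus$dist_right, 1L)
  # the protected window: cuts at s+1, s+2 would leave < 3 bp of the inner
  # copy on the PAM-distal side
  expect_true(all(gd$cut_pos[gd$valid] >= 33L))
  expect_true(all(gd$cut_pos[gd$valid] <= 35L))
})

test_that("emitted protospacer and PAM text match the genome at their coordinates", {
  set.seed(43)
  specs <- lapply(1:12, function(i) {
    plant_spec(sample(3:6, 1L), sample(c(0:3, 8L), 1L), pam = TRUE)
  })
  co <- plant_cohort(specs)
  g <- co$genome
  for (r in seq_len(nrow(co$variants))) {
    cv <- canonicalize_deletion(g, as.list(co$variants[r, ]))
    gd <- enumerate_guides(g, cv)
    for (i in seq_len(nrow(gd))) {
      ml <- nchar(gd$motif[i]); pl <- nchar(gd$protospacer[i])
      if (gd$strand[i] == "+") {
        expect_equal(gd$protospacer[i],
                     genome_fetch(g, gd$chrom[i], gd$pam_start[i] - pl,
                                  gd$pam_start[i]))
        expect_equal(gd$pam[i],
                     genome_fetch(g, gd$chrom[i], gd$pam_start[i],
                                  gd$pam_start[i] + ml))
      } else {
        expect_equal(gd$protospacer[i],
                     revcomp(genome_fetch(g, gd$chrom[i], gd$pam_start[i] + ml,
                                          gd$pam_start[i] + ml + pl)))
        expect_equal(gd$pam[i],
                     revcomp(genome_fetch(g, gd$chrom[i], gd$pam_start[i],
                                          gd$pam_start[i] + ml)))
      }
      # the PAM text itself matches the motif
      expect_match(gd$pam[i], paste0("^", delmh:::iupac_regex(gd$motif[i]), "$"))
    }
  }
})

test_that("enumeration is complete: a brute-force window scan finds the same cuts", {
  set.seed(44)
  specs <- lapply(1:10, function(i) {
    plant_spec(sample(3:5, 1L), sample(0:6, 1L), pam = TRUE)
  })
  co <- plant_cohort(specs)
  g <- co$genome
  for (r in seq_len(nrow(co$variants))) {
    v <- as.list(co$variants[r, ])
    cv <- canonicalize_deletion(g, v)
    gd <- enumerate_guides(g, cv)
    s <- cv$variant$start; n <- nchar(cv$variant$deleted_seq)
    # oracle: every PAM whose cut lies in [s, s+n], found by scanning a
    # generous window base by base
    win_s <- s - 30L; win_e <- s + n + 30L
    win <- genome_fetch(g, v$chrom, win_s, win_e)
    plus <- oracle_motif_starts(win, "NGG") + win_s
    minus <- oracle_motif_starts(win, revcomp("NGG")) + win_s
    cuts <- c(plus - 3L, minus + 3L + 3L)
    strands <- c(rep("+", length(plus)), rep("-", length(minus)))
    keep <- cuts >= s & cuts <= s + n
    want <- sort(paste(cuts[keep], strands[keep]))
    got <- sort(paste(gd$cut_pos, gd$strand))
    expect_equal(got, want)
  }
})

test_that("guide enumeration is strand-symmetric under genome reverse complement", {
  # the enumeration is compared at mirrored *representations*: the
  # canonicalization tie-break (leftmost) is direction-dependent by design,
  # so the mirrored variant is analyzed at the mirror of the original
  # canonical representation, where the configuration label flips
  set.seed(45)
  specs <- lapply(1:10, function(i) {
    plant_spec(sample(3:6, 1L), sample(0:8, 1L), pam = TRUE)
  })
  co <- plant_cohort(specs)
  g <- co$genome
  rc <- revcomp_genome(g)
  L <- g$lengths[["chr1"]]
  flip <- c(OUTER_RIGHT = "OUTER_LEFT", OUTER_LEFT = "OUTER_RIGHT")
  for (r in seq_len(nrow(co$variants))) {
    v <- as.list(co$variants[r, ])
    cv <- canonicalize_deletion(g, v)
    s <- cv$variant$start; n <- nchar(cv$variant$deleted_seq)
    vm <- list(id = v$id, chrom = v$chrom, start = L - s - n,
               deleted_seq = revcomp(cv$variant$deleted_seq))
    fmm <- find_flanking_mh(rc, vm)
    mhm <- fmm[[flip[[cv$mh$config]]]]
    mhm$no_mh <- mhm$mhL == 0L
    cvm <- list(variant = vm, shift_offset = 0L, mh = mhm)
    gd <- enumerate_guides(g, cv)
    gdm <- enumerate_guides(rc, cvm)
    key <- function(df, mirror = FALSE) {
      cuts <- if (mirror) L - df$cut_pos else df$cut_pos
      strands <- if (mirror) ifelse(df$strand == "+", "-", "+") else df$strand
      dl <- if (mirror) df$dist_right else df$dist_left
      dr <- if (mirror) df$dist_left else df$dist_right
      sort(paste(cuts, strands, df$protospacer, df$pam, dl, dr, df$valid))
    }
    expect_equal(key(gdm, mirror = TRUE), key(gd))
  }
})

test_that("the 50-bp cut-distance rule drops remote cuts but keeps two-cut designs", {
  # large deletion with microhomology at both ends: cuts near either copy
  # survive with the nearer-copy rule, interior remote cuts are dropped
  set.seed(46)
  co <- plant_cohort(list(plant_spec(4, 120)), block = 800L)
  g <- co$genome
  v <- as.list(co$variants[1L, ])
  cv <- canonicalize_deletion(g, v)
  gd <- enumerate_guides(g, cv)
  if (nrow(gd)) {
    near <- pmin(gd$dist_left, gd$dist_right)
    expect_true(all(near[gd$valid] <= 50L))
    far <- gd[!gd$valid & gd$cut_pos > v$start + 3L &
                gd$cut_pos < v$start + v$del_len - 3L, ]
    if (nrow(far)) expect_true(all(pmin(far$dist_left, far$dist_right) > 50L))
  }
  strict <- enumerate_guides(g, cv, delmh_params(require_both_within = TRUE))
  expect_true(all(pmax(strict$dist_left, strict$dist_right)[strict$valid] <= 50L))
})
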