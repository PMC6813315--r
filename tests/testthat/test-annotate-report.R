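write_gff3 <- function(lines, path) {
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

test_that("GFF3 1-based closed features convert to 0-based half-open spans", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_gff3("c1\tsrc\tCDS\t11\t20\t.\t+\t0\tID=cds1", gff)
  ann <- load_annotation(gff)
  expect_equal(GenomicRanges::start(ann), 11L)  # GRanges stays 1-based closed
  expect_equal(GenomicRanges::end(ann), 20L)
  # variant [12,15) overlaps [10,20); variant [20,23) does not (half-open)
  expect_equal(classify_context(list(chrom = "c1", start = 12L, del_len = 3L), ann),
               "exonic")
  expect_equal(classify_context(list(chrom = "c1", start = 20L, del_len = 3L), ann),
               "intergenic")
  # adjacent on the left edge: [8,10) does not overlap, [9,11) does
  expect_equal(classify_context(list(chrom = "c1", start = 8L, del_len = 2L), ann),
               "intergenic")
  expect_equal(classify_context(list(chrom = "c1", start = 9L, del_len = 2L), ann),
               "exonic")
})

test_that("genic context precedence is CDS > UTR > exon > gene > intergenic", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(c(
    "c1\tsrc\tgene\t1\t100\t.\t+\t.\tID=g1",
    "c1\tsrc\texon\t10\t30\t.\t+\t.\tID=e1",
    "c1\tsrc\tCDS\t15\t25\t.\t+\t0\tID=c1",
    "c1\tsrc\tfive_prime_UTR\t10\t14\t.\t+\t.\tID=u1"), gff)
  ann <- load_annotation(gff)
  ctx <- function(s, n) classify_context(list(chrom = "c1", start = s, del_len = n), ann)
  expect_equal(ctx(16L, 3L), "exonic")     # CDS + exon + gene
  expect_equal(ctx(10L, 2L), "UTR")        # UTR + exon + gene, no CDS
  expect_equal(ctx(40L, 3L), "intronic")   # gene only
  # spanning CDS and intron counts as exonic (any overlap, precedence)
  expect_equal(ctx(20L, 15L), "exonic")
})

test_that("variants outside all genes are intergenic and NULL annotation is tolerated", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_gff3("c1\tsrc\tgene\t1\t100\t.\t+\t.\tID=g1", gff)
  ann <- load_annotation(gff)
  expect_equal(classify_context(list(chrom = "c1", start = 150L, del_len = 3L), ann),
               "intergenic")
  expect_equal(classify_context(list(chrom = "c2", start = 10L, del_len = 3L), ann),
               "intergenic")
  expect_equal(classify_context(list(chrom = "c1", start = 10L, del_len = 3L), NULL),
               "intergenic")
})

test_that("BED-like annotation with a type column loads with exact coordinates", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("c1\t10\t20\tcds1\t0\t+\tCDS", bed)
  ann <- load_annotation(bed)
  expect_equal(GenomicRanges::start(ann), 11L)
  expect_equal(GenomicRanges::end(ann), 20L)
  expect_equal(classify_context(list(chrom = "c1", start = 19L, del_len = 1L), ann),
               "exonic")
  expect_equal(classify_context(list(chrom = "c1", start = 20L, del_len = 1L), ann),
               "intergenic")
})

test_that("unknown feature types are dropped with a warning", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(c("c1\tsrc\tCDS\t1\t10\t.\t+\t0\tID=a",
               "c1\tsrc\tenhancer\t20\t30\t.\t+\t.\tID=b"), gff)
  expect_warning(ann <- load_annotation(gff), "unknown type")
  expect_length(ann, 1L)
})

test_that("classification agrees with a per-base overlap check", {
  set.seed(71)
  gff <- withr::local_tempfile(fileext = ".gff3")
  f_start1 <- 21L; f_end1 <- 40L     # 1-based closed in the GFF
  write_gff3(sprintf("c1\tsrc\tCDS\t%d\t%d\t.\t+\t0\tID=x", f_start1, f_end1), gff)
  ann <- load_annotation(gff)
  for (i in 1:80) {
    s <- sample(0:60, 1L); n <- sample(1:6, 1L)
    want <- oracle_overlaps(s, s + n, f_start1 - 1L, f_end1)
    got <- classify_context(list(chrom = "c1", start = s, del_len = n), ann)
    expect_equal(got == "exonic", want, info = paste(s, n))
  }
})

test_that("frameshift requires a coding context and non-multiple-of-3 length", {
  expect_true(is_frameshift(4L, "exonic"))
  expect_false(is_frameshift(3L, "exonic"))
  expect_false(is_frameshift(4L, "intronic"))
  expect_false(is_frameshift(5L, "intergenic"))
  expect_true(is_frameshift(5L, "exonic"))
})

test_that("clinical-significance classification uses word-boundary matching", {
  expect_equal(clin_category("Likely pathogenic"), "pathogenic")
  expect_equal(clin_category("Pathogenic/Likely pathogenic"), "pathogenic")
  expect_equal(clin_category("Conflicting interpretations of pathogenicity"),
               "VUS/other")
  expect_equal(clin_category("Benign"), "benign")
  expect_equal(clin_category("Likely benign;Uncertain significance"), "benign")
  expect_equal(clin_category(""), "none")
  expect_equal(clin_category(character(0)), "none")
  expect_equal(clin_category("Uncertain significance"), "VUS/other")
  # substring mode absorbs 'pathogenicity' as the looser reading would
  expect_equal(clin_category("Conflicting interpretations of pathogenicity",
                             substring = TRUE), "pathogenic")
  # pathogenic wins over benign when both appear across labels
  expect_equal(clin_category("Benign;Pathogenic"), "pathogenic")
})

test_that("filter cascade is conjunctive, monotone, and reports the funnel", {
  set.seed(72)
  specs <- c(lapply(1:6, function(i) plant_spec(sample(3:5, 1L), sample(0:4, 1L), pam = TRUE)),
             lapply(1:4, function(i) plant_spec(2, 3)))   # short microhomology
  co <- plant_cohort(specs)
  res <- delmh_run(co$genome, co$variants)
  flt <- apply_filters(res$variants, list(min_del_len = 3L, min_mh_len = 3L))
  funnel <- attr(flt, "funnel")
  expect_equal(funnel$n[1L], 10L)
  expect_true(all(diff(funnel$n) <= 0L))
  # six variants were planted with microhomology >= 3
  expect_equal(funnel$n[nrow(funnel)], 6L)
  # no criteria: identity
  ident <- apply_filters(res$variants, list())
  expect_equal(nrow(ident), nrow(res$variants))
  # unique-guide requirement keeps only variants with a unique guide
  flt2 <- apply_filters(res$variants, list(min_mh_len = 3L,
                                           require_unique_guide = TRUE))
  expect_true(all(flt2$n_unique_guides > 0L))
})

test_that("reports are deterministic, referentially intact, and survive empty input", {
  set.seed(73)
  specs <- lapply(1:5, function(i) plant_spec(sample(3:4, 1L), sample(0:3, 1L), pam = TRUE))
  co <- plant_cohort(specs)
  res <- delmh_run(co$genome, co$variants)
  d1 <- withr::local_tempdir()
  p1 <- file.path(d1, "a"); p2 <- file.path(d1, "b")
  write_reports(res, p1)
  write_reports(res, p2)
  for (suffix in c("-variants.tsv", "-guides.tsv")) {
    expect_identical(readLines(paste0(p1, suffix)),
                     readLines(paste0(p2, suffix)))
  }
  guides <- utils::read.delim(paste0(p1, "-guides.tsv"))
  variants <- utils::read.delim(paste0(p1, "-variants.tsv"))
  expect_true(all(guides$variant_id %in% variants$id))
  expect_true(file.exists(paste0(p1, "-summary.json")))
  js <- jsonlite::read_json(paste0(p1, "-summary.json"))
  expect_equal(js$n_variants, nrow(variants))
  # empty input: header-only TSVs, valid summary
  res0 <- delmh_run(co$genome, co$variants[0, ])
  p0 <- file.path(d1, "empty")
  write_reports(res0, p0)
  expect_length(readLines(paste0(p0, "-guides.tsv")), 1L)
})

test_that("variant-level guide counts are non-increasing along the cascade", {
  set.seed(74)
  specs <- lapply(1:8, function(i) {
    plant_spec(sample(3:6, 1L), sample(c(0:4, 10L, 12L), 1L), pam = TRUE,
               nested = FALSE, offtarget_copies = sample(0:1, 1L))
  })
  co <- plant_cohort(specs)
  res <- delmh_run(co$genome, co$variants)
  v <- res$variants
  expect_true(all(v$n_pam_candidates >= v$n_valid_guides))
  expect_true(all(v$n_valid_guides >= v$n_unique_guides))
  expect_true(all(v$n_unique_guides >= v$n_guides_no_nested))
})
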