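write_test_vcf <- function(lines) {
  path <- withr::local_tempfile(fileext = ".vcf",
                                .local_envir = parent.frame())
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           "NA1\tNA2\tNA3")
  )
  writeLines(c(header, lines), path)
  path
}

test_that("read_vcf converts GT fields to ALT dosages and keeps missing calls", {
  path <- write_test_vcf(c(
    "22\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "22\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t0|0\t./.\t1/1"
  ))
  g <- read_vcf(path)
  expect_s3_class(g, "genotype_matrix")
  expect_equal(unname(g$dosages[, "rs1"]), c(0L, 1L, 2L))
  expect_equal(unname(g$dosages[, "rs2"]), c(0L, NA_integer_, 2L))
  expect_equal(g$variants$pos_bp, c(100L, 200L))
  expect_equal(g$sample_ids, c("NA1", "NA2", "NA3"))
})

test_that("multi-allelic sites are dropped with a reported count", {
  path <- write_test_vcf(c(
    "22\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "22\t150\trs_tri\tA\tG,T\t.\tPASS\t.\tGT\t0/0\t0/1\t0/2",
    "22\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t0/0\t0/0\t1/1"
  ))
  expect_message(g <- read_vcf(path), "1 multi-allelic")
  expect_equal(g$variants$id, c("rs1", "rs2"))
})

test_that("region restriction keeps only in-range variants and warns when empty", {
  path <- write_test_vcf(c(
    "22\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "22\t900\trs2\tC\tT\t.\tPASS\t.\tGT\t0/0\t0/0\t1/1"
  ))
  g <- read_vcf(path, region = "22:50-500")
  expect_equal(g$variants$id, "rs1")
  expect_warning(g2 <- read_vcf(path, region = "21:1-100"), "no variants")
  expect_equal(n_snps(g2), 0L)
  expect_error(read_vcf(path, region = "chr22"), "chrom:start-end")
})

test_that("additive_recode flips majority-ALT columns and records MAF", {
  # ALT freq 5/6 > 0.5 -> flipped to minor-allele counts
  g <- make_gm(cbind(a = c(2L, 2L, 1L), b = c(0L, 1L, 2L)), recode = FALSE)
  r <- additive_recode(g)
  expect_equal(unname(r$dosages[, 1]), c(0L, 0L, 1L))
  expect_equal(r$variants$minor_allele[1], "ref")
  expect_equal(r$variants$maf[1], 1 / 6)
  # ALT freq exactly 0.5 -> kept as ALT
  expect_equal(unname(r$dosages[, 2]), c(0L, 1L, 2L))
  expect_equal(r$variants$minor_allele[2], "alt")
  expect_equal(r$variants$maf[2], 0.5)
})

test_that("additive_recode leaves all-zero columns alone and is idempotent", {
  g <- make_gm(cbind(c(0L, 0L, 0L), c(2L, 1L, 2L)), recode = FALSE)
  r1 <- additive_recode(g)
  expect_equal(unname(r1$dosages[, 1]), c(0L, 0L, 0L))
  expect_equal(r1$variants$maf[1], 0)
  r2 <- additive_recode(r1)
  expect_identical(r2$dosages, r1$dosages)
  expect_identical(r2$variants$maf, r1$variants$maf)
})

test_that("filter_maf is strict at the threshold", {
  # 50 samples, one heterozygote: maf exactly 0.01 -> removed
  dos <- cbind(het1 = c(1L, rep(0L, 49)), common = rep(c(0L, 1L), 25))
  g <- additive_recode(make_gm(dos, recode = FALSE))
  f <- filter_maf(g, 0.01)
  expect_equal(f$variants$id, "s002")
  expect_equal(attr(f, "n_removed"), 1L)
  # monomorphic columns always go
  g2 <- additive_recode(make_gm(cbind(rep(0L, 10), rep(1L, 10)), recode = FALSE))
  expect_equal(n_snps(filter_maf(g2)), 1L)
  expect_error(filter_maf(g, 0.5), "0, 0.5")
  expect_error(filter_maf(g, -0.1), "0, 0.5")
})

test_that("filter_missing removes any variant with a missing call", {
  dos <- cbind(c(NA_integer_, rep(0L, 9)), rep(1L, 10), rep(c(0L, 2L), 5))
  g <- make_gm(dos, recode = FALSE)
  f <- filter_missing(g)
  expect_equal(n_snps(f), 2L)
  expect_false(anyNA(f$dosages))
  g_all_na <- make_gm(matrix(NA_integer_, 4, 2), recode = FALSE)
  expect_warning(f2 <- filter_missing(g_all_na), "empty")
  expect_equal(n_snps(f2), 0L)
})

test_that("the filter chain leaves minor-allele columns in (threshold, 0.5] and preserves order", {
  set.seed(41)
  dos <- matrix(sample(c(0:2, NA), 400, TRUE, prob = c(0.5, 0.3, 0.18, 0.02)),
                20, 20)
  g <- make_gm(dos, recode = FALSE)
  out <- filter_maf(additive_recode(filter_missing(g)), 0.01)
  expect_true(all(out$dosages %in% 0:2))
  expect_true(all(out$variants$maf > 0.01 & out$variants$maf <= 0.5))
  freqs <- colMeans(out$dosages) / 2
  expect_true(all(freqs <= 0.5))
  # order stability: kept ids appear in their original relative order
  expect_identical(out$variants$id,
                   g$variants$id[g$variants$id %in% out$variants$id])
})

test_that("dosage matrix round-trips through TSV + manifest", {
  dos <- matrix(sample(0:2, 60, TRUE), 10, 6)
  g <- additive_recode(make_gm(dos, recode = FALSE))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dosage_matrix(g, path)
  g2 <- read_dosage_matrix(path)
  expect_equal(g2$dosages, g$dosages)
  expect_equal(as.data.frame(g2$variants), as.data.frame(g$variants))
  expect_equal(g2$sample_ids, g$sample_ids)
})

test_that("tampered manifest fails the integrity check", {
  g <- additive_recode(make_gm(matrix(sample(0:2, 30, TRUE), 10, 3),
                               recode = FALSE))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dosage_matrix(g, path)
  mp <- paste0(path, ".manifest.json")
  manifest <- jsonlite::read_json(mp, simplifyVector = TRUE)
  manifest$n_snps <- 99
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE)
  expect_error(read_dosage_matrix(path), "integrity")
})

test_that("writing a matrix with missing entries is refused", {
  g <- make_gm(cbind(c(0L, NA_integer_), c(1L, 2L)), recode = FALSE)
  expect_error(write_dosage_matrix(g, tempfile()), "missing")
})
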