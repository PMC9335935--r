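test_that("VCF genotypes map by unphased allele content", {
  sheet <- sample_sheet(c("m1", "f1"), c("picta", "picta"), c("M", "F"))
  vcf <- write_toy_vcf(withr::local_tempfile(fileext = ".vcf"), c(
    "chr1\t100\t.\tA\tT\t50\tPASS\t.\tGT:DP\t0/1:12\t0/0:9",
    "chr1\t200\t.\tG\tC\t50\tPASS\t.\tGT:DP\t1/0:7\t1|1:20",
    "chr1\t300\t.\tT\tA\t50\tPASS\t.\tGT:DP\t./.:0\t0/1:15"))
  gt <- read_vcf(vcf, sheet)
  expect_equal(nrow(gt$sites), 3)
  expect_equal(unname(gt$geno[, "m1"]), c(1L, 1L, NA))   # 1/0 is het too
  expect_equal(unname(gt$geno[, "f1"]), c(0L, 2L, 1L))   # 1|1 phased hom-alt
  expect_equal(unname(gt$depth[, "m1"]), c(12L, 7L, 0L))
  expect_equal(gt$sites$pos, c(100L, 200L, 300L))
})

test_that("sample order follows the sheet, not the VCF header", {
  vcf <- write_toy_vcf(withr::local_tempfile(fileext = ".vcf"), c(
    "chr1\t100\t.\tA\tT\t50\tPASS\t.\tGT:DP\t0/1:10\t1/1:11"),
    samples = c("a", "b"))
  sheet_ab <- sample_sheet(c("a", "b"), rep("picta", 2), c("M", "F"))
  sheet_ba <- sample_sheet(c("b", "a"), rep("picta", 2), c("F", "M"))
  gt_ab <- read_vcf(vcf, sheet_ab)
  gt_ba <- read_vcf(vcf, sheet_ba)
  expect_equal(colnames(gt_ba$geno), c("b", "a"))
  expect_equal(gt_ba$geno[, "a"], gt_ab$geno[, "a"])
  expect_equal(gt_ba$geno[, "b"], gt_ab$geno[, "b"])
})

test_that("write_vcf / read_vcf round-trips a simulated table exactly", {
  cfg <- scenario_config("independent", n_sdr_sites = 60, n_par_sites = 30,
                         n_auto_sites = 30, eps = 0.05, seed = 21)
  b <- simulate_scenario(cfg)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(b$genotypes, path)
  back <- read_vcf(path, b$sheet)
  expect_identical(back$geno, b$genotypes$geno)
  expect_identical(back$depth, b$genotypes$depth)
  expect_equal(back$sites, b$genotypes$sites, ignore_attr = TRUE)
})

test_that("missing genotypes survive a round trip as ./.", {
  geno <- matrix(c(0L, NA, 1L, 2L), 2, 2,
                 dimnames = list(NULL, c("m1", "f1")))
  gt <- toy_table(geno)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gt, path)
  expect_true(any(grepl("\\./\\.", readLines(path))))
  sheet <- sample_sheet(c("m1", "f1"), c("picta", "picta"), c("M", "F"))
  back <- read_vcf(path, sheet)
  expect_identical(back$geno, gt$geno)
})

test_that("an empty table writes a header-only VCF", {
  gt <- genotype_table(
    data.frame(chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0), qual = numeric(0)),
    matrix(integer(0), 0, 2, dimnames = list(NULL, c("m1", "f1"))))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gt, path)
  lines <- readLines(path)
  expect_match(lines[length(lines)], "^#CHROM")
})

test_that("configuration and format errors are raised", {
  vcf <- write_toy_vcf(withr::local_tempfile(fileext = ".vcf"), c(
    "chr1\t100\t.\tA\tT\t50\tPASS\t.\tGT:DP\t0/1:10\t0/0:11"))
  sheet_bad <- sample_sheet(c("m1", "zz"), rep("picta", 2), c("M", "F"))
  expect_error(read_vcf(vcf, sheet_bad), "absent from VCF")
  no_gt <- write_toy_vcf(withr::local_tempfile(fileext = ".vcf"), c(
    "chr1\t100\t.\tA\tT\t50\tPASS\t.\tDP\t10\t11"))
  sheet <- sample_sheet(c("m1", "f1"), rep("picta", 2), c("M", "F"))
  expect_error(read_vcf(no_gt, sheet))
})

test_that("sample sheets validate ids, species and sex codes", {
  expect_error(sample_sheet(c("a", "a"), rep("picta", 2), c("M", "F")),
               "duplicated")
  expect_error(sample_sheet("a", "swordtail", "M"), "unknown species")
  expect_error(sample_sheet("a", "picta", "male"), "unknown sex")
  path <- withr::local_tempfile(fileext = ".tsv")
  sheet <- sample_sheet(c("a", "b"), c("picta", "wingei"), c("M", "F"))
  write_sample_sheet(sheet, path)
  expect_equal(read_sample_sheet(path)$species, c("picta", "wingei"))
})
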