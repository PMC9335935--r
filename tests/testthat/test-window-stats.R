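test_that("windows tile the chromosome half-open with a short tail", {
  w <- make_windows(c(chrA = 2.5e4), 1e4)
  expect_equal(w$start, c(0, 1e4, 2e4))
  expect_equal(w$end, c(1e4, 2e4, 2.5e4))
  expect_equal(w$end - w$start, c(1e4, 1e4, 5e3))
})

test_that("depth ratios normalise away library-size differences", {
  sheet <- sample_sheet(c("m1", "m2", "f1"), rep("picta", 3),
                        c("M", "M", "F"))
  win <- data.frame(chrom = c("chrX", "chr1"), start = 0, end = 1e4)
  mk <- function(dx, da) data.frame(
    chrom = c("chrX", "chr1"), start = 0, end = 1e4, depth = c(dx, da))
  # equal depth everywhere: ratio 1
  d <- do.call(rbind, Map(function(s, dx, da) cbind(mk(dx, da), sample_id = s),
                          c("m1", "m2", "f1"), c(30, 30, 30), c(30, 30, 30)))
  r <- depth_ratio_windows(d, sheet, autosomes = "chr1")
  expect_equal(r$depth_ratio[r$chrom == "chrX"], 1)
  # males at half coverage on chrX: 0.5
  d <- do.call(rbind, Map(function(s, dx, da) cbind(mk(dx, da), sample_id = s),
                          c("m1", "m2", "f1"), c(15, 15, 30), c(30, 30, 30)))
  r <- depth_ratio_windows(d, sheet, autosomes = "chr1")
  expect_equal(r$depth_ratio[r$chrom == "chrX"], 0.5)
  # unequal male library sizes but proportional windows: still 1 after
  # normalisation (20/20 and 40/40 both normalise to 1)
  d <- do.call(rbind, Map(function(s, dx, da) cbind(mk(dx, da), sample_id = s),
                          c("m1", "m2", "f1"), c(20, 40, 30), c(20, 40, 30)))
  r <- depth_ratio_windows(d, sheet, autosomes = "chr1")
  expect_equal(r$depth_ratio[r$chrom == "chrX"], 1)
  # raw mode would disagree for the same input
  r_raw <- depth_ratio_windows(d, sheet, autosomes = "chr1",
                               normalize = FALSE)
  expect_equal(r_raw$depth_ratio[r_raw$chrom == "chrX"], 1)  # (20+40)/2 / 30
})

test_that("a zero female mean gives an undefined ratio with a warning", {
  sheet <- sample_sheet(c("m1", "f1"), rep("picta", 2), c("M", "F"))
  d <- data.frame(chrom = rep(c("chrX", "chr1"), 2),
                  start = 0, end = 1e4,
                  sample_id = rep(c("m1", "f1"), each = 2),
                  depth = c(30, 30, 0, 30))
  expect_warning(r <- depth_ratio_windows(d, sheet, autosomes = "chr1"),
                 "undefined")
  expect_true(is.na(r$depth_ratio[r$chrom == "chrX"]))
})

test_that("SNP density ratio counts polymorphism within each sex", {
  sheet <- sample_sheet(c("m1", "m2", "f1", "f2"), rep("picta", 4),
                        c("M", "M", "F", "F"))
  # 9 sites: 5 polymorphic in males only, 4 in both sexes
  geno <- rbind(
    matrix(rep(c(0L, 1L, 0L, 0L), 5), 5, 4, byrow = TRUE),
    matrix(rep(c(0L, 1L, 0L, 1L), 4), 4, 4, byrow = TRUE))
  colnames(geno) <- sheet$sample_id
  gt <- toy_table(geno)
  win <- make_windows(c(chr1 = 1000), 1000)
  r <- snp_density_ratio_windows(gt, sheet, win)
  expect_equal(r$n_male_poly, 9L)
  expect_equal(r$n_female_poly, 4L)
  expect_equal(r$snp_density_ratio, 9 / 4)
  # female-monomorphic window is undefined, not zero or infinite
  gt2 <- toy_table(matrix(c(0L, 1L, 0L, 0L), 1, 4,
                          dimnames = list(NULL, sheet$sample_id)))
  r2 <- snp_density_ratio_windows(gt2, sheet, win)
  expect_true(is.na(r2$snp_density_ratio))
})

test_that("male and female SNP densities balance in recombining regions", {
  cfg <- scenario_config("autosome", n_par_sites = 0, n_auto_sites = 3000,
                         autosomes = c(chr1 = 2e7), seed = 31)
  b <- simulate_scenario(cfg)
  win <- make_windows(c(chr1 = 2e7), 1e5)
  r <- snp_density_ratio_windows(b$genotypes, b$sheet, win,
                                 species = "picta")
  nm <- sum(r$n_male_poly); nf <- sum(r$n_female_poly)
  # equal sample sizes per sex: counts should split evenly (3 sigma)
  expect_lt(abs(nm - nf), 3 * sqrt(nm + nf))
})

test_that("envelope quantiles match an independent interpolation oracle", {
  v <- as.numeric(1:1000)
  env <- autosomal_envelope(data.frame(fst = v), statistics = "fst")
  expect_equal(c(env$lower, env$upper), quantile_oracle(v, c(0.025, 0.975)),
               tolerance = 1e-12)
  expect_equal(c(env$lower, env$upper), c(25.975, 975.025))

  env7 <- autosomal_envelope(data.frame(fst = rep(7, 50)), statistics = "fst")
  expect_equal(c(env7$lower, env7$upper), c(7, 7))

  skewed <- c(rep(0, 39), 100)
  envs <- autosomal_envelope(data.frame(fst = skewed), statistics = "fst")
  expect_equal(envs$lower, 0)
  expect_equal(envs$upper, quantile_oracle(skewed, 0.975), tolerance = 1e-12)
  expect_equal(envs$upper, 2.5)

  expect_error(autosomal_envelope(data.frame(fst = rnorm(10)),
                                  statistics = "fst"), "simulate")
})

test_that("the tricube smoother is exact on constants and lines", {
  x <- sort(runif(40, 0, 100))
  expect_equal(smooth_series(x, rep(3, 40)), rep(3, 40), tolerance = 1e-8)
  y <- 2 * x - 5
  expect_equal(smooth_series(x, y), y, tolerance = 1e-8)
  expect_warning(out <- smooth_series(1:5, c(1, 2, 3, 4, 5)), "fewer than 10")
  expect_equal(out, c(1, 2, 3, 4, 5))
})

test_that("the smoother agrees with an independent local-regression fit", {
  set.seed(12)
  x <- sort(runif(57, 0, 100))
  y <- ifelse(x < 50, 0, 1) + rnorm(57, 0, 0.1)
  got <- smooth_series(x, y, span = 0.3)
  ref <- fitted(loess(y ~ x, span = 0.3, degree = 1, family = "gaussian",
                      surface = "direct"))
  expect_equal(got, as.numeric(ref), tolerance = 1e-8)
})
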