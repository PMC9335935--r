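test_that("scenario trees carry the branch lengths the event times imply", {
  cfg <- scenario_config("homologous", t_s = 1, t_sdr = 2)
  tr <- scenario_tree(cfg)
  stems <- tr[tr$internal, ]
  expect_setequal(stems$tips, c("Yp+Yw", "Xp+Xw"))
  expect_equal(stems$length, c(1, 1))
  expect_true(tr$y_linked[tr$branch == "Y_stem"])

  cfg_to <- scenario_config("turnover_wingei", t_s = 1, t_sdr = 2,
                            t_to = 0.25)
  tr_to <- scenario_tree(cfg_to)
  expect_equal(tr_to$length[tr_to$tips == "Xw+Yw"], 1 - 0.25)
  expect_equal(tr_to$length[tr_to$tips == "Xp+Xw+Yw"], 2 - 1)

  cfg_ind <- scenario_config("independent", t_p = 0.4, t_w = 0.4)
  tr_ind <- scenario_tree(cfg_ind)
  expect_equal(unique(tr_ind$length[tr_ind$internal]), 1 - 0.4)

  expect_error(scenario_tree(scenario_config("autosome")), "no gametolog")
})

test_that("expected tree fractions follow rate-weighted internal branches", {
  cfg <- scenario_config("homologous", t_s = 1, t_sdr = 2, alpha = 1)
  ef <- expected_internal_fractions(cfg)
  expect_equal(unname(ef[c("tree1", "tree2")]), c(0.5, 0.5))
  expect_equal(sum(ef), 1)

  # male-biased mutation doubles the Y-stem rate
  ef2 <- expected_internal_fractions(
    scenario_config("homologous", alpha = 2))
  expect_equal(unname(ef2[c("tree1", "tree2")]), c(2 / 3, 1 / 3))

  ef_to <- expected_internal_fractions(
    scenario_config("turnover_wingei", t_s = 1, t_sdr = 2, t_to = 0.5))
  expect_equal(unname(ef_to["tree4"]), 0.5 / 1.5)
  expect_equal(unname(ef_to["tree5"]), 1 / 1.5)
  expect_true(all(ef_to[-c(4, 5)] == 0))
})

test_that("configuration invariants are enforced", {
  expect_error(scenario_config("homologous", t_sdr = 0.5), "t_sdr")
  expect_error(scenario_config("independent", t_p = 2), "t_p")
  expect_error(scenario_config("turnover_wingei", t_to = 2), "t_to")
  expect_error(scenario_config(sdr = c(1, 1e9)), "SDR interval")
  expect_error(scenario_config(d_p = 1.5), "\\[0, 1\\]")
})

test_that("simulation is deterministic and extensible under the seed", {
  cfg <- scenario_config("independent", n_sdr_sites = 120, n_par_sites = 50,
                         n_auto_sites = 50, eps = 0.02, d_p = 0.3, seed = 77)
  b1 <- simulate_scenario(cfg)
  b2 <- simulate_scenario(cfg)
  expect_identical(b1$genotypes$geno, b2$genotypes$geno)
  expect_identical(b1$depth, b2$depth)
  expect_identical(b1$truth, b2$truth)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_scenario_bundle(b1, d1)
  write_scenario_bundle(b2, d2)
  for (f in c("sim.vcf", "samples.tsv", "depth.tsv", "truth.tsv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }

  # enlarging the simulation appends sites without touching earlier ones
  cfg_big <- scenario_config("independent", n_sdr_sites = 200,
                             n_par_sites = 50, n_auto_sites = 50,
                             eps = 0.02, d_p = 0.3, seed = 77)
  b3 <- simulate_scenario(cfg_big)
  small <- b1$truth[b1$truth$site_type == "sdr", ]
  big <- b3$truth[b3$truth$site_type == "sdr", ]
  shared <- intersect(small$pos, big$pos)
  expect_equal(length(shared), nrow(small))
  cols <- c("branch", "pattern", "true_tree", "deleted_on_Yp")
  expect_equal(small[match(shared, small$pos), cols],
               big[match(shared, big$pos), cols], ignore_attr = TRUE)
})

test_that("a fully deleted picta Y can never show trees 5 or 7", {
  cfg <- scenario_config("independent", n_sdr_sites = 4000, d_p = 1,
                         p_homoplasy = 0.2, seed = 55)
  b <- simulate_scenario(cfg)
  ts <- run_treeshare(b$genotypes, b$sheet)
  expect_equal(unname(ts$counts[c("n5", "n7")]), c(0L, 0L))
  # trees needing an observed Yp allele different from Xp all vanish
  expect_equal(unname(ts$counts[c("n1", "n2")]), c(0L, 0L))
})

test_that("scenario configs round-trip through YAML", {
  cfg <- scenario_config("turnover_wingei", alpha = 2.5, d_p = 0.4,
                         n_sdr_sites = 10, seed = 3)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario_config(cfg, path)
  back <- read_scenario_config(path)
  expect_equal(back$scenario, "turnover_wingei")
  expect_equal(back$alpha, 2.5)
  expect_equal(back$samples, cfg$samples)
  expect_equal(back$autosomes, cfg$autosomes)
})

test_that("the truth table covers every emitted site exactly once", {
  cfg <- scenario_config("homologous", n_sdr_sites = 100, n_par_sites = 40,
                         n_auto_sites = 40, seed = 2)
  b <- simulate_scenario(cfg)
  key_sites <- paste(b$genotypes$sites$chrom, b$genotypes$sites$pos)
  key_truth <- paste(b$truth$chrom, b$truth$pos)
  expect_identical(key_sites, key_truth)
  expect_equal(anyDuplicated(key_truth), 0L)
})
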