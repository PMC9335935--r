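test_that("gametolog alleles are inferred from fixed sex-genotype patterns", {
  # females homozygous ref, males all het: X carries ref, Y carries alt
  r <- infer_gametolog_alleles(c(1L, 1L, 1L), c(0L, 0L, 0L))
  expect_false(r$rejected)
  expect_equal(c(r$x_allele, r$y_allele), c("ref", "alt"))
  # males homozygous for the females' allele: X and Y share it
  r <- infer_gametolog_alleles(c(0L, 0L), c(0L, 0L))
  expect_equal(c(r$x_allele, r$y_allele), c("ref", "ref"))
  # polymorphic females reject the site
  r <- infer_gametolog_alleles(c(1L, 1L), c(0L, 1L))
  expect_true(r$rejected)
  expect_equal(r$reason, "female_polymorphic")
  # males homozygous for the opposite allele: excluded configuration
  r <- infer_gametolog_alleles(c(2L, 2L), c(0L, 0L))
  expect_true(r$rejected)
  expect_equal(r$reason, "males_opposite_homozygote")
  # a mixture of male genotypes
  r <- infer_gametolog_alleles(c(1L, 0L), c(0L, 0L))
  expect_equal(r$reason, "males_mixed")
  # sample minima
  r <- infer_gametolog_alleles(c(1L, NA), c(0L, 0L))
  expect_equal(r$reason, "insufficient_samples")
})

test_that("polarisation requires outgroup monomorphism", {
  sp <- c("latipinna", "holbrooki")
  expect_equal(polarize(c(0L, 0L), sp)$ancestral, "ref")
  expect_equal(polarize(c(2L, 2L), sp)$ancestral, "alt")
  r <- polarize(c(0L, 2L), sp)
  expect_true(r$rejected)
  r <- polarize(c(1L, 0L), sp)
  expect_true(r$rejected)
  expect_equal(r$reason, "outgroup_polymorphic")
  r <- polarize(c(0L, NA), sp)
  expect_equal(r$reason, "insufficient_outgroup")
})

test_that("only derived alleles on 2 or 3 chromosomes are informative", {
  call <- function(x, y) structure(list(x_allele = x, y_allele = y,
                                        rejected = FALSE,
                                        reason = NA_character_),
                                   class = "gametolog_call")
  p <- informative_filter(call("alt", "alt"), call("ref", "ref"), "ref")
  expect_true(p$informative)
  expect_setequal(p$pattern, c("Xp", "Yp"))
  p4 <- informative_filter(call("alt", "alt"), call("alt", "alt"), "ref")
  expect_false(p4$informative)
  expect_equal(p4$reason, "size_4")
  p1 <- informative_filter(call("ref", "ref"), call("ref", "alt"), "ref")
  expect_false(p1$informative)
  expect_equal(p1$reason, "size_1")
  rej <- structure(list(x_allele = NA, y_allele = NA, rejected = TRUE,
                        reason = "females_polymorphic"),
                   class = "gametolog_call")
  pr <- informative_filter(rej, call("ref", "ref"), "ref")
  expect_false(pr$informative)
  expect_match(pr$reason, "^picta_")
})

test_that("pattern-to-tree assignments follow the topology table", {
  expect_equal(classify_tree(c("Yp", "Yw")), 1)
  expect_equal(classify_tree(c("Xp", "Yp")), 3)
  expect_equal(classify_tree(c("Xp", "Xw", "Yw")), 5)
  expect_equal(classify_tree(c("Yp", "Xw", "Yw")), 7)
  expect_error(classify_tree("Yw"), "not informative")
  map <- tree_topologies()
  expect_equal(map$interpretation[map$tree_id %in% 1:2],
               rep("homologous_sdr", 2))
  expect_equal(map$interpretation[map$tree_id %in% 9:10],
               rep("implausible", 2))
})

test_that("a hand-built table exercises every rejection reason", {
  ids <- c("picta_M1", "picta_M2", "picta_F1", "picta_F2",
           "wingei_M1", "wingei_M2", "wingei_F1", "wingei_F2",
           "latipinna_1", "holbrooki_1")
  sheet <- sample_sheet(ids,
                        c(rep("picta", 4), rep("wingei", 4),
                          "latipinna", "holbrooki"),
                        c("M", "M", "F", "F", "M", "M", "F", "F",
                          "unknown", "unknown"))
  #          pM1 pM2 pF1 pF2 wM1 wM2 wF1 wF2 out1 out2
  geno <- rbind(
    c(1L, 1L, 0L, 1L, 1L, 1L, 0L, 0L, 0L, 0L),  # picta females polymorphic
    c(1L, 0L, 0L, 0L, 1L, 1L, 0L, 0L, 0L, 0L),  # picta males mixed
    c(1L, 1L, 0L, 0L, 2L, 2L, 0L, 0L, 0L, 0L),  # wingei males opposite hom
    c(1L, 1L, 0L, 0L, 1L, 1L, 0L, 0L, 1L, 0L),  # outgroup heterozygote
    c(2L, 2L, 2L, 2L, 2L, 2L, 2L, 2L, 0L, 0L),  # derived on all four: size 4
    c(1L, 1L, 0L, 0L, 1L, 1L, 0L, 0L, 0L, 0L))  # trees: derived on Yp and Yw
  colnames(geno) <- ids
  gt <- toy_table(geno)
  ts <- run_treeshare(gt, sheet, pooled_maf = 0)
  expect_equal(ts$n_informative, 1L)
  expect_equal(unname(ts$counts["n1"]), 1L)
  reasons <- as.list(ts$reasons)
  expect_equal(reasons[["picta_female_polymorphic"]], 1L)
  expect_equal(reasons[["picta_males_mixed"]], 1L)
  expect_equal(reasons[["wingei_males_opposite_homozygote"]], 1L)
  expect_equal(reasons[["outgroup_polymorphic"]], 1L)
  expect_equal(reasons[["size_4"]], 1L)
})

test_that("simulated histories are recovered exactly without artifacts", {
  for (scen in c("homologous", "independent")) {
    cfg <- scenario_config(scen, n_sdr_sites = 600, n_par_sites = 100,
                           n_auto_sites = 100, seed = 27)
    b <- simulate_scenario(cfg)
    ts <- run_treeshare(b$genotypes, b$sheet)
    truth <- table(factor(b$truth$true_tree, levels = 1:10))
    expect_equal(as.integer(ts$counts), as.integer(truth))
    allowed <- if (scen == "homologous") 1:2 else 3:4
    expect_true(all(which(ts$counts > 0) %in% allowed))
  }
})

test_that("equal X and Y stems split trees 1 and 2 evenly", {
  cfg <- scenario_config("homologous", n_sdr_sites = 2500, seed = 19)
  ts <- run_treeshare(simulate_scenario(cfg)$genotypes,
                      simulate_scenario(cfg)$sheet)
  n1 <- ts$counts[["n1"]]; N <- ts$n_informative
  expect_lt(abs(n1 - N / 2), 3 * sqrt(N * 0.25))
})

test_that("the hypothesis rule reads the counts as documented", {
  mk <- function(...) {
    counts <- setNames(integer(10), paste0("n", 1:10))
    args <- list(...)
    counts[names(args)] <- unlist(args)
    structure(list(counts = counts, n_total = sum(counts) + 100,
                   n_informative = sum(counts)),
              class = "treeshare_result")
  }
  expect_equal(summarize_hypotheses(mk(n3 = 270, n4 = 100))$verdict,
               "independent")
  expect_equal(summarize_hypotheses(mk(n1 = 50, n2 = 50))$verdict,
               "homologous")
  expect_equal(summarize_hypotheses(mk(n9 = 5))$verdict, "ambiguous")
  expect_warning(s0 <- summarize_hypotheses(mk()), "no informative")
  expect_equal(s0$verdict, "ambiguous")
  # a clear tree-5 excess over the implausible-tree background flags a
  # wingei turnover
  s5 <- summarize_hypotheses(mk(n4 = 40, n5 = 60, n9 = 2, n10 = 2))
  expect_true(s5$turnover_wingei_flag)
})

test_that("sample minima are enforced before classification", {
  ids <- c("picta_M1", "picta_F1", "latipinna_1", "holbrooki_1")
  sheet <- sample_sheet(ids, c("picta", "picta", "latipinna", "holbrooki"),
                        c("M", "F", "unknown", "unknown"))
  gt <- toy_table(matrix(0:1, 2, 4, dimnames = list(NULL, ids)))
  expect_error(run_treeshare(gt, sheet), "sample minima")
})
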