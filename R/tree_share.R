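#' The ten gametolog tree topologies
#'
#' A topologically informative SNP has its derived allele fixed on 2 or 3
#' of the four sex chromosomes `Xp`, `Yp` (M. picta X and Y) and `Xw`,
#' `Yw` (P. wingei X and Y). The 6 + 4 = 10 such subsets map one-to-one
#' onto the ten possible gametolog trees. Trees 1-2 (derived allele
#' shared by the two Ys, or the two Xs) indicate a homologous SDR
#' predating the species split; trees 3-4 (derived allele private to one
#' species' X+Y pair) indicate independently evolved SDRs; trees 5-8 are
#' consistent with turnover events (or homoplasy); trees 9-10 are
#' biologically implausible cross-pairings attributable to homoplasy or
#' error. The mapping lives in this one editable table so it can be
#' revised without code changes.
#'
#' @return data.frame with columns `tree_id`, `pattern` (chromosome
#'   subset key, `+`-joined in Xp, Yp, Xw, Yw order) and `interpretation`
#' @export
tree_topologies <- function() {
  data.frame(
    tree_id = 1:10,
    pattern = c("Yp+Yw", "Xp+Xw", "Xp+Yp", "Xw+Yw",
                "Xp+Xw+Yw", "Xp+Yp+Xw", "Yp+Xw+Yw", "Xp+Yp+Yw",
                "Xp+Yw", "Yp+Xw"),
    interpretation = c("homologous_sdr", "homologous_sdr",
                       "independent_sdr", "independent_sdr",
                       "turnover", "turnover", "turnover", "turnover",
                       "implausible", "implausible"),
    stringsAsFactors = FALSE)
}

# canonical subset key in fixed chromosome order
pattern_key <- function(chroms) {
  ord <- c("Xp", "Yp", "Xw", "Yw")
  paste(ord[ord %in% chroms], collapse = "+")
}

#' Infer the fixed X and Y gametolog alleles of one species at a site
#'
#' Requires the females of the species to all be homozygous for the same
#' allele (that allele is the X allele) and the males to be either all
#' heterozygous (the other allele is then the Y allele) or all homozygous
#' for the females' allele (X and Y carry the same allele). Any other
#' male configuration, female polymorphism, or fewer than `min_per_sex`
#' called genotypes per sex rejects the site for that species.
#'
#' @inheritParams classify_sdr_like
#' @return a `gametolog_call` list: `x_allele`, `y_allele` (`"ref"`,
#'   `"alt"` or `NA`), `rejected` (logical), `reason` (`NA` or one of
#'   `"insufficient_samples"`, `"female_polymorphic"`, `"males_mixed"`,
#'   `"males_opposite_homozygote"`)
#' @examples
#' infer_gametolog_alleles(c(1L, 1L, 1L), c(0L, 0L, 0L))
#' @export
infer_gametolog_alleles <- function(male_genotypes, female_genotypes,
                                    min_per_sex = 2) {
  res <- gametolog_matrix(matrix(as.integer(male_genotypes), nrow = 1),
                          matrix(as.integer(female_genotypes), nrow = 1),
                          min_per_sex = min_per_sex)
  structure(list(x_allele = res$x_allele[1], y_allele = res$y_allele[1],
                 rejected = res$rejected[1], reason = res$reason[1]),
            class = "gametolog_call")
}

# vectorised gametolog-allele inference over sites x samples matrices
gametolog_matrix <- function(geno_m, geno_f, min_per_sex = 2) {
  cnt <- function(g) {
    n0 <- rowSums(g == 0L, na.rm = TRUE)
    n1 <- rowSums(g == 1L, na.rm = TRUE)
    n2 <- rowSums(g == 2L, na.rm = TRUE)
    list(n = n0 + n1 + n2, n0 = n0, n1 = n1, n2 = n2)
  }
  m <- cnt(geno_m); f <- cnt(geno_f)
  nsite <- length(m$n)
  x_allele <- y_allele <- rep(NA_character_, nsite)
  reason <- rep(NA_character_, nsite)

  insufficient <- m$n < min_per_sex | f$n < min_per_sex
  reason[insufficient] <- "insufficient_samples"

  f_ref <- f$n0 > 0 & f$n1 == 0 & f$n2 == 0
  f_alt <- f$n2 > 0 & f$n1 == 0 & f$n0 == 0
  fem_poly <- !insufficient & !f_ref & !f_alt
  reason[fem_poly] <- "female_polymorphic"

  ok <- !insufficient & !fem_poly
  x_allele[ok & f_ref] <- "ref"
  x_allele[ok & f_alt] <- "alt"

  m_all_het <- m$n1 > 0 & m$n0 == 0 & m$n2 == 0
  m_all_homref <- m$n0 > 0 & m$n1 == 0 & m$n2 == 0
  m_all_homalt <- m$n2 > 0 & m$n1 == 0 & m$n0 == 0

  # males all het: Y carries the allele opposite to X
  y_allele[ok & m_all_het & f_ref] <- "alt"
  y_allele[ok & m_all_het & f_alt] <- "ref"
  # males all homozygous for the females' allele: Y carries the X allele
  y_allele[ok & m_all_homref & f_ref] <- "ref"
  y_allele[ok & m_all_homalt & f_alt] <- "alt"

  opposite <- ok & ((m_all_homref & f_alt) | (m_all_homalt & f_ref))
  reason[opposite] <- "males_opposite_homozygote"
  mixed <- ok & !m_all_het & !m_all_homref & !m_all_homalt
  reason[mixed] <- "males_mixed"

  rejected <- !is.na(reason)
  x_allele[rejected] <- NA_character_
  y_allele[rejected] <- NA_character_
  list(x_allele = x_allele, y_allele = y_allele, rejected = rejected,
       reason = reason)
}

#' Polarise a site against the outgroups
#'
#' All called individuals of both outgroup species must be homozygous for
#' the same allele, which is then the ancestral allele (the other allele
#' is derived). Any outgroup heterozygote, disagreement between
#' individuals or species, or an outgroup species with no called
#' individual rejects the site.
#'
#' @param outgroup_genotypes integer genotype vector (codes `0/1/2/NA`)
#'   over all outgroup individuals
#' @param outgroup_species character vector (same length) naming each
#'   individual's species; every species listed must have at least one
#'   called genotype
#' @return list: `ancestral` (`"ref"`, `"alt"` or `NA`), `rejected`,
#'   `reason` (`NA`, `"insufficient_outgroup"` or
#'   `"outgroup_polymorphic"`)
#' @export
polarize <- function(outgroup_genotypes, outgroup_species) {
  res <- polarize_matrix(matrix(as.integer(outgroup_genotypes), nrow = 1),
                         outgroup_species)
  list(ancestral = res$ancestral[1], rejected = res$rejected[1],
       reason = res$reason[1])
}

polarize_matrix <- function(geno_o, outgroup_species) {
  species <- unique(outgroup_species)
  nsite <- nrow(geno_o)
  called_per_sp <- sapply(species, function(sp) {
    rowSums(!is.na(geno_o[, outgroup_species == sp, drop = FALSE]))
  })
  if (nsite == 1) called_per_sp <- matrix(called_per_sp, nrow = 1)
  insufficient <- rowSums(called_per_sp >= 1) < length(species)

  n0 <- rowSums(geno_o == 0L, na.rm = TRUE)
  n1 <- rowSums(geno_o == 1L, na.rm = TRUE)
  n2 <- rowSums(geno_o == 2L, na.rm = TRUE)
  all_ref <- n0 > 0 & n1 == 0 & n2 == 0
  all_alt <- n2 > 0 & n1 == 0 & n0 == 0

  ancestral <- rep(NA_character_, nsite)
  reason <- rep(NA_character_, nsite)
  reason[insufficient] <- "insufficient_outgroup"
  poly <- !insufficient & !all_ref & !all_alt
  reason[poly] <- "outgroup_polymorphic"
  ok <- !insufficient & !poly
  ancestral[ok & all_ref] <- "ref"
  ancestral[ok & all_alt] <- "alt"
  list(ancestral = ancestral, rejected = !is.na(reason), reason = reason)
}

#' Build the derived-allele presence pattern for a site
#'
#' Combines the two species' gametolog calls with the polarisation into
#' the subset of `{Xp, Yp, Xw, Yw}` carrying the derived allele. The
#' pattern is informative iff the derived allele is fixed on 2 or 3 of
#' the four chromosomes.
#'
#' @param call_picta,call_wingei `gametolog_call`s from
#'   [infer_gametolog_alleles()]
#' @param ancestral `"ref"` or `"alt"` from [polarize()]
#' @return list: `pattern` (character vector subset of
#'   `c("Xp","Yp","Xw","Yw")` or `NULL`), `informative`,
#'   `reason` (`NA` or `"size_0"`, `"size_1"`, `"size_4"`, or the
#'   upstream rejection reason)
#' @export
informative_filter <- function(call_picta, call_wingei, ancestral) {
  if (call_picta$rejected) {
    return(list(pattern = NULL, informative = FALSE,
                reason = paste0("picta_", call_picta$reason)))
  }
  if (call_wingei$rejected) {
    return(list(pattern = NULL, informative = FALSE,
                reason = paste0("wingei_", call_wingei$reason)))
  }
  if (is.na(ancestral)) {
    return(list(pattern = NULL, informative = FALSE,
                reason = "unpolarized"))
  }
  derived <- if (ancestral == "ref") "alt" else "ref"
  alleles <- c(Xp = call_picta$x_allele, Yp = call_picta$y_allele,
               Xw = call_wingei$x_allele, Yw = call_wingei$y_allele)
  pattern <- names(alleles)[alleles == derived]
  size <- length(pattern)
  if (size %in% c(2, 3)) {
    list(pattern = pattern, informative = TRUE, reason = NA_character_)
  } else {
    list(pattern = NULL, informative = FALSE,
         reason = sprintf("size_%d", size))
  }
}

#' Map an informative presence pattern to its tree id
#'
#' @param pattern character vector subset of `c("Xp","Yp","Xw","Yw")` of
#'   size 2 or 3
#' @param map topology table, by default [tree_topologies()]
#' @return integer tree id in 1..10
#' @export
classify_tree <- function(pattern, map = tree_topologies()) {
  if (length(pattern) < 2 || length(pattern) > 3) {
    stop_data("pattern of size ", length(pattern), " is not informative")
  }
  key <- pattern_key(pattern)
  id <- map$tree_id[match(key, map$pattern)]
  if (is.na(id)) stop_data("pattern not in topology map: ", key)
  id
}

#' Classify every SNP into one of the ten gametolog trees
#'
#' The per-site pipeline of the allele-sharing analysis: a pooled
#' minor-allele-frequency filter over the analysis cohort (wingei +
#' picta + outgroups), per-species gametolog-allele inference, outgroup
#' polarisation, the 2-or-3-chromosome informativeness filter, and tree
#' classification. Returns per-site assignments, genome-wide counts
#' `n1..n10`, and tallies of uninformative sites by reason. Fractions are
#' reported under two denominators: the strict informative set, and the
#' relaxed set of all sites entering the analysis (which includes sites
#' polymorphic within species).
#'
#' @param gt a [genotype_table()] (biallelic SNPs; run
#'   [apply_site_filters()] first)
#' @param sheet a [sample_sheet()] containing at least `min_per_sex`
#'   males and females each of wingei and picta and `min_outgroup`
#'   individuals each of latipinna and holbrooki
#' @param min_per_sex minimum called genotypes per focal species and sex
#' @param min_outgroup minimum called genotypes per outgroup species
#' @param pooled_maf minor-allele-frequency floor computed over the
#'   pooled cohort's called alleles (0 disables)
#' @param map topology table (see [tree_topologies()])
#' @return a `treeshare_result`: list with `sites` (per-site data.frame:
#'   `chrom`, `pos`, `pattern`, `tree_id`, `reason`), `counts` (named
#'   n1..n10), `reasons` (table), `n_total`, `n_informative`
#' @export
run_treeshare <- function(gt, sheet, min_per_sex = 2, min_outgroup = 1,
                          pooled_maf = 0.2, map = tree_topologies()) {
  pick <- function(sp, sex = NULL) sheet_samples(sheet, species = sp, sex = sex)
  groups <- list(picta_m = pick("picta", "M"), picta_f = pick("picta", "F"),
                 wingei_m = pick("wingei", "M"), wingei_f = pick("wingei", "F"))
  outg <- c(pick("latipinna"), pick("holbrooki"))
  bad <- c(names(groups)[vapply(groups, length, 1L) < min_per_sex],
           if (length(pick("latipinna")) < min_outgroup) "latipinna",
           if (length(pick("holbrooki")) < min_outgroup) "holbrooki")
  if (length(bad)) {
    stop_config("sample minima unsatisfiable for: ",
                paste(bad, collapse = ", "))
  }
  cohort <- c(unlist(groups, use.names = FALSE), outg)
  gt <- subset_genotypes(gt, samples = cohort)
  if (any(grepl(",", gt$sites$alt, fixed = TRUE))) {
    stop_data("multi-allelic sites present; apply_site_filters first")
  }

  nsite <- nrow(gt$sites)
  reason <- rep(NA_character_, nsite)
  tree_id <- rep(NA_integer_, nsite)
  pattern <- rep(NA_character_, nsite)

  if (nsite) {
    # pooled maf over the analysis cohort
    if (pooled_maf > 0) {
      ac <- called_allele_counts(gt$geno)
      tot <- ac[, "ref"] + ac[, "alt"]
      maf <- ifelse(tot > 0, pmin(ac[, "ref"], ac[, "alt"]) / tot, 0)
      low <- maf < pooled_maf
      reason[low] <- "pooled_maf"
    }
    todo <- is.na(reason)

    gp <- gametolog_matrix(gt$geno[, groups$picta_m, drop = FALSE],
                           gt$geno[, groups$picta_f, drop = FALSE],
                           min_per_sex = min_per_sex)
    gw <- gametolog_matrix(gt$geno[, groups$wingei_m, drop = FALSE],
                           gt$geno[, groups$wingei_f, drop = FALSE],
                           min_per_sex = min_per_sex)
    og_species <- sheet$species[match(outg, sheet$sample_id)]
    po <- polarize_matrix(gt$geno[, outg, drop = FALSE], og_species)

    rej_p <- todo & gp$rejected
    reason[rej_p] <- paste0("picta_", gp$reason[rej_p])
    todo <- is.na(reason)
    rej_w <- todo & gw$rejected
    reason[rej_w] <- paste0("wingei_", gw$reason[rej_w])
    todo <- is.na(reason)
    rej_o <- todo & po$rejected
    reason[rej_o] <- po$reason[rej_o]
    todo <- is.na(reason)

    if (any(todo)) {
      derived <- ifelse(po$ancestral == "ref", "alt", "ref")
      hit <- cbind(Xp = gp$x_allele == derived,
                   Yp = gp$y_allele == derived,
                   Xw = gw$x_allele == derived,
                   Yw = gw$y_allele == derived)
      size <- rowSums(hit)
      keys <- apply(hit, 1, function(h) pattern_key(c("Xp", "Yp", "Xw",
                                                      "Yw")[h]))
      inf <- todo & size %in% c(2, 3)
      reason[todo & !inf] <- sprintf("size_%d", size[todo & !inf])
      tree_id[inf] <- map$tree_id[match(keys[inf], map$pattern)]
      pattern[inf] <- keys[inf]
    }
  }

  counts <- stats::setNames(integer(10), paste0("n", 1:10))
  if (any(!is.na(tree_id))) {
    tab <- table(factor(tree_id, levels = 1:10))
    counts[] <- as.integer(tab)
  }
  structure(list(
    sites = data.frame(chrom = gt$sites$chrom, pos = gt$sites$pos,
                       pattern = pattern, tree_id = tree_id,
                       reason = reason, stringsAsFactors = FALSE),
    counts = counts,
    reasons = table(reason[!is.na(reason)]),
    n_total = nsite,
    n_informative = sum(!is.na(tree_id))),
    class = "treeshare_result")
}

#' @export
print.treeshare_result <- function(x, ...) {
  cat(sprintf("treeshare_result: %d sites, %d informative\n",
              x$n_total, x$n_informative))
  print(x$counts)
  invisible(x)
}

#' Summarise tree counts against the SDR-history hypotheses
#'
#' Applies a transparent decision rule, echoed in the output: the
#' homologous-SDR verdict requires at least half of informative sites in
#' trees 1-2; the independent-SDR verdict at least half in trees 3-4;
#' otherwise ambiguous. Independently of the verdict, a wingei-turnover
#' flag is raised when the tree-5 count exceeds a Poisson upper bound on
#' the homoplasy background estimated from the biologically implausible
#' trees 9-10. The rule is a reporting heuristic over counts; fractions
#' under both denominators are reported regardless.
#'
#' @param tc a `treeshare_result` from [run_treeshare()]
#' @return a `hypothesis_summary` list: `counts`, `fractions` (of the
#'   informative set), `fractions_total` (of all analysed sites),
#'   `verdict`, `turnover_wingei_flag`, `decision_rule`
#' @export
summarize_hypotheses <- function(tc) {
  n <- tc$counts
  N <- sum(n)
  rule <- paste("homologous if (n1+n2)/N >= 0.5;",
                "independent if (n3+n4)/N >= 0.5; else ambiguous.",
                "turnover_wingei flagged if n5 > homoplasy background",
                "(n9+n10)/2 + 3*sqrt(max((n9+n10)/2, 1))")
  if (N == 0) {
    warning("no informative sites; empty hypothesis summary")
    return(structure(list(counts = n, fractions = n * NA_real_,
                          fractions_total = n * NA_real_,
                          verdict = "ambiguous",
                          turnover_wingei_flag = FALSE,
                          decision_rule = rule),
                     class = "hypothesis_summary"))
  }
  frac <- n / N
  lam <- (n[["n9"]] + n[["n10"]]) / 2
  to_flag <- n[["n5"]] > lam + 3 * sqrt(max(lam, 1))
  verdict <- if ((n[["n1"]] + n[["n2"]]) / N >= 0.5) {
    "homologous"
  } else if ((n[["n3"]] + n[["n4"]]) / N >= 0.5) {
    "independent"
  } else {
    "ambiguous"
  }
  if (verdict == "ambiguous" && to_flag) verdict <- "turnover_wingei"
  structure(list(counts = n, fractions = frac,
                 fractions_total = n / tc$n_total,
                 verdict = verdict,
                 turnover_wingei_flag = to_flag,
                 decision_rule = rule),
            class = "hypothesis_summary")
}

#' @export
print.hypothesis_summary <- function(x, ...) {
  cat("hypothesis_summary verdict:", x$verdict,
      if (x$turnover_wingei_flag) "(turnover_wingei flagged)" else "", "\n")
  print(round(x$fractions, 4))
  invisible(x)
}
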