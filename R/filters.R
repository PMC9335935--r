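#' Site-filter configuration
#'
#' Bundles the thresholds of the site-filter cascade applied by
#' [apply_site_filters()]. The defaults mirror a short-read diploid
#' calling pipeline: quality >= 20, biallelic SNPs only, indels and
#' singletons removed, per-genotype minimum depth 3.
#'
#' `max_missing_fraction` is the *allowed* fraction of missing genotypes
#' per site (`0` = no missing genotype tolerated, `1` = no missingness
#' filter). Note this is the complement of the VCFtools `--max-missing`
#' argument, which states the *required present* fraction.
#'
#' @param min_qual minimum variant quality score (sites with missing QUAL
#'   are kept)
#' @param biallelic_snps_only drop multi-allelic records
#' @param drop_indels drop indel and symbolic records
#' @param drop_singletons drop sites whose minor allele is observed exactly
#'   once over all called alleles (i.e. one heterozygote carries the only
#'   copy)
#' @param min_depth per-genotype depth below which a call is masked to
#'   missing (3 for a depth-3 pipeline, 10 for a depth-10 pipeline)
#' @param max_missing_fraction allowed missing-genotype fraction in `[0,1]`
#' @param min_maf minimum minor-allele frequency over called alleles
#' @return a `filter_config` list
#' @export
filter_config <- function(min_qual = 20, biallelic_snps_only = TRUE,
                          drop_indels = TRUE, drop_singletons = TRUE,
                          min_depth = 3, max_missing_fraction = 1,
                          min_maf = 0) {
  if (min_qual < 0 || min_depth < 0) stop_config("thresholds must be non-negative")
  if (max_missing_fraction < 0 || max_missing_fraction > 1) {
    stop_config("max_missing_fraction must be in [0, 1]")
  }
  if (min_maf < 0 || min_maf > 1) stop_config("min_maf must be in [0, 1]")
  structure(list(min_qual = min_qual,
                 biallelic_snps_only = biallelic_snps_only,
                 drop_indels = drop_indels,
                 drop_singletons = drop_singletons,
                 min_depth = min_depth,
                 max_missing_fraction = max_missing_fraction,
                 min_maf = min_maf),
            class = "filter_config")
}

# allele counts over called genotypes; returns matrix with ref/alt rows
called_allele_counts <- function(geno) {
  n0 <- rowSums(geno == 0L, na.rm = TRUE)
  n1 <- rowSums(geno == 1L, na.rm = TRUE)
  n2 <- rowSums(geno == 2L, na.rm = TRUE)
  cbind(ref = 2 * n0 + n1, alt = 2 * n2 + n1)
}

#' Apply the site-filter cascade
#'
#' Filters are applied in a fixed order so that removal counts are
#' comparable across runs: quality, indels, biallelic SNPs, per-genotype
#' depth masking (masks calls to missing; removes no site by itself),
#' singletons, missingness, minor-allele frequency. Counts of sites
#' removed at each stage are returned as a `filter_report`, together with
#' the number of genotype calls masked at the depth stage.
#'
#' @param gt a [genotype_table()]
#' @param cfg a [filter_config()]
#' @return list with elements `genotypes` (the filtered
#'   [genotype_table()]) and `report` (a `filter_report` data.frame with
#'   attributes `input_sites`, `output_sites`, `genotypes_masked`)
#' @export
apply_site_filters <- function(gt, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  gt <- validate_genotype_table(gt)
  input_sites <- nrow(gt$sites)
  stages <- c("quality", "indel", "biallelic", "depth_mask", "singleton",
              "missingness", "maf")
  removed <- stats::setNames(integer(length(stages)), stages)

  keep_site <- function(gt, keep, stage) {
    removed[stage] <<- removed[stage] + sum(!keep)
    subset_genotypes(gt, sites = keep)
  }

  if (nrow(gt$sites)) {
    q <- gt$sites$qual
    gt <- keep_site(gt, is.na(q) | q >= cfg$min_qual, "quality")
  }
  if (nrow(gt$sites) && cfg$drop_indels) {
    ref_len <- nchar(gt$sites$ref)
    alt_max <- vapply(strsplit(gt$sites$alt, ",", fixed = TRUE),
                      function(a) max(nchar(a)), numeric(1))
    symbolic <- grepl("[<>*]", gt$sites$alt)
    gt <- keep_site(gt, ref_len == 1 & alt_max == 1 & !symbolic, "indel")
  }
  if (nrow(gt$sites) && cfg$biallelic_snps_only) {
    gt <- keep_site(gt, !grepl(",", gt$sites$alt, fixed = TRUE), "biallelic")
  }
  genotypes_masked <- 0L
  if (nrow(gt$sites) && cfg$min_depth > 0) {
    mask <- !is.na(gt$geno) & !is.na(gt$depth) & gt$depth < cfg$min_depth
    genotypes_masked <- sum(mask)
    if (genotypes_masked) gt$geno[mask] <- NA_integer_
  }
  if (nrow(gt$sites) && cfg$drop_singletons) {
    ac <- called_allele_counts(gt$geno)
    minor <- pmin(ac[, "ref"], ac[, "alt"])
    gt <- keep_site(gt, minor != 1, "singleton")
  }
  if (nrow(gt$sites) && cfg$max_missing_fraction < 1) {
    miss <- rowMeans(is.na(gt$geno))
    gt <- keep_site(gt, miss <= cfg$max_missing_fraction, "missingness")
  }
  if (nrow(gt$sites) && cfg$min_maf > 0) {
    ac <- called_allele_counts(gt$geno)
    tot <- ac[, "ref"] + ac[, "alt"]
    maf <- ifelse(tot > 0, pmin(ac[, "ref"], ac[, "alt"]) / tot, 0)
    gt <- keep_site(gt, maf >= cfg$min_maf, "maf")
  }

  report <- data.frame(stage = stages, sites_removed = as.integer(removed),
                       stringsAsFactors = FALSE)
  attr(report, "input_sites") <- input_sites
  attr(report, "output_sites") <- nrow(gt$sites)
  attr(report, "genotypes_masked") <- genotypes_masked
  class(report) <- c("filter_report", class(report))
  list(genotypes = gt, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report: %d sites in, %d out (%d genotype calls masked)\n",
              attr(x, "input_sites"), attr(x, "output_sites"),
              attr(x, "genotypes_masked")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Write a filter report as TSV
#' @param report a `filter_report`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_filter_report <- function(report, path) {
  df <- as.data.frame(report)
  df <- rbind(df,
              data.frame(stage = c("input_sites", "output_sites",
                                   "genotypes_masked"),
                         sites_removed = c(attr(report, "input_sites"),
                                           attr(report, "output_sites"),
                                           attr(report, "genotypes_masked"))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
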