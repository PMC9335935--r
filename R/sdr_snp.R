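#' Classify a site as SDR-like (putatively Y-linked)
#'
#' An allele is putatively Y-linked when every male that carries it is
#' heterozygous for it (no male is homozygous for it), at least one male
#' carries it, and it is absent from all called female genotypes. Such
#' alleles are "Y-like", their alternates "X-like", and the sites
#' "SDR-like SNPs". Either the reference or the alternate allele may
#' qualify; the call records which. Sites with fewer than `min_per_sex`
#' called genotypes in either sex are `insufficient_data`. With small
#' samples SDR-like patterns arise by chance on autosomes, which
#' [autosomal_fp_rate()] quantifies.
#'
#' @param male_genotypes,female_genotypes integer genotype vectors coded
#'   `0/1/2/NA`
#' @param min_per_sex minimum called genotypes required per sex
#' @return list with `status` (one of `"sdr_like"`, `"female_specific"`,
#'   `"neither"`, `"insufficient_data"`) and `y_like_allele` (`"ref"`,
#'   `"alt"` or `"none"`)
#' @examples
#' classify_sdr_like(c(1L, 1L, 1L), c(0L, 0L))
#' @export
classify_sdr_like <- function(male_genotypes, female_genotypes,
                              min_per_sex = 2) {
  scan <- sdr_scan_matrix(matrix(as.integer(male_genotypes), nrow = 1),
                          matrix(as.integer(female_genotypes), nrow = 1),
                          min_per_sex = min_per_sex,
                          min_females_carrying = 1)
  if (scan$status[1] == "female_specific") {
    # this entry point only asks the SDR-like question
    return(list(status = "neither", y_like_allele = "none"))
  }
  list(status = scan$status[1], y_like_allele = scan$y_like_allele[1])
}

#' Classify a site as carrying female-restricted alleles
#'
#' A site is female-specific when one allele is carried by at least
#' `min_females_carrying` females and by no male, with at least
#' `min_per_sex` called genotypes in each sex.
#'
#' @inheritParams classify_sdr_like
#' @param min_females_carrying minimum number of females carrying the
#'   allele (1 by default; the restriction criterion is presence in
#'   females and absence from males)
#' @return list with `status` and `y_like_allele = "none"`
#' @export
classify_female_specific <- function(male_genotypes, female_genotypes,
                                     min_per_sex = 2,
                                     min_females_carrying = 1) {
  scan <- sdr_scan_matrix(matrix(as.integer(male_genotypes), nrow = 1),
                          matrix(as.integer(female_genotypes), nrow = 1),
                          min_per_sex = min_per_sex,
                          min_females_carrying = min_females_carrying)
  status <- scan$status[1]
  if (status == "sdr_like") status <- "neither"
  list(status = status, y_like_allele = "none")
}

# vectorised per-site classification over sites x samples matrices.
# For each allele A: carriers/homozygotes per sex from genotype codes.
sdr_scan_matrix <- function(geno_m, geno_f, min_per_sex = 2,
                            min_females_carrying = 1) {
  cnt <- function(g) {
    n0 <- rowSums(g == 0L, na.rm = TRUE)
    n1 <- rowSums(g == 1L, na.rm = TRUE)
    n2 <- rowSums(g == 2L, na.rm = TRUE)
    list(n = n0 + n1 + n2, n0 = n0, n1 = n1, n2 = n2)
  }
  m <- cnt(geno_m); f <- cnt(geno_f)
  enough <- m$n >= min_per_sex & f$n >= min_per_sex

  sdr_for <- function(carriers_m, hom_m, carriers_f) {
    carriers_m >= 1 & hom_m == 0 & carriers_f == 0
  }
  # allele = alt: carriers have code 1 or 2; hom carriers code 2
  sdr_alt <- sdr_for(m$n1 + m$n2, m$n2, f$n1 + f$n2)
  # allele = ref: carriers 0 or 1; hom carriers 0
  sdr_ref <- sdr_for(m$n0 + m$n1, m$n0, f$n0 + f$n1)

  fs_for <- function(carriers_f, carriers_m) {
    carriers_f >= min_females_carrying & carriers_m == 0
  }
  fs_alt <- fs_for(f$n1 + f$n2, m$n1 + m$n2)
  fs_ref <- fs_for(f$n0 + f$n1, m$n0 + m$n1)

  status <- rep("neither", length(enough))
  y_like <- rep("none", length(enough))
  is_sdr <- enough & (sdr_alt | sdr_ref)
  status[is_sdr] <- "sdr_like"
  y_like[enough & sdr_alt] <- "alt"
  y_like[enough & sdr_ref & !sdr_alt] <- "ref"
  status[enough & !is_sdr & (fs_alt | fs_ref)] <- "female_specific"
  status[!enough] <- "insufficient_data"
  list(status = status, y_like_allele = y_like)
}

#' Scan all sites for SDR-like and female-specific SNPs
#'
#' @param gt a filtered [genotype_table()]
#' @param sheet a [sample_sheet()]
#' @param species optional species restriction
#' @param min_per_sex minimum called genotypes per sex
#' @param min_females_carrying see [classify_female_specific()]
#' @return data.frame with columns `chrom`, `pos`, `status`,
#'   `y_like_allele`
#' @export
sdr_snp_scan <- function(gt, sheet, species = NULL, min_per_sex = 2,
                         min_females_carrying = 1) {
  males <- sheet_samples(sheet, species = species, sex = "M")
  females <- sheet_samples(sheet, species = species, sex = "F")
  if (!length(males) || !length(females)) {
    stop_config("need male and female samples")
  }
  scan <- sdr_scan_matrix(gt$geno[, males, drop = FALSE],
                          gt$geno[, females, drop = FALSE],
                          min_per_sex = min_per_sex,
                          min_females_carrying = min_females_carrying)
  data.frame(chrom = gt$sites$chrom, pos = gt$sites$pos,
             status = scan$status, y_like_allele = scan$y_like_allele,
             stringsAsFactors = FALSE)
}

#' Empirical autosomal false-positive rate of the SDR-like classifier
#'
#' Applies the SDR-like scan to autosomal sites -- the internal control:
#' with few samples, autosomal SNPs can match the Y-linked heterozygosity
#' pattern by chance, and this rate calibrates how enriched a true SDR
#' must be.
#'
#' @inheritParams sdr_snp_scan
#' @param autosomes optional chromosome names to restrict to
#' @return fraction of classified autosomal sites with status `sdr_like`
#'   (0, with a warning, for empty input)
#' @export
autosomal_fp_rate <- function(gt, sheet, autosomes = NULL, species = NULL,
                              min_per_sex = 2) {
  if (!is.null(autosomes)) {
    keep <- gt$sites$chrom %in% autosomes
    gt <- subset_genotypes(gt, sites = keep)
  }
  if (!nrow(gt$sites)) {
    warning("no autosomal sites; returning 0")
    return(0)
  }
  calls <- sdr_snp_scan(gt, sheet, species = species,
                        min_per_sex = min_per_sex)
  mean(calls$status == "sdr_like")
}
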