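#' Genotype tables
#'
#' The central container of the pipeline: a sites-by-samples matrix of
#' diploid genotype calls with per-call read depths and per-site metadata.
#' Genotypes are coded as integers: `0` = homozygous reference,
#' `1` = heterozygous, `2` = homozygous alternate, `NA` = missing.
#' All positions are 1-based (VCF convention).
#'
#' Hemizygous males are *not* representable: like the diploid variant
#' callers the pipeline emulates, every call is a diploid genotype, and
#' hemizygosity only enters through the imputation artifact modelled by
#' the simulator.
#'
#' @param sites data.frame with columns `chrom` (character), `pos`
#'   (1-based integer, strictly increasing within each chromosome), `ref`,
#'   `alt` (character; `alt` may temporarily hold comma-separated alleles
#'   for multi-allelic records, which site filters remove) and `qual`
#'   (numeric, `NA` allowed)
#' @param geno integer matrix, `nrow(sites)` x `n samples`, values in
#'   `{0, 1, 2, NA}`; column names are sample ids
#' @param depth integer matrix of the same shape: read depth supporting
#'   each call (non-negative; `0` allowed for missing calls)
#' @return an object of class `genotype_table`
#' @export
genotype_table <- function(sites, geno, depth = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (is.null(depth)) {
    depth <- matrix(NA_integer_, nrow(geno), ncol(geno),
                    dimnames = dimnames(geno))
  }
  depth <- as.matrix(depth)
  storage.mode(depth) <- "integer"
  dimnames(depth) <- dimnames(geno)
  gt <- structure(list(sites = sites, geno = geno, depth = depth),
                  class = "genotype_table")
  validate_genotype_table(gt)
}

#' @rdname genotype_table
#' @param gt object to validate
#' @export
validate_genotype_table <- function(gt) {
  sites <- gt$sites
  need <- c("chrom", "pos", "ref", "alt", "qual")
  if (!all(need %in% names(sites))) {
    stop_data("sites must have columns ", paste(need, collapse = ", "))
  }
  if (nrow(sites) != nrow(gt$geno) || nrow(sites) != nrow(gt$depth)) {
    stop_data("sites, geno and depth must agree in row count")
  }
  if (!identical(dim(gt$geno), dim(gt$depth))) {
    stop_data("geno and depth must have identical dimensions")
  }
  if (is.null(colnames(gt$geno))) stop_data("geno must carry sample ids as colnames")
  if (nrow(sites)) {
    same_ref_alt <- !is.na(sites$ref) & sites$ref == sites$alt
    if (any(same_ref_alt)) stop_data("ref equal to alt at some sites")
    ord <- order(sites$chrom, sites$pos)
    if (!identical(as.integer(ord), seq_len(nrow(sites)))) {
      stop_data("sites must be sorted by chrom then pos")
    }
    dup <- stats::ave(sites$pos, sites$chrom,
                      FUN = function(p) c(FALSE, diff(p) <= 0))
    if (any(dup > 0)) stop_data("pos must be strictly increasing within chrom")
    if (any(gt$depth < 0, na.rm = TRUE)) stop_data("negative depths")
    bad <- gt$geno[!is.na(gt$geno)]
    if (length(bad) && (any(bad < 0) || any(bad > 2))) {
      stop_data("genotype codes must be 0, 1, 2 or NA")
    }
  }
  gt
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d sites x %d samples (%s)\n",
              nrow(x$sites), ncol(x$geno),
              paste(unique(x$sites$chrom), collapse = ", ")))
  invisible(x)
}

#' Number of sites in a genotype table
#' @param gt a [genotype_table()]
#' @return integer
#' @export
n_sites <- function(gt) nrow(gt$sites)

#' Subset a genotype table
#'
#' @param gt a [genotype_table()]
#' @param sites logical or integer index over sites
#' @param samples character vector of sample ids (order is respected)
#' @return a [genotype_table()]
#' @export
subset_genotypes <- function(gt, sites = NULL, samples = NULL) {
  if (is.null(sites)) sites <- seq_len(nrow(gt$sites))
  if (is.null(samples)) samples <- colnames(gt$geno)
  missing_s <- setdiff(samples, colnames(gt$geno))
  if (length(missing_s)) {
    stop_config("samples absent from genotype table: ",
                paste(missing_s, collapse = ", "))
  }
  genotype_table(gt$sites[sites, , drop = FALSE],
                 gt$geno[sites, samples, drop = FALSE],
                 gt$depth[sites, samples, drop = FALSE])
}
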