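#' Per-site Weir & Cockerham variance components between the sexes
#'
#' Computes the Weir & Cockerham (1984) per-locus variance components
#' `a` (among populations), `b` (among individuals within populations)
#' and `c` (within individuals) for two groups -- here males and females
#' of one species, so that theta = a/(a+b+c) measures X--Y
#' differentiation as a proxy. Sites monomorphic across both groups
#' return `(0, 0, 0)` and are flagged non-informative; a group with no
#' called genotype (or a configuration where the estimator's denominators
#' vanish) yields an undefined result.
#'
#' @param male_genotypes,female_genotypes integer genotype vectors coded
#'   `0/1/2/NA` as in [genotype_table()]
#' @return list with `a`, `b`, `c`, `theta`, `informative` (logical) and
#'   `defined` (logical)
#' @examples
#' site_fst_components(c(1L, 1L, 1L), c(0L, 0L, 0L))
#' @export
site_fst_components <- function(male_genotypes, female_genotypes) {
  comp <- wc_components_matrix(
    matrix(as.integer(male_genotypes), nrow = 1),
    matrix(as.integer(female_genotypes), nrow = 1))
  list(a = comp$a[1], b = comp$b[1], c = comp$c[1],
       theta = comp$theta[1],
       informative = comp$informative[1],
       defined = comp$defined[1])
}

# vectorised WC (1984) components for r = 2 groups, over a sites x samples
# genotype matrix per group
wc_components_matrix <- function(geno_m, geno_f) {
  grp <- function(g) {
    n0 <- rowSums(g == 0L, na.rm = TRUE)
    n1 <- rowSums(g == 1L, na.rm = TRUE)
    n2 <- rowSums(g == 2L, na.rm = TRUE)
    n <- n0 + n1 + n2
    list(n = n,
         p = ifelse(n > 0, (2 * n2 + n1) / (2 * n), NA_real_),
         h = ifelse(n > 0, n1 / n, NA_real_))
  }
  m <- grp(geno_m)
  f <- grp(geno_f)
  n1 <- m$n; n2 <- f$n
  nbar <- (n1 + n2) / 2
  # r = 2 populations throughout
  nc <- 2 * nbar - (n1^2 + n2^2) / (2 * nbar)
  pbar <- ifelse(nbar > 0, (n1 * m$p + n2 * f$p) / (2 * nbar), NA_real_)
  s2 <- ifelse(nbar > 0,
               (n1 * (m$p - pbar)^2 + n2 * (f$p - pbar)^2) / nbar, NA_real_)
  hbar <- ifelse(nbar > 0, (n1 * m$h + n2 * f$h) / (2 * nbar), NA_real_)

  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 / 2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2

  defined <- n1 > 0 & n2 > 0 & is.finite(a) & is.finite(b) & is.finite(cc)
  mono <- defined & ((m$p == 0 & f$p == 0) | (m$p == 1 & f$p == 1))
  a[mono] <- 0; b[mono] <- 0; cc[mono] <- 0
  a[!defined] <- NA_real_; b[!defined] <- NA_real_; cc[!defined] <- NA_real_
  denom <- a + b + cc
  theta <- ifelse(defined & !mono & denom != 0, a / denom, NA_real_)
  list(a = a, b = b, c = cc, theta = theta,
       informative = defined & !mono, defined = defined)
}

#' Windowed FST between males and females
#'
#' The per-window estimate is the ratio-of-sums estimator
#' `sum(a) / sum(a + b + c)` over the informative sites falling in each
#' window; windows without informative sites are `NA`. Negative values
#' are reported as computed (not clamped), as the estimator behaves.
#'
#' @param gt a filtered [genotype_table()]
#' @param sheet a [sample_sheet()]
#' @param windows a window data.frame from [make_windows()]
#' @param species optional species restriction for the M/F contrast
#' @return `windows` with columns `fst` and `n_fst_sites` appended
#' @export
window_fst <- function(gt, sheet, windows, species = NULL) {
  males <- sheet_samples(sheet, species = species, sex = "M")
  females <- sheet_samples(sheet, species = species, sex = "F")
  if (!length(males) || !length(females)) {
    stop_config("need at least one male and one female sample")
  }
  comp <- wc_components_matrix(gt$geno[, males, drop = FALSE],
                               gt$geno[, females, drop = FALSE])
  idx <- assign_windows(gt$sites, windows)
  num <- den <- nsite <- numeric(nrow(windows))
  ok <- comp$informative & !is.na(idx)
  if (any(ok)) {
    num <- num + rowsum_by(comp$a[ok], idx[ok], nrow(windows))
    den <- den + rowsum_by(comp$a[ok] + comp$b[ok] + comp$c[ok], idx[ok],
                           nrow(windows))
    nsite <- nsite + rowsum_by(rep(1, sum(ok)), idx[ok], nrow(windows))
  }
  windows$fst <- ifelse(nsite > 0 & den != 0, num / den, NA_real_)
  windows$n_fst_sites <- as.integer(nsite)
  windows
}

# sum of x by integer window index, returning a dense vector of length nw
rowsum_by <- function(x, idx, nw) {
  out <- numeric(nw)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

# map sites to 0-based half-open windows; NA when outside every window
assign_windows <- function(sites, windows) {
  idx <- rep(NA_integer_, nrow(sites))
  for (ch in unique(windows$chrom)) {
    w <- windows[windows$chrom == ch, , drop = FALSE]
    on_ch <- which(sites$chrom == ch)
    if (!length(on_ch)) next
    # pos is 1-based; windows are 0-based half-open
    p0 <- sites$pos[on_ch] - 1L
    j <- findInterval(p0, w$start)
    inside <- j >= 1 & p0 < w$end[pmax(j, 1)]
    idx[on_ch[inside]] <- which(windows$chrom == ch)[j[inside]]
  }
  idx
}
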