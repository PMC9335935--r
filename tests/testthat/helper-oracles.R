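# Independent oracles and fixture builders used across the suite.

# Weir & Cockerham (1984) variance components via the nested-ANOVA
# mean-squares route: an algebraically different transcription of the
# estimator than the package's direct formulas. Two populations (males,
# females); genotypes coded 0/1/2/NA.
wc_anova_oracle <- function(male, female) {
  g <- c(male, female)
  pop <- rep(c(1, 2), c(length(male), length(female)))
  keep <- !is.na(g)
  g <- g[keep]; pop <- pop[keep]
  n_i <- tabulate(pop, 2)
  if (any(n_i == 0)) return(list(a = NA_real_, b = NA_real_, c = NA_real_,
                                 theta = NA_real_))
  y <- unlist(lapply(g, function(x) switch(x + 1, c(0, 0), c(0, 1), c(1, 1))))
  ind <- rep(seq_along(g), each = 2)
  popa <- rep(pop, each = 2)
  N <- length(g); r <- 2
  ybar <- mean(y)
  ybar_i <- tapply(y, popa, mean)
  ybar_ij <- tapply(y, ind, mean)
  SSP <- sum(2 * n_i * (ybar_i - ybar)^2)
  SSI <- sum(2 * (ybar_ij - ybar_i[pop])^2)
  SSG <- sum((y - ybar_ij[ind])^2)
  MSP <- SSP / (r - 1)
  MSI <- SSI / (N - r)
  MSG <- SSG / N
  nc <- (N - sum(n_i^2) / N) / (r - 1)
  a <- (MSP - MSI) / (2 * nc)
  b <- (MSI - MSG) / 2
  cc <- MSG
  list(a = a, b = b, c = cc, theta = a / (a + b + cc))
}

# empirical quantile with linear interpolation between order statistics,
# written from the h = (n - 1) p + 1 definition
quantile_oracle <- function(x, p) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  sapply(p, function(pp) {
    h <- (n - 1) * pp + 1
    lo <- floor(h)
    if (lo >= n) return(x[n])
    x[lo] + (h - lo) * (x[lo + 1] - x[lo])
  })
}

# exact probability that a site with Hardy-Weinberg genotypes at allele
# frequency p looks SDR-like, by enumerating every genotype combination;
# the qualifying condition is written directly from the definition (an
# allele seen in males only in heterozygotes, absent from females),
# independently of the package's matrix logic
sdr_like_prob_oracle <- function(p, n_m, n_f) {
  gprob <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  combos <- expand.grid(rep(list(0:2), n_m + n_f))
  pr_tot <- 0
  for (k in seq_len(nrow(combos))) {
    g <- as.integer(combos[k, ])
    m <- g[seq_len(n_m)]; f <- g[n_m + seq_len(n_f)]
    ok_alt <- any(m >= 1) && !any(m == 2) && all(f == 0)
    ok_ref <- any(m <= 1) && !any(m == 0) && all(f == 2)
    if (ok_alt || ok_ref) pr_tot <- pr_tot + prod(gprob[g + 1])
  }
  pr_tot
}

# tiny multi-sample VCF written as text; used by the I/O tests
write_toy_vcf <- function(path, records,
                          samples = c("m1", "f1")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, records), path)
  path
}

# a small genotype table built directly, bypassing VCF parsing
toy_table <- function(geno, depth = NULL, chrom = "chr1",
                      ref = NULL, alt = NULL, qual = NULL) {
  geno <- as.matrix(geno)
  if (is.null(colnames(geno))) {
    colnames(geno) <- paste0("s", seq_len(ncol(geno)))
  }
  n <- nrow(geno)
  sites <- data.frame(
    chrom = chrom, pos = seq_len(n) * 100L,
    ref = ref %||% rep("A", n), alt = alt %||% rep("T", n),
    qual = qual %||% rep(50, n), stringsAsFactors = FALSE)
  if (is.null(depth)) depth <- matrix(30L, n, ncol(geno),
                                      dimnames = dimnames(geno))
  genotype_table(sites, geno, depth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
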