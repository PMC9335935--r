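#' Tile a chromosome with non-overlapping windows
#'
#' Windows are BED-style 0-based half-open intervals of the requested
#' width tiling each chromosome end to end (the last window may be
#' short).
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp
#' @param width window width in bp (10 kb for read-depth comparisons,
#'   100 kb for the SNP-based statistics, by convention)
#' @return data.frame with columns `chrom`, `start`, `end`
#' @export
make_windows <- function(chrom_lengths, width) {
  stopifnot(width > 0, !is.null(names(chrom_lengths)))
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    start <- seq(0, len - 1, by = width)
    data.frame(chrom = ch, start = start, end = pmin(start + width, len),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Read / write a per-window, per-sample depth table
#'
#' Long-format table with one row per (window, sample): columns `chrom`,
#' `start`, `end`, `sample_id`, `depth` (mean reads per bp).
#'
#' @param path TSV path
#' @return data.frame
#' @export
read_depth_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  need <- c("chrom", "start", "end", "sample_id", "depth")
  if (!all(need %in% names(df))) {
    stop_data("depth table must have columns ", paste(need, collapse = ", "))
  }
  if (any(df$depth < 0, na.rm = TRUE)) stop_data("negative depths")
  df
}

#' Per-window male:female read-depth ratio
#'
#' Each sample's window depths are first normalised by that sample's mean
#' depth over autosomal windows, so library-size differences cancel; the
#' statistic is then (mean over males) / (mean over females) of the
#' normalised depths. A fully degenerate (deleted) Y halves male depth and
#' drives the ratio towards 0.5. Set `normalize = FALSE` for raw fold
#' coverage.
#'
#' @param depth a long depth table (see [read_depth_table()])
#' @param sheet a [sample_sheet()]
#' @param autosomes character vector of autosome chromosome names used for
#'   normalisation
#' @param species optional species restriction
#' @param normalize normalise by per-sample autosome-wide mean depth
#' @return data.frame of windows with `depth_ratio` (NA, with a warning
#'   tally, where the female mean is zero)
#' @export
depth_ratio_windows <- function(depth, sheet, autosomes, species = NULL,
                                normalize = TRUE) {
  males <- sheet_samples(sheet, species = species, sex = "M")
  females <- sheet_samples(sheet, species = species, sex = "F")
  if (!length(males) || !length(females)) {
    stop_config("need at least one male and one female sample")
  }
  used <- depth$sample_id %in% c(males, females)
  depth <- depth[used, , drop = FALSE]
  if (normalize) {
    auto <- depth[depth$chrom %in% autosomes, , drop = FALSE]
    if (!nrow(auto)) stop_config("no autosomal windows available for normalisation")
    means <- tapply(auto$depth, auto$sample_id, mean, na.rm = TRUE)
    if (any(is.na(means) | means == 0)) {
      stop_data("sample with zero or undefined autosomal mean depth")
    }
    depth$depth <- depth$depth / as.numeric(means[depth$sample_id])
  }
  key <- paste(depth$chrom, depth$start, depth$end, sep = "\r")
  is_m <- depth$sample_id %in% males
  mean_m <- tapply(depth$depth[is_m], key[is_m], mean, na.rm = TRUE)
  mean_f <- tapply(depth$depth[!is_m], key[!is_m], mean, na.rm = TRUE)
  ukey <- unique(key)
  parts <- do.call(rbind, strsplit(ukey, "\r", fixed = TRUE))
  out <- data.frame(chrom = parts[, 1], start = as.numeric(parts[, 2]),
                    end = as.numeric(parts[, 3]), stringsAsFactors = FALSE)
  mm <- as.numeric(mean_m[ukey])
  ff <- as.numeric(mean_f[ukey])
  out$depth_ratio <- ifelse(!is.na(ff) & ff > 0 & !is.na(mm), mm / ff,
                            NA_real_)
  n_undef <- sum(is.na(out$depth_ratio))
  if (n_undef) {
    warning(sprintf("%d windows with undefined depth ratio", n_undef))
  }
  out[order(out$chrom, out$start), , drop = FALSE]
}

# sites polymorphic within a set of samples: both alleles seen among
# called genotypes
polymorphic_within <- function(geno) {
  ac <- called_allele_counts(geno)
  ac[, "ref"] > 0 & ac[, "alt"] > 0
}

#' Per-window male:female SNP density ratio
#'
#' Counts, per window, sites polymorphic among the male samples and sites
#' polymorphic among the female samples ("polymorphic within sex": both
#' alleles observed among that sex's called genotypes), and reports their
#' ratio; windows with no female-polymorphic site are `NA`.
#'
#' @inheritParams window_fst
#' @return `windows` with columns `n_male_poly`, `n_female_poly`,
#'   `snp_density_ratio` appended
#' @export
snp_density_ratio_windows <- function(gt, sheet, windows, species = NULL) {
  males <- sheet_samples(sheet, species = species, sex = "M")
  females <- sheet_samples(sheet, species = species, sex = "F")
  if (!length(males) || !length(females)) {
    stop_config("need at least one male and one female sample")
  }
  poly_m <- polymorphic_within(gt$geno[, males, drop = FALSE])
  poly_f <- polymorphic_within(gt$geno[, females, drop = FALSE])
  idx <- assign_windows(gt$sites, windows)
  nw <- nrow(windows)
  cm <- rowsum_by(as.numeric(poly_m[!is.na(idx)]), idx[!is.na(idx)], nw)
  cf <- rowsum_by(as.numeric(poly_f[!is.na(idx)]), idx[!is.na(idx)], nw)
  windows$n_male_poly <- as.integer(cm)
  windows$n_female_poly <- as.integer(cf)
  windows$snp_density_ratio <- ifelse(cf > 0, cm / cf, NA_real_)
  windows
}

#' Assemble the five-statistic window table
#'
#' Runs the SNP-based window statistics (FST, SNP density ratio, SDR-like
#' SNP density, female-specific SNP density) at one window width over one
#' genotype table, plus site counts. Read-depth ratios live on their own
#' (typically finer) window grid; see [depth_ratio_windows()].
#'
#' @inheritParams window_fst
#' @param min_per_sex minimum called genotypes per sex for the per-site
#'   SDR-like / female-specific classification
#' @return `windows` with statistic columns appended
#' @export
window_stat_table <- function(gt, sheet, windows, species = NULL,
                              min_per_sex = 2) {
  windows <- window_fst(gt, sheet, windows, species = species)
  windows <- snp_density_ratio_windows(gt, sheet, windows, species = species)
  calls <- sdr_snp_scan(gt, sheet, species = species,
                        min_per_sex = min_per_sex)
  idx <- assign_windows(gt$sites, windows)
  nw <- nrow(windows)
  ok <- !is.na(idx)
  windows$sdr_like_density <- as.integer(
    rowsum_by(as.numeric(calls$status[ok] == "sdr_like"), idx[ok], nw))
  windows$female_specific_density <- as.integer(
    rowsum_by(as.numeric(calls$status[ok] == "female_specific"), idx[ok], nw))
  windows$n_sites <- as.integer(rowsum_by(rep(1, sum(ok)), idx[ok], nw))
  windows
}

# core empirical quantile convention: linear interpolation between order
# statistics (R type 7)
envelope_quantiles <- function(x, probs = c(0.025, 0.975)) {
  x <- x[!is.na(x)]
  stats::quantile(x, probs = probs, type = 7, names = FALSE)
}

#' Autosomal envelope of a window statistic
#'
#' Empirical 2.5% and 97.5% quantiles of each statistic over autosomal
#' windows, the null band against which sex-chromosome windows are judged.
#' By construction about 5% of autosomal windows themselves fall outside
#' the band. Quantiles use linear interpolation between order statistics.
#'
#' @param stats_df a window table restricted to autosomes
#' @param statistics names of statistic columns
#' @param min_windows minimum number of defined windows required per
#'   statistic
#' @return data.frame with columns `statistic`, `lower`, `upper`,
#'   `n_windows`
#' @export
autosomal_envelope <- function(stats_df,
                               statistics = c("fst", "snp_density_ratio",
                                              "sdr_like_density",
                                              "female_specific_density"),
                               min_windows = 40) {
  out <- lapply(statistics, function(s) {
    if (!s %in% names(stats_df)) stop_config("no column ", s)
    v <- stats_df[[s]]
    v <- v[!is.na(v)]
    if (length(v) < min_windows) {
      stop_data(sprintf(
        "only %d defined autosomal windows for %s (need >= %d); simulate or supply more autosome",
        length(v), s, min_windows))
    }
    q <- envelope_quantiles(v)
    data.frame(statistic = s, lower = q[1], upper = q[2],
               n_windows = length(v), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Fraction of windows outside an envelope
#'
#' @param values numeric window values (NA ignored)
#' @param lower,upper envelope bounds
#' @return fraction of defined values strictly outside `[lower, upper]`
#' @export
fraction_outside_envelope <- function(values, lower, upper) {
  v <- values[!is.na(values)]
  if (!length(v)) return(NA_real_)
  mean(v < lower | v > upper)
}

#' Tricube local linear smoother
#'
#' Locally weighted linear regression (tricube kernel) evaluated at the
#' input positions, the smoother drawn as trend curves over window
#' statistics. For each point, the `floor(span * n)` nearest neighbours
#' receive tricube weights on distance scaled by the furthest included
#' neighbour; a weighted least-squares line is then evaluated at the
#' point. Matches `stats::loess(degree = 1, surface = "direct")`.
#' Reporting-only: smoothed values never feed classification.
#'
#' @param x numeric positions
#' @param y numeric values (NA pairs dropped)
#' @param span neighbourhood fraction in (0, 1]
#' @return numeric vector of smoothed values aligned with `x` (NA where
#'   `y` was NA); if fewer than 10 defined points, `y` is returned
#'   unchanged with a warning
#' @export
smooth_series <- function(x, y, span = 0.3) {
  stopifnot(length(x) == length(y), span > 0, span <= 1)
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 10) {
    warning("fewer than 10 defined points; returning input unsmoothed")
    return(y)
  }
  xs <- x[ok]; ys <- y[ok]
  n <- length(xs)
  q <- max(2L, as.integer(floor(span * n)))
  fit <- vapply(seq_len(n), function(i) {
    d <- abs(xs - xs[i])
    dq <- sort(d, partial = q)[q]
    if (dq == 0) return(mean(ys[d == 0]))
    w <- pmax(0, 1 - (d / dq)^3)^3
    stats::lm.wfit(cbind(1, xs - xs[i]), ys, w)$coefficients[1]
  }, numeric(1))
  out <- rep(NA_real_, length(y))
  out[ok] <- fit
  out
}
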