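#' Configuration for an end-to-end run
#'
#' Inputs may be given as file paths (VCF, sample-sheet TSV, depth TSV)
#' or as the in-memory objects a [simulate_scenario()] bundle provides.
#'
#' @param vcf VCF path or a [genotype_table()]
#' @param sheet sample-sheet TSV path or a [sample_sheet()]
#' @param depth depth-table TSV path, a long depth data.frame, or `NULL`
#'   to skip the read-depth statistic
#' @param filter a [filter_config()]
#' @param sex_chrom name of the chromosome of interest
#' @param autosomes character vector of autosome names (disjoint from
#'   `sex_chrom`)
#' @param focal_species species for the male/female window statistics
#'   (default: first species in the sheet with called males and females)
#' @param width_depth window width for the read-depth ratio (default
#'   10 kb)
#' @param width_other window width for the SNP-based statistics (default
#'   100 kb)
#' @param outdir optional output directory for TSV/YAML reports
#' @param seed integer seed recorded in the report
#' @return a `run_config` list
#' @export
run_config <- function(vcf, sheet, depth = NULL, filter = filter_config(),
                       sex_chrom, autosomes, focal_species = NULL,
                       width_depth = 1e4, width_other = 1e5,
                       outdir = NULL, seed = 1) {
  if (sex_chrom %in% autosomes) {
    stop_config("sex_chrom and autosomes must be disjoint")
  }
  for (p in list(vcf, sheet, depth)) {
    if (is.character(p) && length(p) == 1 && !file.exists(p)) {
      stop_config("missing file: ", p)
    }
  }
  structure(list(vcf = vcf, sheet = sheet, depth = depth, filter = filter,
                 sex_chrom = sex_chrom, autosomes = autosomes,
                 focal_species = focal_species, width_depth = width_depth,
                 width_other = width_other, outdir = outdir, seed = seed),
            class = "run_config")
}

#' Run the full divergence-and-history pipeline
#'
#' Site filters, the five sliding-window male/female divergence
#' statistics (read-depth ratio on the fine window grid; FST, SNP density
#' ratio, SDR-like and female-specific SNP densities on the coarse grid)
#' with autosomal envelopes, the per-site SDR-like scan with its
#' autosomal false-positive control, the gametolog tree-sharing
#' classification, and the hypothesis summary. Per-stage site counts are
#' logged; if the sample sheet cannot support the tree-sharing analysis
#' (e.g. autosome-only cohorts), that stage reports zero informative
#' sites rather than failing.
#'
#' @param cfg a [run_config()]
#' @return a `run_report` list: `filter_report`, `windows_depth`,
#'   `windows_stats`, `envelopes`, `sdr_calls`, `autosomal_fp_rate`,
#'   `treeshare`, `hypotheses`, `log`
#' @export
run_full <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  sheet <- if (is.character(cfg$sheet)) read_sample_sheet(cfg$sheet) else
    validate_sample_sheet(cfg$sheet)
  gt <- if (is.character(cfg$vcf)) read_vcf(cfg$vcf, sheet) else
    validate_genotype_table(cfg$vcf)
  depth <- if (is.character(cfg$depth)) read_depth_table(cfg$depth) else
    cfg$depth

  log <- list()
  note <- function(stage, n) log[[length(log) + 1]] <<- data.frame(
    stage = stage, sites = n, stringsAsFactors = FALSE)
  note("input", nrow(gt$sites))

  flt <- apply_site_filters(gt, cfg$filter)
  gt <- flt$genotypes
  note("filtered", nrow(gt$sites))

  focal <- cfg$focal_species
  if (is.null(focal)) {
    for (sp in unique(sheet$species)) {
      if (length(sheet_samples(sheet, sp, "M")) &&
          length(sheet_samples(sheet, sp, "F"))) { focal <- sp; break }
    }
  }
  if (is.null(focal)) stop_config("no species with both sexes in the sheet")

  chrom_max <- tapply(gt$sites$pos, gt$sites$chrom, max)
  lens <- stats::setNames(as.numeric(chrom_max), names(chrom_max))
  win <- make_windows(lens, cfg$width_other)
  stats_tab <- window_stat_table(gt, sheet, win, species = focal)
  note("windows", nrow(stats_tab))

  env <- tryCatch(
    autosomal_envelope(stats_tab[stats_tab$chrom %in% cfg$autosomes, ]),
    error = function(e) { warning(conditionMessage(e)); NULL })

  win_depth <- NULL
  if (!is.null(depth)) {
    win_depth <- depth_ratio_windows(depth, sheet, cfg$autosomes,
                                     species = focal)
  }

  sdr_calls <- sdr_snp_scan(gt, sheet, species = focal)
  fp <- autosomal_fp_rate(gt, sheet, autosomes = cfg$autosomes,
                          species = focal)
  note("sdr_like_sites", sum(sdr_calls$status == "sdr_like"))

  ts <- tryCatch(run_treeshare(gt, sheet),
                 error = function(e) {
                   if (inherits(e, "sdrscan_config_error")) NULL else stop(e)
                 })
  if (is.null(ts)) {
    ts <- structure(list(sites = data.frame(), counts = stats::setNames(
      integer(10), paste0("n", 1:10)), reasons = table(character(0)),
      n_total = 0L, n_informative = 0L), class = "treeshare_result")
  }
  note("informative_sites", ts$n_informative)
  hyp <- suppressWarnings(summarize_hypotheses(ts))

  report <- structure(list(filter_report = flt$report,
                           windows_depth = win_depth,
                           windows_stats = stats_tab,
                           envelopes = env,
                           sdr_calls = sdr_calls,
                           autosomal_fp_rate = fp,
                           treeshare = ts,
                           hypotheses = hyp,
                           focal_species = focal,
                           log = do.call(rbind, log)),
                      class = "run_report")
  if (!is.null(cfg$outdir)) write_run_report(report, cfg)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report (focal species:", x$focal_species, ")\n")
  print(x$log, row.names = FALSE)
  cat("verdict:", x$hypotheses$verdict, "\n")
  invisible(x)
}

# write every tabular output with a provenance header
write_run_report <- function(report, cfg) {
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(df, name) {
    if (!is.null(df)) {
      write_tsv_with_header(df, file.path(cfg$outdir, name),
                            config = unclass(cfg))
    }
  }
  out(as.data.frame(report$filter_report), "filter_report.tsv")
  out(report$windows_stats, "window_stats.tsv")
  out(report$windows_depth, "window_depth_ratio.tsv")
  out(report$envelopes, "autosomal_envelopes.tsv")
  out(report$sdr_calls, "sdr_snp_calls.tsv")
  out(report$treeshare$sites, "treeshare_sites.tsv")
  out(data.frame(tree = names(report$treeshare$counts),
                 count = as.integer(report$treeshare$counts)),
      "treeshare_counts.tsv")
  out(report$log, "stage_log.tsv")
  yaml::write_yaml(list(
    verdict = report$hypotheses$verdict,
    turnover_wingei_flag = report$hypotheses$turnover_wingei_flag,
    decision_rule = report$hypotheses$decision_rule,
    fractions = as.list(report$hypotheses$fractions),
    autosomal_fp_rate = report$autosomal_fp_rate,
    n_informative = report$treeshare$n_informative,
    n_total = report$treeshare$n_total,
    seed = cfg$seed),
    file.path(cfg$outdir, "summary.yaml"))
  invisible(cfg$outdir)
}
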