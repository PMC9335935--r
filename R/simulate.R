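#' Scenario configuration for the sex-chromosome history simulator
#'
#' Describes one generative scenario for the four-gametolog system
#' (`Xp`/`Yp` = M. picta X/Y, `Xw`/`Yw` = P. wingei X/Y, plus two
#' outgroups). Times are in arbitrary coalescent-style units; only
#' relative branch lengths matter for allele-sharing patterns, so the
#' defaults are stated modelling choices, not biological estimates.
#'
#' Scenarios: `"homologous"` (one ancestral SDR older than the species
#' split), `"independent"` (recombination suppressed separately in each
#' lineage after the split), `"turnover_wingei"` (ancestral SDR retained
#' in picta; a new wingei Y derived from the X at `t_to`), `"autosome"`
#' (no sex linkage anywhere).
#'
#' @param scenario one of `"homologous"`, `"independent"`,
#'   `"turnover_wingei"`, `"autosome"`
#' @param t_s species split time
#' @param t_sdr ancestral SDR origin (> `t_s`; homologous / turnover)
#' @param t_p,t_w per-species SDR origins (< `t_s`; independent)
#' @param t_to turnover time (< `t_s`; turnover_wingei)
#' @param alpha male-bias mutation multiplier applied to Y-transmitted
#'   branches (>= 1 under male-biased mutation)
#' @param p_homoplasy per-site probability of a second, recurrent
#'   mutation on another branch (0 disables; artifacts "off")
#' @param d_p,d_w per-site probability that an SDR site is deleted on the
#'   picta / wingei Y; at deleted sites every male of that species is
#'   imputed homozygous for his X allele and his depth contribution
#'   halves (the diploid-caller hemizygosity artifact)
#' @param map_fail additional Y-read mapping-failure rate thinning male
#'   depth in SDR windows
#' @param eps per-genotype error rate (one allele flipped)
#' @param lambda mean sequencing depth in reads per bp
#' @param lib_sigma lognormal sd of per-sample library-size multipliers
#' @param samples named list of sample counts: focal species as
#'   `c(M = , F = )`, outgroups as single integers
#' @param sex_chrom,chrom_len sex chromosome name and length (bp)
#' @param sdr integer length-2 vector: SDR interval (1-based, inclusive)
#' @param autosomes named vector of autosome lengths (bp)
#' @param n_sdr_sites,n_par_sites,n_auto_sites segregating-site counts:
#'   in the SDR, in the recombining remainder of the sex chromosome, and
#'   per autosome
#' @param window_width depth-window width (bp)
#' @param beta_shape shape of the symmetric Beta allele-frequency
#'   distribution at recombining sites
#' @param seed master integer seed; per-site substreams are derived from
#'   it by counter, so enlarging a simulation never perturbs earlier
#'   sites
#' @return a `scenario_config` list
#' @export
scenario_config <- function(scenario = c("homologous", "independent",
                                         "turnover_wingei", "autosome"),
                            t_s = 1, t_sdr = 2, t_p = 0.5, t_w = 0.5,
                            t_to = 0.5, alpha = 1, p_homoplasy = 0,
                            d_p = 0, d_w = 0, map_fail = 0, eps = 0,
                            lambda = 30, lib_sigma = 0.1,
                            samples = list(wingei = c(M = 3, F = 3),
                                           picta = c(M = 3, F = 3),
                                           latipinna = 1, holbrooki = 1),
                            sex_chrom = "chr12", chrom_len = 6e6,
                            sdr = c(1500001, 4500000),
                            autosomes = c(chr1 = 6e6, chr2 = 6e6),
                            n_sdr_sites = 3000, n_par_sites = 800,
                            n_auto_sites = 1500, window_width = 1e4,
                            beta_shape = 0.5, seed = 1) {
  scenario <- match.arg(scenario)
  cfg <- structure(as.list(environment()), class = "scenario_config")
  validate_scenario_config(cfg)
}

#' @rdname scenario_config
#' @param cfg a `scenario_config`
#' @export
validate_scenario_config <- function(cfg) {
  with(cfg, {
    if (any(c(t_s, t_sdr, t_p, t_w, t_to) <= 0)) {
      stop_config("all times must be > 0")
    }
    if (scenario %in% c("homologous", "turnover_wingei") && t_sdr <= t_s) {
      stop_config("t_sdr must exceed t_s for scenario ", scenario)
    }
    if (scenario == "independent" && (t_p >= t_s || t_w >= t_s)) {
      stop_config("t_p and t_w must be below t_s for the independent scenario")
    }
    if (scenario == "turnover_wingei" && t_to >= t_s) {
      stop_config("t_to must be below t_s")
    }
    for (x in c(p_homoplasy, d_p, d_w, map_fail, eps)) {
      if (x < 0 || x > 1) stop_config("rates and fractions must be in [0, 1]")
    }
    if (sdr[1] < 1 || sdr[2] > chrom_len || sdr[1] >= sdr[2]) {
      stop_config("SDR interval outside the sex chromosome")
    }
    if (alpha <= 0 || lambda <= 0 || window_width <= 0) {
      stop_config("alpha, lambda and window_width must be positive")
    }
  })
  cfg
}

#' Read / write a scenario configuration as YAML
#' @param path YAML file path
#' @return a validated `scenario_config`
#' @export
read_scenario_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$samples)) {
    raw$samples <- lapply(raw$samples, function(s) {
      if (length(s) > 1 || is.list(s)) unlist(s) else s
    })
  }
  if (!is.null(raw$autosomes)) raw$autosomes <- unlist(raw$autosomes)
  if (!is.null(raw$sdr)) raw$sdr <- unlist(raw$sdr)
  do.call(scenario_config, raw)
}

#' @rdname read_scenario_config
#' @param cfg a `scenario_config`
#' @export
write_scenario_config <- function(cfg, path) {
  to_yaml <- function(x) {
    if (is.list(x)) {
      lapply(x, to_yaml)
    } else if (is.numeric(x) && !is.null(names(x))) {
      as.list(x)
    } else {
      x
    }
  }
  yaml::write_yaml(lapply(unclass(cfg), to_yaml), path)
  invisible(path)
}

#' The rooted four-gametolog tree of a scenario
#'
#' Returns the branch set of the rooted tree over `Xp`, `Yp`, `Xw`, `Yw`
#' implied by a scenario's event times: one row per branch with the
#' subset of tips below it, its length, and whether it is Y-transmitted
#' (and so carries the `alpha` mutation-rate multiplier). Mutations on
#' branches with 2-3 tips below produce topologically informative
#' allele-sharing patterns; terminal-branch mutations are private to one
#' chromosome.
#'
#' @param cfg a [scenario_config()] with `scenario != "autosome"`
#' @return data.frame with columns `branch`, `tips` (pattern key),
#'   `length`, `y_linked`, `internal`
#' @export
scenario_tree <- function(cfg) {
  if (cfg$scenario == "autosome") {
    stop_config("the autosome scenario has no gametolog tree")
  }
  br <- function(branch, tips, len, y_linked) {
    data.frame(branch = branch, tips = pattern_key(tips), length = len,
               y_linked = y_linked, internal = length(tips) %in% c(2, 3),
               stringsAsFactors = FALSE)
  }
  rows <- switch(cfg$scenario,
    homologous = list(
      # ((Yp,Yw),(Xp,Xw)): X-Y split at t_sdr, species splits at t_s
      br("Y_stem", c("Yp", "Yw"), cfg$t_sdr - cfg$t_s, TRUE),
      br("X_stem", c("Xp", "Xw"), cfg$t_sdr - cfg$t_s, FALSE),
      br("Yp", "Yp", cfg$t_s, TRUE),
      br("Yw", "Yw", cfg$t_s, TRUE),
      br("Xp", "Xp", cfg$t_s, FALSE),
      br("Xw", "Xw", cfg$t_s, FALSE)),
    independent = list(
      # ((Xp,Yp),(Xw,Yw)): root at the species split; suppression at
      # t_p / t_w; the stems are X-transmitted (recombining) lineages
      br("picta_stem", c("Xp", "Yp"), cfg$t_s - cfg$t_p, FALSE),
      br("wingei_stem", c("Xw", "Yw"), cfg$t_s - cfg$t_w, FALSE),
      br("Xp", "Xp", cfg$t_p, FALSE),
      br("Yp", "Yp", cfg$t_p, TRUE),
      br("Xw", "Xw", cfg$t_w, FALSE),
      br("Yw", "Yw", cfg$t_w, TRUE)),
    turnover_wingei = list(
      # (((Xw,Yw),Xp),Yp): ancestral SDR at t_sdr kept in picta; the
      # wingei Y re-derived from the X at t_to
      br("Yp", "Yp", cfg$t_sdr, TRUE),
      br("X_lineage_stem", c("Xp", "Xw", "Yw"), cfg$t_sdr - cfg$t_s, FALSE),
      br("Xp", "Xp", cfg$t_s, FALSE),
      br("wingei_XY_stem", c("Xw", "Yw"), cfg$t_s - cfg$t_to, FALSE),
      br("Xw", "Xw", cfg$t_to, FALSE),
      br("Yw", "Yw", cfg$t_to, TRUE)))
  do.call(rbind, rows)
}

#' Expected tree fractions from the scenario tree
#'
#' The analytic oracle for recovery tests: with artifacts off, a site is
#' informative iff its mutation fell on an internal (2-3 tip) branch, and
#' the expected fraction of informative sites showing each tree is
#' proportional to that branch's mutation weight, `length * alpha` on
#' Y-transmitted branches and `length` otherwise.
#'
#' @param cfg a [scenario_config()], `scenario != "autosome"`
#' @param map topology table (see [tree_topologies()])
#' @return named numeric vector `tree1..tree10` summing to 1
#' @export
expected_internal_fractions <- function(cfg, map = tree_topologies()) {
  tr <- scenario_tree(cfg)
  tr$weight <- tr$length * ifelse(tr$y_linked, cfg$alpha, 1)
  internal <- tr[tr$internal, , drop = FALSE]
  out <- stats::setNames(numeric(10), paste0("tree", 1:10))
  ids <- map$tree_id[match(internal$tips, map$pattern)]
  out[ids] <- internal$weight / sum(internal$weight)
  out
}

# ---- simulation ----------------------------------------------------------

sim_sheet <- function(cfg) {
  rows <- list()
  for (sp in names(cfg$samples)) {
    s <- cfg$samples[[sp]]
    if (!is.null(names(s)) && all(c("M", "F") %in% names(s))) {
      for (sex in c("M", "F")) {
        k <- s[[sex]]
        if (k > 0) {
          rows[[length(rows) + 1]] <- data.frame(
            sample_id = sprintf("%s_%s%d", sp, sex, seq_len(k)),
            species = sp, sex = sex, stringsAsFactors = FALSE)
        }
      }
    } else if (s > 0) {
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = sprintf("%s_%d", sp, seq_len(s)),
        species = sp, sex = "unknown", stringsAsFactors = FALSE)
    }
  }
  validate_sample_sheet(do.call(rbind, rows))
}

# sorted distinct positions within [lo, hi], under a derived seed.
# Layer keys are negative so they can never collide with the per-site
# substreams, which are keyed by segment offset plus position.
sim_positions <- function(seed, k, n, lo, hi) {
  set.seed(derive_seed(seed, k))
  sort(sample(seq.int(lo, hi), n, replace = FALSE))
}

# per-site substream key: segments are spaced far beyond any chromosome
# length so each (segment, position) pair owns one stream
site_key <- function(seg, pos) seg * 2^26 + pos

#' Simulate genotypes, depths and truth under one scenario
#'
#' Places one mutation per SDR segregating site on a branch of the
#' scenario tree (probability proportional to branch length, times
#' `alpha` on Y-transmitted branches), optionally a second homoplastic
#' hit on another branch, and assembles diploid genotypes: females X/X,
#' males X/Y, with fixed per-species gametolog alleles inside the SDR.
#' Recombining (PAR) and autosomal sites draw a shared allele frequency
#' from a symmetric Beta and Hardy-Weinberg genotypes with X and Y
#' exchangeable. Artifact layers: per-genotype error `eps`; Y deletions
#' (`d_p`, `d_w`) at which males of the species are imputed homozygous
#' for their X allele and their site depth halves; mapping failure
#' thinning male depth in SDR windows. Per-window sample depths are
#' Poisson draws at rate `lambda * copies / 2`, scaled by per-sample
#' library-size multipliers. Everything is deterministic under `seed`.
#'
#' @param cfg a [scenario_config()]
#' @return a `scenario_bundle` list: `genotypes` (a [genotype_table()]),
#'   `sheet`, `depth` (long window-depth table), `truth` (per-site truth
#'   data.frame), `config`
#' @export
simulate_scenario <- function(cfg) {
  cfg <- validate_scenario_config(cfg)
  sheet <- sim_sheet(cfg)
  n_samp <- nrow(sheet)
  bases <- c("A", "C", "G", "T")
  has_sdr <- cfg$scenario != "autosome"
  tr <- if (has_sdr) scenario_tree(cfg) else NULL
  if (has_sdr) tr$weight <- tr$length * ifelse(tr$y_linked, cfg$alpha, 1)

  picta_m <- sheet$species == "picta" & sheet$sex == "M"
  picta_f <- sheet$species == "picta" & sheet$sex == "F"
  wingei_m <- sheet$species == "wingei" & sheet$sex == "M"
  wingei_f <- sheet$species == "wingei" & sheet$sex == "F"
  focal_m <- picta_m | wingei_m

  # --- SDR sites: one (or two) mutations on the scenario tree ---
  sdr_list <- NULL
  if (has_sdr && cfg$n_sdr_sites > 0) {
    n <- cfg$n_sdr_sites
    pos <- sim_positions(cfg$seed, -11, n, cfg$sdr[1], cfg$sdr[2])
    hit <- matrix(FALSE, n, 4, dimnames = list(NULL, c("Xp", "Yp", "Xw", "Yw")))
    branch1 <- branch2 <- rep(NA_character_, n)
    del_p <- del_w <- logical(n)
    ref <- alt <- character(n)
    tipsets <- strsplit(tr$tips, "+", fixed = TRUE)
    for (i in seq_len(n)) {
      set.seed(derive_seed(cfg$seed, site_key(0, pos[i])))
      b1 <- sample(nrow(tr), 1, prob = tr$weight)
      branch1[i] <- tr$branch[b1]
      carriers <- tipsets[[b1]]
      if (cfg$p_homoplasy > 0 && stats::runif(1) < cfg$p_homoplasy) {
        others <- setdiff(seq_len(nrow(tr)), b1)
        b2 <- others[sample.int(length(others), 1,
                                prob = tr$weight[others])]
        branch2[i] <- tr$branch[b2]
        carriers <- union(carriers, tipsets[[b2]])
      }
      hit[i, carriers] <- TRUE
      del_p[i] <- cfg$d_p > 0 && stats::runif(1) < cfg$d_p
      del_w[i] <- cfg$d_w > 0 && stats::runif(1) < cfg$d_w
      rr <- sample(bases, 2)
      ref[i] <- rr[1]; alt[i] <- rr[2]
    }
    # ancestral allele is always ref at SDR sites; derived is alt
    geno <- matrix(0L, n, n_samp, dimnames = list(NULL, sheet$sample_id))
    # females: X/X
    geno[, picta_f] <- 2L * hit[, "Xp"]
    geno[, wingei_f] <- 2L * hit[, "Xw"]
    # males: X/Y
    geno[, picta_m] <- hit[, "Xp"] + hit[, "Yp"]
    geno[, wingei_m] <- hit[, "Xw"] + hit[, "Yw"]
    # outgroups stay ancestral (0)
    size <- rowSums(hit)
    keys <- apply(hit, 1, function(h) pattern_key(colnames(hit)[h]))
    map <- tree_topologies()
    tree_id <- ifelse(size %in% c(2, 3),
                      map$tree_id[match(keys, map$pattern)], NA_integer_)
    sdr_list <- list(
      sites = data.frame(chrom = cfg$sex_chrom, pos = pos, ref = ref,
                         alt = alt, stringsAsFactors = FALSE),
      geno = geno,
      truth = data.frame(chrom = cfg$sex_chrom, pos = pos,
                         site_type = "sdr", branch = branch1,
                         branch2 = branch2, pattern = keys,
                         true_tree = tree_id,
                         deleted_on_Yp = del_p, deleted_on_Yw = del_w,
                         stringsAsFactors = FALSE))
  }

  # --- recombining sites (PAR and autosomes): X-Y exchangeable ---
  hw_segment <- function(chrom, positions, seg) {
    n <- length(positions)
    geno <- matrix(0L, n, n_samp, dimnames = list(NULL, sheet$sample_id))
    ref <- alt <- character(n)
    for (i in seq_len(n)) {
      set.seed(derive_seed(cfg$seed, site_key(seg, positions[i])))
      p <- stats::rbeta(1, cfg$beta_shape, cfg$beta_shape)
      geno[i, ] <- stats::rbinom(n_samp, 2, p)
      rr <- sample(bases, 2)
      ref[i] <- rr[1]; alt[i] <- rr[2]
    }
    list(sites = data.frame(chrom = chrom, pos = positions, ref = ref,
                            alt = alt, stringsAsFactors = FALSE),
         geno = geno,
         truth = data.frame(chrom = chrom, pos = positions,
                            site_type = if (chrom == cfg$sex_chrom) "par"
                                        else "autosome",
                            branch = NA_character_, branch2 = NA_character_,
                            pattern = NA_character_, true_tree = NA_integer_,
                            deleted_on_Yp = FALSE, deleted_on_Yw = FALSE,
                            stringsAsFactors = FALSE))
  }

  segs <- list()
  if (!is.null(sdr_list)) segs <- c(segs, list(sdr_list))
  if (cfg$n_par_sites > 0) {
    # PAR positions drawn on the flank(s) outside the SDR (whole
    # chromosome in the autosome scenario)
    if (has_sdr) {
      flanks <- c(seq.int(1, max(1, cfg$sdr[1] - 1)),
                  if (cfg$sdr[2] < cfg$chrom_len)
                    seq.int(cfg$sdr[2] + 1, cfg$chrom_len))
    } else {
      flanks <- seq.int(1, cfg$chrom_len)
    }
    set.seed(derive_seed(cfg$seed, -12))
    pos <- sort(sample(flanks, cfg$n_par_sites))
    segs <- c(segs, list(hw_segment(cfg$sex_chrom, pos, 1)))
  }
  for (a in seq_along(cfg$autosomes)) {
    if (cfg$n_auto_sites > 0) {
      ch <- names(cfg$autosomes)[a]
      pos <- sim_positions(cfg$seed, -(20 + a), cfg$n_auto_sites, 1,
                           cfg$autosomes[[a]])
      segs <- c(segs, list(hw_segment(ch, pos, 1 + a)))
    }
  }

  sites <- do.call(rbind, lapply(segs, `[[`, "sites"))
  geno <- do.call(rbind, lapply(segs, `[[`, "geno"))
  truth <- do.call(rbind, lapply(segs, `[[`, "truth"))
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  geno <- geno[ord, , drop = FALSE]
  truth <- truth[ord, , drop = FALSE]
  nsite <- nrow(sites)

  # --- genotype error layer: flip one allele with probability eps ---
  truth$error <- FALSE
  if (cfg$eps > 0 && nsite) {
    set.seed(derive_seed(cfg$seed, -1))
    flip <- matrix(stats::runif(nsite * n_samp) < cfg$eps, nsite, n_samp)
    up <- matrix(stats::runif(nsite * n_samp) < 0.5, nsite, n_samp)
    new <- geno
    new[flip & geno == 0L] <- 1L
    new[flip & geno == 2L] <- 1L
    new[flip & geno == 1L & up] <- 2L
    new[flip & geno == 1L & !up] <- 0L
    geno <- new
    truth$error <- rowSums(flip) > 0
  }

  # --- hemizygote-imputation artifact: deletion overrides the call ---
  del_cell <- matrix(FALSE, nsite, n_samp)
  if (any(truth$deleted_on_Yp)) {
    rows <- which(truth$deleted_on_Yp)
    xp_hom <- ifelse(grepl("Xp", truth$pattern[rows]), 2L, 0L)
    geno[rows, picta_m] <- xp_hom
    del_cell[rows, picta_m] <- TRUE
  }
  if (any(truth$deleted_on_Yw)) {
    rows <- which(truth$deleted_on_Yw)
    xw_hom <- ifelse(grepl("Xw", truth$pattern[rows]), 2L, 0L)
    geno[rows, wingei_m] <- xw_hom
    del_cell[rows, wingei_m] <- TRUE
  }

  # --- per-cell read depths ---
  set.seed(derive_seed(cfg$seed, -2))
  lib_scale <- exp(stats::rnorm(n_samp, 0, cfg$lib_sigma))
  copies <- matrix(2, nsite, n_samp)
  if (has_sdr) {
    in_sdr <- sites$chrom == cfg$sex_chrom & sites$pos >= cfg$sdr[1] &
      sites$pos <= cfg$sdr[2]
    copies[in_sdr, focal_m] <- 1 + (1 - cfg$map_fail)
    copies[del_cell] <- 1
  }
  set.seed(derive_seed(cfg$seed, -3))
  depth_cells <- matrix(
    stats::rpois(nsite * n_samp,
                 cfg$lambda * rep(lib_scale, each = nsite) * copies / 2),
    nsite, n_samp, dimnames = list(NULL, sheet$sample_id))

  qual <- {
    set.seed(derive_seed(cfg$seed, -4))
    round(stats::runif(nsite, 30, 90), 1)
  }
  sites$qual <- qual
  gt <- genotype_table(sites, geno, depth_cells)

  depth <- sim_depth_table(cfg, sheet, lib_scale)

  structure(list(genotypes = gt, sheet = sheet, depth = depth,
                 truth = truth, config = cfg),
            class = "scenario_bundle")
}

# per-window per-sample mean depths (reads per bp)
sim_depth_table <- function(cfg, sheet, lib_scale) {
  lens <- c(stats::setNames(cfg$chrom_len, cfg$sex_chrom), cfg$autosomes)
  win <- make_windows(lens, cfg$window_width)
  has_sdr <- cfg$scenario != "autosome"
  focal_m <- sheet$species %in% c("picta", "wingei") & sheet$sex == "M"
  # expected deleted fraction of each window (overlap with the SDR times
  # the deletion probability), per focal species
  overlap <- rep(0, nrow(win))
  if (has_sdr) {
    on_sex <- win$chrom == cfg$sex_chrom
    ov <- pmax(0, pmin(win$end, cfg$sdr[2]) - pmax(win$start, cfg$sdr[1] - 1))
    overlap[on_sex] <- (ov / (win$end - win$start))[on_sex]
  }
  nw <- nrow(win)
  ns <- nrow(sheet)
  d_sp <- ifelse(sheet$species == "picta", cfg$d_p,
                 ifelse(sheet$species == "wingei", cfg$d_w, 0))
  # male copies in a window: X copy plus the surviving, mappable Y part
  copies <- matrix(2, nw, ns)
  if (has_sdr) {
    for (j in which(focal_m)) {
      y_part <- 1 - overlap * (d_sp[j] + (1 - d_sp[j]) * cfg$map_fail)
      copies[, j] <- 1 + y_part
    }
  }
  set.seed(derive_seed(cfg$seed, -5))
  width <- win$end - win$start
  mu <- cfg$lambda * width * copies * rep(lib_scale, each = nw) / 2
  reads <- matrix(stats::rpois(nw * ns, mu), nw, ns)
  data.frame(chrom = rep(win$chrom, ns),
             start = rep(win$start, ns),
             end = rep(win$end, ns),
             sample_id = rep(sheet$sample_id, each = nw),
             depth = as.numeric(reads / width),
             stringsAsFactors = FALSE)
}

#' Write a scenario bundle to disk
#'
#' Emits `sim.vcf` (VCF 4.2, GT:DP), `samples.tsv`, `depth.tsv`,
#' `truth.tsv` and `config.yaml` into `dir`.
#'
#' @param bundle a `scenario_bundle` from [simulate_scenario()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_scenario_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vcf(bundle$genotypes, file.path(dir, "sim.vcf"))
  write_sample_sheet(bundle$sheet, file.path(dir, "samples.tsv"))
  utils::write.table(bundle$depth, file.path(dir, "depth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_scenario_config(bundle$config, file.path(dir, "config.yaml"))
  invisible(dir)
}
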