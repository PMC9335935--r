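---
title: "Models and methods: window divergence scans and gametolog tree sharing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: window divergence scans and gametolog tree sharing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdrscan)
```

# The problem

In a young XY system the X and Y still share most of their sequence, so
their divergence must be read indirectly, from differences between males
(XY) and females (XX) in a resequencing cohort. Two questions drive this
package. First, *where* (if anywhere) on a sex chromosome is recombination
between X and Y suppressed — the sex-determining region, SDR? Second, when
two related species both carry an SDR on the homologous chromosome, *did
those SDRs descend from one ancestral SDR*, or did they arise independently,
possibly through a turnover in which a new Y was derived from an X?

The package answers the first question with sliding-window male/female
divergence statistics judged against autosomal envelopes, and the second
with an allele-sharing classification of SNPs into the ten possible
gametolog tree topologies. A scenario simulator generates data with known
truth so that every stage can be validated without access to real
resequencing data.

# Site filters

`apply_site_filters()` applies a fixed cascade: variant quality (default
≥ 20), indel/symbolic removal, biallelic-SNP selection, per-genotype
depth masking (calls below `min_depth` become missing — the site is not
dropped, it falls through to the missingness rule), singleton removal,
missingness, and minor-allele frequency. The order is fixed, not
configurable, so that removal counts are comparable across runs; it mirrors
the natural order of a calling pipeline (quality at calling, then record
type, then genotype-level depth, then cohort-level composition). A
*singleton* is a site whose minor allele is observed exactly once over all
called alleles — one heterozygote carrying the only copy — the convention
of the common VCF filtering tools. `max_missing_fraction` is the *allowed*
missing fraction (0 = no missing genotype tolerated), the complement of the
VCFtools `--max-missing` convention; the mapping is stated in the help page
because it is a recurring source of confusion.

Two presets recur in practice: a depth-3 configuration for scans on a
high-quality distant reference, and a depth-10, no-missing, maf-0.2
configuration for within-genus genotype work. Both are just
`filter_config()` calls.

# The five window statistics

Windows are non-overlapping BED-style tiles (`make_windows()`): 10 kb for
read-depth comparisons, 100 kb for the SNP-based statistics. Read depth is
compared on finer windows because coverage is measured at every base,
whereas SNP-based statistics need enough segregating sites per window to be
stable.

**Read-depth ratio.** Each sample's window depths are first normalised by
that sample's autosome-wide mean. This step is deliberate: with a handful
of individuals per sex, library-size differences of tens of percent are
routine and would otherwise dominate the M:F contrast. The statistic is
then mean(males)/mean(females) of normalised depths. A fully deleted (or
unmappable) Y drives it to 0.5; `normalize = FALSE` gives raw fold
coverage.

**F<sub>ST</sub> between the sexes.** Per site, the Weir–Cockerham (1984)
two-population variance components *a* (between groups), *b* (between
individuals within groups) and *c* (within individuals) are computed from
sample sizes, allele frequencies and observed heterozygote frequencies,
with males and females as the two groups; windows report the ratio-of-sums
Σa/Σ(a+b+c) over informative (polymorphic, defined) sites. Monomorphic
sites contribute nothing; negative values are reported as computed, never
clamped, because truncation would bias window averages upward. The test
suite checks the components against an independent transcription of the
estimator through the nested-ANOVA mean-squares route, to 1e-10 on random
configurations.

**SNP density ratio.** "Polymorphic in a sex" means both alleles are
observed among that sex's called genotypes. The alternative reading
(called-within-sex density) is not implemented; with it, the ratio mostly
measures missingness, not divergence.

**SDR-like SNPs.** An allele is putatively Y-linked when every male
carrying it is heterozygous, at least one male carries it, and no called
female carries it; either ref or alt may qualify and the call records
which. Sites with fewer than 2 called genotypes per sex are
`insufficient_data`, not negatives. With small cohorts this pattern arises
by chance — `autosomal_fp_rate()` measures how often, and the test suite
pins that rate to an exact enumeration over Hardy–Weinberg genotype
combinations. The chance rate falls steeply with sample size, which is the
quantitative reason the SDR call rests on window densities against
autosomal envelopes, not on individual sites.

**Female-specific SNPs.** One allele carried by at least one female and no
male. Requiring *all* females would conflate the statistic with allele
frequency; the ≥ 1 threshold is configurable.

**Envelopes.** The 2.5% and 97.5% empirical quantiles of each statistic
over autosomal windows, with linear interpolation between order statistics
(the R type-7 convention, stated so results are reproducible across
languages). By construction about 5% of autosomal windows fall outside
their own envelope — so a window outside the band is *suggestive*, and only
a contiguous run of outlying windows is evidence of an SDR. The
calibration test verifies the 5% directly.

**Smoothing.** Trend curves use tricube-weighted local linear regression
(`smooth_series()`, span 0.3, `floor(span * n)` nearest neighbours),
matching `stats::loess(degree = 1, surface = "direct")` to machine
precision — the suite asserts this. Smoothed values are reporting-only and
never feed any classification.

# Gametolog tree sharing

For each focal species at each biallelic site,
`infer_gametolog_alleles()` accepts only two male configurations given
females fixed for one allele: all males heterozygous (Y carries the other
allele) or all males homozygous for the female allele (X and Y identical).
All other configurations are rejected with a reason
(`female_polymorphic`, `males_mixed`, `males_opposite_homozygote`,
`insufficient_samples`) — rejections are values, not errors, and are
tallied. `polarize()` requires every called outgroup individual, in both
outgroup species, to be homozygous for the same allele, which becomes the
ancestral state.

A site is *topologically informative* when the derived allele is fixed on
2 or 3 of {X<sub>p</sub>, Y<sub>p</sub>, X<sub>w</sub>, Y<sub>w</sub>}.
There are exactly C(4,2) + C(4,3) = 10 such subsets and they map one-to-one
onto the 10 rooted gametolog trees; the mapping lives in one editable table
(`tree_topologies()`) so it can be revised without touching code. Subsets
of size 0, 1 or 4 carry no topological signal. The suite proves the
bijection by enumerating all 16 subsets.

Two filter-placement decisions deserve a note. The minor-allele-frequency
floor (default 0.2) is computed over the *pooled* analysis cohort (both
focal species plus outgroups), before the per-species fixation rules. A
per-species maf filter would be incoherent here: any informative site is
necessarily monomorphic in at least one species (that is what "derived
allele absent from that species" means), so a within-species maf floor
would discard every informative site. Second, missingness is enforced
through the per-sex and per-outgroup called-sample minima rather than a
blanket no-missing rule, which keeps the sample-minimum semantics explicit.
Counts are reported under two denominators — the strict informative set and
all sites entering the analysis — because within-species-polymorphic sites
are informative about error processes even though they cannot be placed on
a tree.

`summarize_hypotheses()` applies a deliberately transparent decision rule,
echoed verbatim in its output: a homologous verdict needs at least half the
informative sites in trees 1–2; an independent verdict at least half in
trees 3–4; otherwise ambiguous. A wingei-turnover flag is raised when the
tree-5 count exceeds a Poisson upper bound (mean + 3σ) on the homoplasy
background estimated from trees 9–10, which — being biologically
implausible — can only arise from homoplasy or error and hence calibrate
it. This is a reporting heuristic over counts, not a likelihood test, and
is labelled as such in the output.

# The simulator

`simulate_scenario()` is a per-site generative model on a fixed gametolog
tree, not a coalescent: adequate for the allele-sharing patterns,
degeneration signals and artifacts the analysis consumes, and transparent
enough that expected tree fractions have a closed form
(`expected_internal_fractions()`: internal branch length × `alpha` on
Y-transmitted branches, normalised). What it does *not* emulate: linked
genealogical noise along the chromosome, gene conversion, selection,
introgression, and within-species polymorphism beyond genotype error and
recombining-region sites. Passing recovery tests therefore demonstrate the
*classifier logic* is right, not that real data are free of those
processes.

Scenario trees follow from the event times: `homologous` gives
((Y<sub>p</sub>,Y<sub>w</sub>),(X<sub>p</sub>,X<sub>w</sub>)) with the X–Y
split at `t_sdr` and species splits at `t_s`; `independent` gives
((X<sub>p</sub>,Y<sub>p</sub>),(X<sub>w</sub>,Y<sub>w</sub>)) with
within-species X–Y splits at `t_p`, `t_w`; `turnover_wingei` keeps the
ancestral SDR in picta and re-derives the wingei Y from the X at `t_to`.
Times are in arbitrary units — only relative branch lengths matter for
which patterns arise, so defaults (`t_s = 1`, `t_sdr = 2`,
`t_p = t_w = t_to = 0.5`) are modelling choices stated here, not
biological estimates. Sample counts default to the small-cohort design the
analysis targets: 3 males and 3 females per focal species and one
individual per outgroup.

Each SDR site is ascertained as a variant and receives one mutation on a
branch drawn with probability proportional to length (× `alpha` on
Y-transmitted branches); a per-branch rate symbol is unnecessary because
placement only depends on relative weights. Homoplasy is a per-site
probability of a second, recurrent hit drawn from the *remaining* branches
— including internal ones, because the realistic recurrent-mutation route
to the size-3 patterns (trees 5–8) is a hit on one species' X/Y stem plus
a hit on the other species' terminal branch; terminal-only pairs can only
produce size-2 patterns. Recombining sites (PAR and autosomes) draw a
shared allele frequency from Beta(0.5, 0.5) — a U-shaped spectrum loosely
resembling a neutral site-frequency spectrum — and Hardy–Weinberg
genotypes with X and Y exchangeable.

The artifact layers mirror what short-read pipelines actually do. At a
site deleted on a species' Y (probability `d_p` / `d_w`), every male of
that species is *imputed homozygous for his X allele* — exactly the
diploid-caller behaviour at hemizygous sites — and his site depth halves.
This is why, under a homologous history with heavy picta-Y deletion,
X-private and X-stem mutations masquerade as picta X+Y clades: tree 3 and
tree 6 counts inflate while trees 1, 2, 5 and 7 (all of which need an
observed Y<sub>p</sub> allele different from X<sub>p</sub>) collapse — the
direction the acceptance suite asserts. Genotype error flips one allele of
a call with probability `eps`; deletion overrides error, because the
imputation happens downstream in a real caller. Mapping failure `map_fail`
thins male depth in SDR windows without touching genotypes. Window depths
are Poisson draws at `lambda × width × copies/2`, scaled by lognormal
per-sample library sizes (`lib_sigma`), which the depth-ratio
normalisation must (and does) cancel.

Reproducibility: one master seed; every site owns a substream keyed by
segment and genomic position, so enlarging a simulation appends sites
without perturbing existing ones; whole-matrix layers (error, depth,
library sizes) use their own derived sub-seeds. Identical configurations
produce byte-identical output files.

# Numerical and edge-case conventions

* Undefined window values (no informative site; zero female mean) are
  `NA` in memory and `"NA"` in TSV output, never silently dropped.
* F<sub>ST</sub> is undefined (flagged, `NA`) when a group has no called
  genotype or the estimator's denominators vanish (e.g. one diploid per
  group); monomorphic sites return exact zeros and are excluded from
  window sums.
* Genotypes are coded 0/1/2/NA by non-reference allele count; phase
  separators are ignored on input. Depth absent from a VCF reads as 0.
* All positions are 1-based inside the package (VCF convention); window
  coordinates in outputs are 0-based half-open (BED convention).
* Hemizygosity is deliberately unrepresentable in the genotype container:
  like the callers the pipeline emulates, every call is diploid, and
  hemizygosity exists only as the imputation artifact.
* The envelope requires ≥ 40 defined autosomal windows and errors with
  advice otherwise; the smoother passes through with a warning below 10
  points.

# Problem sizes used by the tests

The suite validates scenario recovery on roughly 6,500–9,000 SDR sites per
scenario (≥ 2,000 informative sites, so that a 3-binomial-σ comparison to
the analytic fractions is sharp), artifact directions on 4,000–12,000
sites, and the envelope calibration on 400 autosomal 100-kb windows; these
sizes give stable statistics while keeping the whole suite under a minute
on one core. Unit tests use handfuls of sites built in code.

# Known limitations

* The generative model is site-independent given the tree: no linkage
  disequilibrium, so confidence statements that rely on inter-site
  independence are optimistic for real data.
* The hypothesis verdict is a count-threshold heuristic; it reports the
  evidence (all ten fractions, both denominators) precisely so users can
  apply their own decision standard.
* The turnover flag depends on trees 9–10 as a homoplasy gauge; with very
  few informative sites it is conservative by construction.
* `infer_gametolog_alleles()` assumes an XY system; ZW systems would need
  the sexes swapped by the caller.
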