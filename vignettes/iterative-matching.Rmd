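---
title: "Iterative matched case-control consensus analysis of microbiome cohorts"
author: "micomatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Iterative matched case-control consensus analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micomatch)
```

## The problem

Prospective general-population cohorts are the right place to look for
early gut-microbiome markers of a later-life disease such as celiac
disease, but they are brutally imbalanced: in a cohort of ~1478 infants
with stool sampled at one year, only ~26 (1.8%) go on to a diagnosis,
up to two decades later.  Comparing 26 future cases against 1450+
controls in one shot either drowns the cases or overpowers the test
with whatever heterogeneity happens to structure the controls.

`micomatch` implements an iterative matched case-control consensus
design.  Metadata variables that measurably structure community
composition are identified first and used as matching covariates; then
many (by default 100) independently seeded control subsets are drawn,
each matching every case to `ratio = 2` controls with equal covariate
values; two statistical branches are run on every subset; and only taxa
that are significant in at least `cut = 50` of the iterations are
reported.  The consensus rule absorbs the variability contributed by
*which* controls are drawn, which a single matched subset cannot.

## Pipeline stages and their models

### Table preparation

Counts enter as a taxa-by-samples integer matrix inside a
`MicrobiomeCohort` (a `SummarizedExperiment` subclass).  Samples with
fewer than `min_reads = 1000` total reads are dropped; taxa must show
`min_count = 5` or more reads in at least `min_samples = 5` samples;
ASV tables are then agglomerated to genus (unassigned ASVs keep their
own label as a pseudo-genus so reads are never discarded).  Filters are
applied in that order.  Relative abundance divides each sample by its
total; *total abundance* multiplies relative abundance by the sample's
qPCR-measured 16S rRNA copies per gram of stool, a proxy for absolute
microbial load.  Both transforms are column-linear, so they commute
with genus agglomeration; a unit test asserts this identity.

### Confounder screening

Between-sample dissimilarity uses the binomial deviance: for samples
$j,k$ and taxon counts $x_i, y_i$ with $n_i = x_i + y_i$,

$$d_{jk} = \sum_{i:\,n_i>0} \frac{1}{n_i}\Big[x_i\ln\tfrac{x_i}{n_i} +
  y_i\ln\tfrac{y_i}{n_i} + n_i\ln 2\Big],$$

the scaled deviance of an even-split binomial null; a taxon private to
one sample contributes exactly $\ln 2$.  Each candidate metadata
variable is tested against this matrix with a one-variable PERMANOVA
(999 permutations by default, missing labels dropped per variable), and
p values are Benjamini–Hochberg adjusted across the screened set.
Variables with $p_{adj} < 0.05$ become matching covariates; in the
motivating cohort these are geographic region and siblings at birth.

### Matching

For each case, the eligible pool is every control equal to the case on
all matching covariates whose case-side value is observed.  Two rules
handle missing data: a covariate missing *on the case* is relaxed for
that case (a case with unknown siblings status is matched on region
alone — its pool is then visibly larger, as in the distributed case
table); a control missing a *required* covariate is excluded from that
pool.  Draws are uniform without replacement; within an iteration a
control serves at most one case (reuse would pseudo-replicate samples
inside the per-iteration tests; a flag restores reuse).  Cases are
processed scarcest-pool-first, which makes sequential feasibility
deterministic and maximal.  Iteration $i$ uses seed
`base_seed + i - 1`, so any iteration can be replayed alone.

### Prevalence / core-microbiome branch

Prevalence of a taxon in a group is the fraction of that group's
samples containing it at all, irrespective of abundance.  At each
matched subset the table is filtered at a prevalence threshold
(`threshold = 60` percent; a taxon survives if it reaches the threshold
in *either* group, preserving group-specific cores — a flag requires
all groups), a random forest (500 trees, $\sqrt{p}$ candidate features
per split) predicts case/control, and taxa are ranked by unscaled mean
decrease in out-of-bag accuracy (MDA, percentage points) under
per-taxon permutation.  The `top_k = 30` taxa with positive MDA are the
iteration's hits; direction is the group with the larger mean
abundance.  An OOB-error curve across thresholds 0, 5, …, 100 is
provided so the analyst can pick the threshold balancing error against
taxon representation; the threshold itself is a configuration input,
not an automated choice.

### Differential-abundance branch

A deliberately transparent negative-binomial Wald test, run without
any prevalence pre-filter.  Size factors are the zero-tolerant
"poscounts" median-of-ratios (per-taxon reference
$r_i = (\prod_{c_{ij}>0} c_{ij})^{1/m}$ with $m$ the full sample count;
factors rescaled to geometric mean 1).  Dispersion is per-taxon
floored method-of-moments on normalized counts,
$\hat\alpha_i = \max\big((v_i-\bar\mu_i)/\bar\mu_i^2,\,10^{-8}\big)$ —
no trend fitting or empirical-Bayes shrinkage, a documented fidelity
gap relative to full DESeq2-style machinery, accepted to keep the
test's behaviour auditable at matched-subset sizes.  The effect is
$LFC = \log_2\frac{\bar k_{case}+\tfrac12}{\bar k_{control}+\tfrac12}$
(the symmetric half-count shift keeps taxa absent from one group at a
finite LFC), the standard error comes from the expected information
with plug-in means, $z = LFC/SE$ is referred to the standard normal,
and p values are BH-adjusted *within each iteration* across taxa.
Outlier (Cook's-distance-style) filtering is deliberately not applied.

Feeding the relative-composition analysis: fractions cannot enter a
count model, and scaling them to pseudo-counts distorts the shot-noise
granularity (we verified against a reference NB implementation that
the implied Poisson term is then off by the scaling factor, which
destabilizes moment-based dispersion).  The relative branch therefore
consumes the raw counts — median-of-ratios normalization removes
library size, so the contrast is compositional by construction.  The
total-abundance branch rounds copies-per-gram values to integers;
at $\sim 10^{10}$ copies/g the rounding is immaterial and the qPCR
noise is absorbed into the dispersion.

### Consensus and host-factor association

Per taxon, branch and abundance mode, the pipeline counts significant
iterations (abundance branch: $p_{adj} < \alpha$; core branch:
membership in the positive-MDA top-$k$), flags consensus at
$\ge$ `cut`, calls direction by majority across counted iterations
(ties break toward "control", with a warning), and marks taxa whose
consensus holds in both abundance modes — the intersection is the
reported signature.  Consensus taxa are then tested against host
factors on the full cohort (Mann–Whitney for two-level factors,
Kruskal–Wallis otherwise, global BH across the taxon-by-factor grid,
reported only when significant in both modes), and early-life
questionnaire factors are tested against status by Monte-Carlo
chi-square with fixed margins ($B = 2000$).

## The synthetic cohort generator

Because the cohort's sequence data cannot ship with a package, every
stage is exercised on synthetic cohorts whose defaults mirror the study
conditions: 1478 subjects, case probability 0.0176, four regions,
binary siblings with 1.5% missingness, compound HLA-DR-DQ genotype
strings (~20% of subjects carry DR3-DQ2.5), negative-binomial genus
counts (dispersion 0.5) with log-normal library-size factors and
baseline means, and log-normal qPCR loads (median $10^{10}$ copies/g).
Planted effects come in two independent classes: `n_lfc_taxa` taxa
with a $\pm$ `effect_lfc_magnitude` (default 2) log2 fold change, and
`n_prev_taxa` taxa Bernoulli-thinned to presence probability 0.9 in
the enriched group versus 0.9 − `prevalence_delta` (default 0.4) in
the deficient group.  The full record of what was planted is stored
as the ground-truth table alongside the cohort.

The generator splits the single "number of effect taxa" idea into the
two classes explicitly, because the two statistical branches are meant
to detect them separately.  An optional Beta-distributed per-taxon
presence probability (`prevalence_shape1/2`) can sparsify background
taxa the way real infant genus tables are sparse; it is off by
default because the clean planted/null separation used by the
recovery checks presumes a non-sparse background (see limitations).

What the generator does *not* emulate: taxon-taxon correlation,
compositional closure effects, taxonomy misassignment, longitudinal
structure, and the long-tailed prevalence spectrum of real tables
(unless the sparsity knob is turned on).  Green recovery tests
therefore demonstrate the machinery's operating characteristics under
its own assumptions, not performance on real sequencing data.

## Numerical and design choices

* Filtering order: samples → taxa → agglomeration; transforms after.
* Prevalence-filter merge rule: ANY group (flag for ALL).
* MDA ties break lexicographically by taxon label; `top_k = 1`
  therefore has a deterministic answer.
* Dispersion floor $10^{-8}$; all-zero taxa flagged untestable.
* PERMANOVA defaults to 999 permutations; p values can never be
  smaller than $1/(B+1)$.
* Incidence is displayed to 1 decimal, means/SDs to 2, percentages to
  whole numbers, matching how cohort tables are printed; HLA carriage
  is an exact substring match, so "DR3-DQ2" without the allele suffix
  does not count as DR3-DQ2.5 carriage.
* All randomness flows from explicit integer seeds; a pipeline run
  with a fixed configuration is bit-reproducible, and the per-design
  seed is reused for that design's forests.

## Problem sizes used by the automated checks

The test suite runs the full 100-iteration, two-branch, two-mode
pipeline on three replicate 1478-subject cohorts with 150 genera
(10 + 10 planted effects), five null 600-subject cohorts, a 200-
replicate PERMANOVA calibration, and a 10,000-iteration matching
uniformity check — sizes chosen so the whole suite completes on a
laptop-class single core while keeping each check's Monte-Carlo error
well inside its acceptance band.

## Known limitations

* **The case sample is fixed.**  Iterating over control draws cannot
  average away a chance deviation carried by the cases themselves.
  With ~130 null taxa, a few standard-normal-tail case profiles are
  expected, and both branches re-detect them in every iteration.  The
  two-mode intersection removes most (independent qPCR noise halves a
  borderline $z$ while planted effects survive), but under a global
  null the prevalence/core branch — whose top-$k$ MDA ranking is a
  ranking, not a calibrated test — still promotes a handful of taxa to
  consensus when the case sample is small.  Treat core-branch
  consensus taxa as candidates whose support is the abundance branch
  and the mode intersection, not as error-controlled discoveries.
* The method-of-moments dispersion is noisier than shrinkage-based
  estimators at $n = 78$; its miscalibration is visible mostly as
  mild conservatism in the type-I checks.
* Matching covariates must be categorical; continuous covariates would
  need a different (propensity/nearest-neighbour) matcher, which is
  out of scope.
* Exact numerical parity with the reference random-forest pipeline is
  impossible across RNGs; only operating characteristics are
  comparable.
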