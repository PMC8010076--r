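---
title: "Dual-platform differential proteomics: models, thresholds and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-platform differential proteomics: models, thresholds and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualquant)
```

## The problem

Quantitative proteomics of mouse models of multiple sclerosis — cuprizone-induced
demyelination (CPZ) and experimental autoimmune encephalomyelitis (EAE) — asks
which frontal-cortex proteins change in abundance relative to matched control
animals, and which of those changes are robust enough to nominate biomarker
candidates. Two complementary LC–MS designs answer it with different strengths:

* a **pooled isobaric-label (TMT) experiment**, where equal protein amounts from
  every animal of a condition are combined into one labelled channel. Pooling
  sacrifices biological replication, so significance must come from the shape of
  the ratio distribution itself;
* a **per-animal label-free experiment**, which keeps each mouse as a separate
  run and supports a classical ANOVA across groups, at the cost of more missing
  values and run-to-run variation.

`dualquant` implements both pipelines and the cross-platform *verification*
idea: a protein is trusted only when both designs call it regulated in the same
direction. The `dualquant()` fit runs everything and returns a classed object
with `print()`, `summary()`, `coef()` and `plot()` methods.

## The pooled-channel model

Reporter intensities are log2-transformed and each channel is centred on its
median, removing per-channel loading and labelling offsets
(`normalize_channels()`). Ratios are differences on this scale:
`log2_ratio(p, c) = norm(p, c) − norm(p, control(c))`, with the control channel
chosen per condition (`CPZ-42d` against its 42-day control, both EAE stages
against the EAE control).

With no replicates, significance comes from a **Gaussian empirical null**: for
each condition the log2 ratios are standardized by their own mean and SD,
`z = (x − μ̂)/σ̂`, and two-sided normal tail probabilities are corrected by
Benjamini–Hochberg within the condition. The assumptions are that most proteins
are unregulated and that the null ratio distribution is approximately normal on
the log2 scale — which is also why z-scores are computed on log2 ratios, not
linear ones. When a heavy regulated tail might inflate σ̂, a robust variant
(median and MAD) is available via `robust_z = TRUE`; the plain moments are the
default because the statistic is conventionally defined that way and the
simulations below stay well calibrated with it.

A protein is called regulated on this platform when `q < 0.05` (configurable
via `tmt_q_cut`), with the direction given by the sign of the log2 ratio.

## The per-animal model

Label-free runs are first normalized by **median log-ratio scaling**: each
sample is divided by one factor chosen so its median log2 ratio to a reference
run (the sample with fewest missing values) is zero. This is a stand-in for the
proprietary default normalization of common label-free software; a
total-intensity option exists for sensitivity analysis. The procedure is
idempotent and exact for global loading differences.

All control animals are pooled into one CTR group (11 animals under the default
design: 6 cuprizone controls and 5 EAE controls). Each protein then gets **one
omnibus one-way ANOVA p-value** (`stats::oneway.test`, equal variances) across
the disease groups plus CTR, computed on log2 abundances over observed values
only. A protein enters the test only if every group has at least two observed
values; there is no imputation. BH runs across proteins with a valid p.

The regulation call is a strict conjunction, the **significance cascade**:

* fold change over CTR ≥ 2.0 (up) or ≤ 0.7 (down) — means of normalized linear
  abundances;
* ANOVA p < 0.05;
* q below a per-condition cut-off: 0.05 for CPZ-42d, 0.051 for EAE-16d, 0.11
  for EAE-32d. The stratification encodes how uniformly the animals of each
  condition respond — the recovery-phase EAE-32d group is the most
  heterogeneous and gets the loosest bound.

Fold changes inside the dead band (0.7, 2.0) are never called, however small
the p. Every threshold is a parameter of `cascade_thresholds()`.

## Integration

`verify_regulated()` intersects the two platforms at (protein, condition)
resolution and keeps same-direction agreements; opposite-direction pairs are
excluded and reported in an attribute rather than silently dropped.
`assign_evidence_weights()` produces the pathway-tool input weighting (0.005
when significant with > 1.2-fold on both platforms, 0.05 on exactly one) — note
the relaxed 1.2-fold criterion replaces the cascade's dead band there.
`combined_ratio_matrix()` lays out the six (platform × condition) log2-ratio
columns, and `cluster_conditions()` clusters them after per-row z-scoring
(Euclidean distance, average linkage, the defaults of the usual heat-map
tools). The fit clusters the **regulated protein list** rather than all
quantified proteins: after row z-scoring, rows of pure noise carry exactly as
much weight as signal rows, and with thousands of unregulated proteins they
drown the condition structure.

Annotation is file-driven by design — ortholog maps and body-fluid presence
tables are plain TSVs, never network lookups, so results are reproducible.
`ora_test()` is a standard hypergeometric overrepresentation test whose
default universe is every protein quantified on at least one platform.

## What the simulator emulates

`sim_config()` + `simulate_study()` generate both matrices from one ground
truth so every stage can be benchmarked. Per protein: a base log2 abundance
(normal, mean 20, SD 1.5 — a wide log-normal intensity distribution); per
condition: the true log2 effect; per animal: biological noise (SD 0.4 log2
units, the scale of between-mouse variability in cortex tissue); per
measurement: technical noise (SD 0.1); per channel or run: loading offsets.
Pooled channels average the simulated individuals on the log2 scale (a linear
option exists) and have no missing values; the per-animal matrix has 5% of
cells missing completely at random. Default group sizes are 5 (CPZ-42d),
6 (EAE-16d), 12 (EAE-32d), 6 + 5 controls.

Effects default to 5% of proteins with |log2FC| uniform in [1, 2.5]. Their
structure across conditions follows `scheme`: the default `"by_control"` gives
the two EAE stages one shared effect and cuprizone an independent one,
mirroring the biology of two distinct disease models sampled at two stages of
one of them; `"shared"` and `"independent"` are available for benchmarks that
need them. Signs are drawn independently per control block by default
(`sign_mode = "iid"`).

`sign_mode = "median_neutral"` instead ties the effect sign to the protein's
side of the abundance median: up-spikes go to proteins above it, down-spikes
below. The point is subtle but important for exactness benchmarks: median
centring is only *exactly* unbiased when the spiked regulation cannot move any
channel median. With unconstrained signs, an unbalanced set of spikes crossing
the median shifts it by a few order-statistic gaps (~0.01 log2 units at 2000
proteins), which is invisible to the z-statistic (a per-condition constant
cancels in standardization) but breaks machine-precision recovery of the
encoded truth. This is the proteomic analogue of compositional bias in
spike-in RNA-seq benchmarks, where differential features are balanced so that
normalization stays neutral. The label-free pipeline needs no such care: its
normalization is a median of log-ratios that are exactly zero for the
unregulated majority, hence exactly zero overall.

What the simulator does **not** model: peptide-level rollup, reporter-ion
isotope impurities, intensity-dependent missingness (missingness is MCAR
only), retention-time drift, and shared biological animals between the two
platforms (individuals are drawn independently per platform, which is
conservative for cross-platform concordance). Passing benchmarks therefore
demonstrate the statistical machinery, not robustness to those artefacts.

## Numerical choices and degenerate inputs

* Ratios, z, p, q are invariant to rescaling any channel by a positive
  constant, and BH ties receive identical q-values by the step-up minimum.
* A condition whose log2 ratios have zero spread raises a degenerate-
  distribution error rather than returning z = ±Inf.
* ANOVA on a protein whose observed values are all identical returns p = 1;
  an infinite F (zero within-group variance with distinct means) would give
  p = 0 and is clamped to the smallest positive double so BH stays defined.
* Proteins missing in a channel are dropped from that condition's TMT ratio
  set; label-free proteins enter the ANOVA only with ≥ 2 observations in every
  group.
* Clustering drops incomplete rows, drops zero-variance rows before z-scoring,
  and takes columns in label order so ties break deterministically.
* Histogram bins are centred on multiples of the bin width so a symmetric null
  has its mode bin at zero.

## Problem sizes used in the packaged checks

The test-suite and acceptance benchmarks run at the study's own scale: 2000
simulated proteins, the default group sizes above, 20 seeds for null
calibration, 10 seeds for spike-in recovery (|log2FC| = 2, the cascade's
boundary effect size) and clustering topology. At these sizes the whole suite
completes in about a minute on one core.

## Known limitations

* The Gaussian empirical null inherits the usual caveat of pooled designs: it
  measures deviation from the cohort of proteins, not biological replication,
  so a globally perturbed proteome would mis-calibrate it.
* The omnibus ANOVA gives one p per protein; a condition-specific contrast
  option is not provided — the per-condition information enters through the
  fold change and the stratified q cut-offs.
* The per-condition q cut-offs are taken as given study parameters, not
  derived quantities.
* Verification treats the platforms symmetrically; it does not model their
  different fold-change compression (pooled TMT ratios are typically
  compressed relative to label-free ones, visible in the packaged reference
  panel, e.g. HEMO: 1.8-fold pooled vs 3.3-fold label-free).
```{r example}
study <- simulate_study(sim_config(n_proteins = 500, seed = 1))
fit <- dualquant(study$reporter, study$labelfree$values, study$labelfree$samples)
summary(fit)
score_against_truth(fit, study$truth)
```
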