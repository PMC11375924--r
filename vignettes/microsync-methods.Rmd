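---
title: "Methods: regional synchronicity of microglial activity from TSPO-PET uptake tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regional synchronicity of microglial activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and data model

`microsync` operates downstream of image reconstruction and atlas
extraction: its inputs are wide tables of mean tracer uptake per subject and
volume of interest (VOI), an atlas metadata table mapping VOIs to
compartments and hemispheres, and a cohort manifest (cohort assignment,
reference-cohort mapping, covariates such as cognition scores and TSPO
binding status). No image formats are handled. All values must be strictly
positive and finite; cohorts of fewer than three subjects are rejected at
the correlation stages because the Pearson p-value is degenerate below
n = 3. Low-affinity binders (LAB) of TSPO radiotracers are excluded a
priori through a manifest rule (`tspo_binding != 'LAB'`), mirroring the
standard practice for the rs6971 polymorphism.

Each VOI listed in the table is treated as atomic; whether bilateral region
means were volume-weighted upstream is not recoverable from region-mean
exports, so no pooling or weighting is applied here.

# Normalization

`global_mean_scale()` divides each subject's row by that subject's mean
over the table's VOI set, giving standardized uptake value ratios (SUVR)
with unit row mean. This is the unweighted region-mean approximation to the
image-space global-mean operation — the package only sees region means, so
a voxel-weighted whole-brain mean is out of reach; the approximation is
exact when VOI volumes are equal. Two alternatives are provided:
division by an external per-subject reference (`myocardium` tag, a
brain-independent quantification), and division by a best reference region
(BR). The BR is the VOI minimizing the absolute Cohen's d between two
cohorts on global-mean-scaled uptake; "lowest Cohen's d" is read as
smallest effect *magnitude*, since a large negative effect is no better a
reference than a large positive one. Cohen's d uses the conventional
pooled SD with Bessel-corrected group variances. Ties on |d| are broken by
lexicographic VOI id with a logged warning.

# The bootstrapped ICC

For every unordered VOI pair, Pearson's correlation is computed on each of
`n_rep` bootstrap resamples of subjects (equal inclusion probability,
replacement, resample size = cohort size), transformed with
`Z = arctanh(R)`, and averaged; the mean Z is the interregional correlation
coefficient (ICC). Defaults follow the species conventions: 10,000
resamples for mouse cohorts, 1,000 for human cohorts (the `mouse`/`human`
presets of `run_pipeline()`).

Numerical choices:

* **Boundary clipping.** Resampling with replacement can make a resample
  exactly collinear (|R| = 1), whose Z is infinite and would poison the
  mean. |R| is clipped to `1 - 1e-7` before `arctanh`, mapping the boundary
  to ±8.4056.
* **Zero-variance resamples.** A resample in which either VOI is constant
  has no defined correlation; such resamples are excluded from that pair's
  mean and counted in a log line. A pair invalid in more than half of the
  resamples is masked (`NA`) rather than reported from a minority of
  resamples.
* **p-values.** The significance filter uses the two-sided Pearson test
  (t distribution, df = n − 2) on the *original*, non-resampled cohort.
  The bootstrap exists to stabilize the correlation estimate, not to build
  a null distribution; a bootstrap-derived p would confound the two roles.
  The implementation is algebraically identical to `stats::cor.test` and is
  tested against it.
* **Magnitude threshold on the Z scale.** Since the ICC is defined as a
  mean Fisher Z, the significance magnitude rule (|ICC| > 0.5, negative
  values included) is applied on the Z scale, not the R scale.

Significant connections (joint |Z| and p rule) are classified from
compartment labels: equal labels give that class, mixed labels the
hyphenated sorted pair (`cortical-subcortical`, `parietal-temporal`). The
three classes partition the edge set, so class counts always sum to the
total. Pairs are canonically ordered (lexicographic by VOI id) and counted
once. Cohort summaries report the quartiles Q1/Q2/Q3 of |ICC| (the
distributions are non-Gaussian, so the median, not the mean, is the
headline figure), and cohorts are compared with a two-tailed Wilcoxon
signed-rank test on the paired |ICC| vectors (normal approximation;
zero-difference pairs dropped, an all-equal comparison is reported as
p = 1 with a flag). Connection counts are standardized across experiments
as cohort/reference ratios, conventionally printed to two decimals.

# The desynchronization index

The normative model is one straight line per unordered VOI pair, fitted on
a reference cohort: within each bootstrap resample an ordinary
least-squares fit of the higher-indexed VOI on the lower-indexed VOI, with
slope and intercept averaged over valid resamples. Averaging the
per-resample fits (rather than fitting once to bootstrap-averaged data) is
the natural reading of a "mean of bootstraps" fit and keeps the model
consistent with the ICC's mean-Z construction. The orientation of the fit
is a free choice; because the score uses the *perpendicular* (orthogonal)
distance rather than the vertical residual, the index is nearly insensitive
to it, and one line per pair (d<sub>ij</sub> = d<sub>ji</sub>) suffices.

A subject's index for VOI *i* is the sum of perpendicular distances over
the N − 1 pairs containing *i*; each pair distance is computed once and
credited to both members, so the index sums to twice the total pair
deviation. The index carries SUVR units and scales linearly under a common
rescaling of all uptake values — which is why scoring is only meaningful on
normalized tables. Per-VOI z-scoring is deliberately not applied by
default; the raw SUVR-unit index is what enters group statistics.

Reference cohorts are scored by leave-one-out: fold k trains on n − 1
subjects (fold seed = base seed + k) and scores the held-out subject,
yielding an unbiased normative distribution. External cohorts are scored
against the full reference fit. The control analysis on a motor-sensory
network uses exactly the same steps on a different VOI subset.

# Group inference and the DI-vs-SUVR comparison

Per VOI: Shapiro–Wilk within each group, one-way ANOVA across three groups
(significance at p < 0.05), and all three pairwise two-tailed unpaired
t-tests. The t-tests default to the equal-variance Student form, with Welch
behind a flag, since no variant is canonical for this analysis. The
"top-rated" VOIs for the composite read-out are operationalized
data-dependently as the ANOVA-significant VOIs ranked by F (the count is
configurable); PC1 of the column-standardized index sub-matrix over those
VOIs is the single per-subject read-out, sign-anchored so that higher PC1
means more desynchronization (non-negative correlation with the
per-subject mean index; PCA signs are otherwise arbitrary). Constant
columns are dropped with a warning.

Cognition correlations report Pearson's r, the two-sided p, and the
least-squares slope/intercept of the index on the score, with
Benjamini–Hochberg FDR adjustment across the VOI list and significance at
adjusted p < 0.05. The BH implementation is the stock `p.adjust`, verified
against a brute-force step-up oracle in the test suite.

Discriminability: per VOI, (cohort mean) / (reference-cohort mean) is
formed separately for SUVR and for the index (reference index from
leave-one-out), and the two ratio profiles are compared with a paired
two-tailed t-test across the pooled analysis VOI list plus Cohen's d of the
paired differences. Pooling across the whole VOI list (rather than per
network) is the default because the comparison is between two *profiles*
over the same regions. Identical test and reference cohorts make every
ratio exactly 1 and the paired differences constant; that case is flagged
degenerate and no p is reported.

# Cohort-size robustness

`subject_drop_curve()` descends from the full cohort size to `min_n`,
subsampling both cohorts to n subjects, recomputing both ICC matrices and
their RMSE (root mean square difference over jointly unmasked pairs, each
pair once). Dropping one subject at a time with a single random draw is
seed-fragile, so the default averages `n_draws = 20` draws per step;
`n_draws = 1` reproduces the single-draw procedure. At the full size the
cohorts are used as-is. The derived ICC seeds are stored per row, so every
entry is independently recomputable. The output includes a knee heuristic —
the smallest n whose mean RMSE is within 10% of the full-size RMSE —
explicitly labelled a heuristic; the judgment of what counts as robust is
left to the user.

# The synthetic generator

Scanner data for this kind of study are typically not publicly deposited,
so the generator is a first-class module that reproduces the statistical
structure the analysis assumes:

* per subject, a standard-normal shared activation factor `f` and a
  log-normal global scale `g` (injected-activity variability, default SD
  0.2 on the log scale, about 20%);
* per region, uptake `g * max(eps, baseline + loading * f + noise)` with
  `eps = 1e-6` keeping values positive, baselines on an SUVR-like scale
  (1.1 cortical-type, 0.95 otherwise);
* **regionally heterogeneous loadings** (default: a fixed ramp from −0.08
  to 0.32 across the region list, mean 0.12, about twice the default
  regional noise SD of 0.06). The heterogeneity is essential: global-mean
  scaling divides by the row mean and therefore cancels a perfectly uniform
  factor *exactly*; what survives normalization — and what the dense
  connectome of a synchronized cohort reflects — is the regional *pattern*
  of activation, which also produces negatively correlated region pairs.
  A single shared factor is the simplest structure with this property;
  multi-factor extensions can be emulated by summing cohorts' configs.
* desynchronization restricted to a configured region set: the loading is
  multiplied by `1 - desync_loading_drop` and the noise SD by
  `desync_noise_inflation`, both modulated per subject by a log-normal
  severity draw (SD 0.25), mimicking between-subject variation in disease
  burden;
* a cognition score `base - slope * latent + noise` (defaults 29, 6, 1.5,
  emulating an MMSE-like ceiling near 29 in controls and a strong decline
  with burden), coupled to the *latent* desynchronization magnitude rather
  than to any measured index, so that recovery tests are non-circular.

All randomness is drawn as unit normals and scaled afterwards; configs that
differ only in an SD parameter therefore share the rest of the stream, and
global-mean scaling removes `g` exactly (a tested identity). Staged disease
is emulated with drop/inflation pairs (0.3, 1.5) and (0.6, 2.5) around the
defaults; study bundles add a train/test control pair.

What the generator does **not** emulate: the true covariance structure of
regional TSPO uptake (unknown), spatial autocorrelation between neighboring
regions, partial-volume and spill-in effects, binding-affinity genotype
effects on scale, or any mechanistic microglial biology. Passing tests
therefore demonstrate that the pipeline recovers the *qualitative*
orderings it is designed to detect under its own assumptions — not that it
reproduces any particular cohort's ICC values.

# Problem sizes and test design

The test and acceptance workloads use sizes chosen to exercise the study
design at desk scale: 21-region mouse-style atlases with cohorts of 12–14
subjects; bootstrap depths of 200–1,000 within tests and 10,000 (mouse
convention) in the acceptance script; 500 replicates for the type-I suite
(independent regions, n = 14, 1,000 resamples each); 30 replicates for the
staged-connectome ordering, whose single-cohort counts at n = 14 fluctuate
too strongly for single-draw comparisons; and pooled cohorts of
12 + 17 + 17 = 46 subjects for the PC1–cognition recovery, matching the
pooled size of a three-group human design. Exact identities (identity
resample vs. plain Pearson, double-counting of pair distances, byte-level
determinism per seed) are asserted at 1e-12 or bitwise.

# Pipeline configuration

`run_pipeline()` wires the stages from a named list or YAML file. A full
synthetic run:

```yaml
seed: 7
preset: mouse          # 10,000 resamples, |Z| > 0.5, p < 0.005
out_dir: results/run1
stages: [simulate, normalize, icc, di, eval, robustness]
simulate:
  n_subjects: 14
  desync_loading_drops: [0.3, 0.6]
  desync_noise_inflations: [1.5, 2.5]
di:
  train_cohort: CTRL_train
eval:
  groups: [CTRL_test, DISEASE_1, DISEASE_2]
robustness:
  min_n: 6
  n_draws: 20
```

To analyze measured data, drop `simulate` from `stages` and point `inputs:`
at `uptake`/`atlas`/`manifest` CSV paths. Every artifact is written once
(inputs are never mutated) with a `.provenance.json` sidecar carrying the
seed, thresholds, input md5 hashes and package version; reruns with the
same configuration and seed are byte-identical.

# Known limitations

* ICCs are cohort-level constructs; per-pair interpretation is limited, and
  the index is the intended subject-level read-out.
* The p-value source for the significance filter (original-cohort Pearson
  test) is a design decision; a bootstrap-derived p is available as an
  optional research mode only through the ICC matrix's resample machinery,
  not as a default, and the two should not be mixed within one analysis.
* Connection-number ratios are only comparable across experiments when the
  reference cohorts are equivalent; ratios against non-equivalent
  references deserve caution.
* No graph-theoretic metrics beyond counts and classes, no covariate
  adjustment of fits, no nonlinear normative models.
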