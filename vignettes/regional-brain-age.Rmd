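---
title: "Regional brain age and parity: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional brain age and parity: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regionage)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter, what the
synthetic-cohort generator does and does not emulate, and the choices made
where the design was genuinely open.

## The analysis in one paragraph

Starting from per-participant regional brain volumes (34 bilateral cortical
regions and 9 bilateral/midline subcortical structures after hemisphere
averaging), the pipeline residualizes the volumes on nuisance variables,
groups them into covariance clusters by agglomerative clustering on
Spearman rank correlations, and fits a separate cross-validated brain-age
model per feature set (all regions, each cluster, each subcluster of the
most exposure-associated cluster, and each single region of the strongest
subcluster). Each feature set's out-of-fold *brain-age delta* (predicted
minus chronological age) is regressed on the exposure — number of live
childbirths — with chronological age as covariate. Feature sets are
compared with a correlated-estimates Z test, multiplicity is controlled by
Benjamini–Hochberg FDR, unique regional contributions are assessed by
leave-one-out log-likelihood comparison under Wilks' theorem, and the shape
of the exposure relation is probed with weighted polynomial fits on
per-parity group means.

## Preprocessing

**Exclusions.** Participants are removed when flagged with a pre-existing
diagnosis, when missing the exposure, or when any of three metrics — the
hemisphere-averaged surface-quality score (an Euler-number proxy), mean
cortical volume, or mean subcortical volume — lies more than 4 SD from the
sample mean. Choices made here:

- "±4 SD" is read as a *strict* inequality: a point at exactly 4 SD is
  retained.
- Z-scores are computed after the diagnosis exclusion but before any metric
  exclusion (the diagnosis rule is logically prior; the metric rules are
  then order-free because the retained set is the complement of the union
  of flags).
- The two per-hemisphere quality scores are averaged before thresholding
  (configurable to "worst-of-two"); the source protocol does not specify.
- A metric with zero spread flags nobody: with no variance, no point
  deviates from the mean. (The alternative — erroring — would make the
  degenerate all-identical input unusable even though its correct handling
  is obvious.)

**Residualization.** Each feature column is replaced by OLS residuals on an
intercept plus scanner site, quality score, intracranial volume, and ethnic
background (categorical variables one-hot encoded, first level dropped;
rank-deficient designs are rejected with the offending columns named). The
fit uses the full analysis sample *before* any train/test split, mirroring
the emulated study design. This induces a mild dependence between training
and test folds through the shared residualization fit; it is deliberate
(fidelity to the emulated procedure) and is the main known leakage in the
pipeline.

## Clustering

Distance is `1 − ρ` on the Spearman matrix (mid-rank ties), linkage is
*average* (`complete` and Ward on the same distance are available options).
The tree is cut to exactly `k` clusters; `k` is a parameter with defaults 5
at the top level and 2 for subclustering — the structure the analysis is
designed around — because no automatic cut criterion is part of the
emulated procedure, so none is invented. Labels are renumbered 1..k in
order of first appearance, making the partition deterministic given the
input column order; permuting columns permutes labels but not the
partition, and any strictly monotone transform of a column leaves
everything unchanged (rank invariance).

## Brain-age models

The default engine is gradient-boosted regression trees (xgboost) with
maximum depth 6, 140 estimators, and learning rate 0.1 — the tuned optimum
of the emulated analysis, reachable in this package's own randomized search
(`tune_params()`, 10 folds × 10 candidate draws over depth 3–12, 60–220
trees in steps of 40, and rates {0.1, 0.01, 0.05}, scored by
cross-validated MAE). A linear least-squares engine sits behind the same
fit/predict contract; simulation-heavy work (calibration and recovery
studies, most tests) uses it because the synthetic generator's
feature–age relation is linear, making the linear engine both fast and
well-specified for that data.

Folds are a seeded uniform random partition, and one fold assignment is
*shared across all feature sets of a run* so that per-set deltas are
comparable participant by participant — the property the pairwise Z test
depends on. Each participant receives exactly one out-of-fold prediction;
`delta = predicted − age` holds row-wise by construction.

Accuracy is summarized by Pearson r (95% CI via Fisher's z), R² computed as
1 − SSres/SStot (not the square of r, so a mis-calibrated model can score
negative), RMSE, and MAE, all in years. Permutation feature importance is
the mean MAE increase over seeded shuffles of one column at a time.

## Association statistics

**Age-bias correction.** Brain-age predictions regress toward the training
mean, leaving delta negatively correlated with age. Following the emulated
procedure, the main exposure regressions keep raw deltas and adjust for age
as a covariate; group-level analyses (polynomial fits, Cohen's d) first
residualize delta on age. The two schemes agree exactly on the exposure
coefficient (Frisch–Waugh), which the test suite asserts to 1e-8.

**Correlated-estimates Z.** For two feature sets fitted on the same
participants, Z = (β₁ − β₂)/√(σ₁² + σ₂² − 2ρσ₁σ₂). The dependence
parameter ρ is operationalized as the Pearson correlation between the two
*age-corrected delta vectors*: that is the quantity that induces dependence
between the two coefficient estimates, and the phrase "correlation between
the two sets of associations" admits no other computable reading at the
participant level. ρ is an explicit argument of `compare_associations()`,
so alternative operationalizations can be supplied. In the pipeline's
recovery criterion a pairwise difference counts as significant at
uncorrected two-sided p < 0.05; the FDR-adjusted p-values are also reported
(`pairwise_comparisons()`), and the displayed matrix marks adjusted
significance.

**Wilks comparison.** The exposure is regressed on all region deltas (plus
age); dropping one region at a time gives ΔLL = LL_full − LL_reduced ≥ 0,
referred to χ²(1) — one parameter difference per left-out region — with
Z = √(2ΔLL) reported alongside. BH adjustment runs across the left-out
regions. Values of ΔLL negative within numerical tolerance (< 1e-8) are
clamped to zero.

**Polynomial group fits.** Participants are grouped by exposure count;
groups at or above 6 births are merged (placed at their count-weighted mean
exposure) because the tail counts are too sparse for stable means. Group
SE is the within-group SD/√n; degree-1 and degree-2 fits use weights 1/SE²;
the comparison is the standard nested-WLS F. The degree-2 fit is also
reported in orthogonal polynomials — identical fitted values, but
coefficients free of the raw-parameterization collinearity. A group of
fewer than 2 members outside the merge rule is an error (its SE is
undefined). On data where the linear fit already interpolates the group
means, the comparison F is numerically 0/0; tests therefore assert the
zero residual directly rather than the F value.

**Group contrast.** Parous vs nulliparous: OLS of delta on the indicator
plus age; Cohen's d from age-corrected deltas with pooled SD, signed as
parous minus nulliparous so d and β agree in sign, with the large-sample
SE √((n₁+n₂)/(n₁n₂) + d²/(2(n₁+n₂))).

**FDR.** `fdr_adjust()` wraps `stats::p.adjust(method = "BH")` behind a
named pipeline stage with input validation; the test suite checks it
against a brute-force implementation of the step-up definition on 1,000
random vectors.

## The synthetic cohort

The generator emulates the analysis-relevant structure of a large
population imaging cohort of middle- and older-aged women:

- **Ages**: truncated normal (mean 63.59, SD 7.38, range 45.13–82.27
  years), truncation by rejection sampling — the simplest law matching the
  three published moments/bounds.
- **Parity**: multinomial on the empirical group proportions of the
  19,787-women reference sample (mean 1.72, SD 1.16), or exact per-group
  counts for bookkeeping fixtures; parity recording is missing completely
  at random at a configurable rate (default 9/19,796).
- **Volumes**: per region, baseline + linear age slope (−0.25% of baseline
  per year, a typical mid-to-late-life atrophy rate) + confounder terms
  (intracranial volume, site offsets, quality score, ethnicity) +
  correlated Gaussian noise + exposure terms. Baselines are plausible
  bilateral means (e.g. hippocampus 3,900 mm³, accumbens 550 mm³); noise
  CVs are 5.5–9% of baseline, smaller for large well-segmented structures.
- **Correlation structure**: a nested factor model — a block factor shared
  by each of five region blocks (the clustering ground truth, default
  cross-member correlation 0.15) plus a sub-block factor (loadings ≈
  0.35–0.55) splitting the temporo-limbic block into cortical-temporal and
  subcortical-limbic groups, plus hemisphere-specific noise (left/right
  correlation ≈ 0.9). Exposure effects are linear in birth count, matching
  the finding that only the linear term is needed.

What it does **not** emulate: realistic marginal distributions of the
lifestyle covariates (they are plausible but uncalibrated, as the source
publishes no distributions for most), non-linear age trajectories,
site-by-age interactions, longitudinal change, or any image-level artifact
structure. Passing tests therefore demonstrate that the *pipeline*
recovers structure it is pointed at, not that real data contain that
structure.

**The planted effect** (`parity_effect_config()`): per-birth volume
*increases* (less apparent aging) confined to the six subcortical-limbic
regions, with slopes proportional to each region's residual correlation
with the accumbens. This "accumbens-centred channel" has a useful property:
in a joint regression of exposure on all six regions, the unique
contribution falls entirely on the accumbens while every region still
shows a marginal association — the qualitative signature the pipeline is
meant to detect (and the one reported for parity and limbic brain aging).
An earlier design with independent per-region slopes plus a shared factor
shift was rejected: with correlated noise, the small-effect regions acted
as suppressors in the leave-one-out comparison and false-flagged at high
rates. The overall scale (accumbens at 0.18 residual SD per birth,
`strength = 1`) is roughly twice the standardized effect implied by the
reference study's volume associations because the recovery studies run at
n = 5,000 rather than ≈20,000 participants; at the original standardized
magnitudes the unique accumbens contribution would be undetectable at that
sample size and the scenario could not exercise the nested comparison.
With five truly-null regions under BH at q = 0.05 next to one strong
signal, a spurious co-flag retains ≈5–8% probability per replicate purely
from the multiplicity arithmetic, so "only the accumbens flagged" is
expected in roughly 92% of replicates — the recovery rate the acceptance
checks are designed around (≥ 90%).

## Problem sizes and numerical choices

Simulation-based checks use n = 5,000 participants for clustering and
recovery (estimation noise on a Spearman entry is then ≈0.014, far below
the designed within/between-block gaps), n = 500 × 2,000 replicates for the
Monte-Carlo size of the two tests, and 20 seeded replicates for end-to-end
recovery — sizes chosen so each property is measured with comfortable
statistical margin. Exact-arithmetic claims are asserted tightly:
residualization idempotence and Frisch–Waugh to 1e-8, rank-oracle Spearman
to 1e-12, z = β/se to 1e-10. Degenerate inputs either take the obviously
correct limit (zero-spread metrics, constant predictions → R² defined, r
undefined and returned as NA) or error with the offending column named
(constant columns in correlation, rank-deficient designs, undersized
groups or clusters).

## Known limitations

- Residualization-before-split leakage, inherited from the emulated design
  (documented above).
- The linear engine is exact for the generator but is not a substitute for
  the boosted engine on real, non-linear data; the boosted engine is the
  default outside simulations.
- The duplicate listing of the caudal anterior cingulate in the source's
  cluster table (and the omission of the caudal middle frontal region) is
  resolved by assigning each region exactly once: the anterior cingulate to
  the cingulate/polar block, the caudal middle frontal to the
  fronto-central block.
- p-values from the χ²(1) reference for the Wilks Z are asymptotic; at the
  simulated sample sizes this is inconsequential, but the choice is
  recorded because published per-region p-values are not always consistent
  with any single reference distribution.
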