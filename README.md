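# regionage

Regional brain-age modelling and its association with number of childbirths,
as a tested, reusable R pipeline.

## The problem

Brain-age prediction estimates a person's age from structural MRI features;
the *brain-age delta* (predicted minus chronological age) summarizes whether
their brain looks older or younger than expected. Global deltas compress all
regions into one number. This package implements the *regional* variant of
the analysis: regional volumes (34 Desikan–Killiany cortical regions per
hemisphere plus 17 subcortical volumes) are hemisphere-averaged, residualized
on scanner and quality nuisance variables, grouped into covariance clusters
by hierarchical clustering on Spearman rank correlations, and a separate
cross-validated prediction model is fitted per cluster, per subcluster, and
per single region. Each feature set yields its own delta, whose association
with an exposure count — here, number of live childbirths in a cohort of
middle- and older-aged women, motivated by evidence that pregnancy-related
brain changes may be traceable decades later — is then tested and compared.

The statistical core:

- **Exposure regression.** OLS of delta on exposure with chronological age
  as covariate (classical SEs, two-sided t tests), optionally with an
  extended covariate set; Benjamini–Hochberg FDR across feature sets.
- **Correlated-estimates Z test.** Two feature sets fitted on the same
  participants give dependent coefficient estimates; they are compared with

  Z = (β₁ − β₂) / √(σ₁² + σ₂² − 2ρσ₁σ₂),

  with ρ the correlation between the two age-corrected delta vectors.
- **Leave-one-out log-likelihood comparison.** Exposure is regressed on all
  region-specific deltas jointly; each region is dropped in turn and
  ΔLL = LL_full − LL_reduced is referred to χ²(1) via Wilks' theorem
  (Z = √(2ΔLL)), isolating regions with *unique* contributions.
- **Weighted polynomial group fits.** Per-parity group means of
  age-corrected delta (sparse tail groups merged), fitted by degree-1 and
  degree-2 weighted least squares (weights 1/SE²), with an F comparison and
  an orthogonal-polynomial cross-check.

Because the motivating data (UK Biobank) are restricted, the package ships a
calibrated synthetic-cohort generator (`sim_config()`, `simulate_cohort()`)
that reproduces the analysis-relevant structure — truncated-normal ages,
the empirical parity distribution, age trends, confounder loadings, block-
structured residual correlation across regions, and an optional planted
parity effect concentrated in subcortical-limbic regions
(`parity_effect_config()`). Every stage is therefore testable end to end.

## Worked example

```r
library(regionage)

cfg <- pipeline_config(
  sim    = parity_effect_config(n = 5000, seed = 1),  # synthetic cohort
  params = model_params(engine = "lm"),               # fast linear engine
  seed   = 1
)
result <- run_pipeline(cfg)
result
#> Regional brain-age pipeline
#>   retained n: 4997 of 5000
#>   clusters: 5 | strongest association: cluster_3 -> subclusters: 2 | strongest: subcluster_2
#>
#> Cluster associations (delta ~ births + age):
#>   feature_set         beta         se          t            p        p_adj
#> 1   cluster_1 -0.009399834 0.02628410 -0.3576243 7.206396e-01 7.206396e-01
#> 2   cluster_2  0.016308510 0.02874979  0.5672567 5.705653e-01 7.206396e-01
#> 3   cluster_3 -0.210844714 0.03288367 -6.4118357 1.570359e-10 7.851797e-10
#> 4   cluster_4 -0.010289125 0.02544932 -0.4042986 6.860105e-01 7.206396e-01
#> 5   cluster_5  0.031942852 0.02850004  1.1208002 2.624268e-01 6.560670e-01
```

Three participants were excluded by the QC rules, the five planted
covariance blocks were recovered, and only the temporo-limbic cluster
(cluster 3) shows a negative association: about −0.21 years of apparent
brain aging per childbirth, FDR-significant, while the other four clusters
sit at chance. Drilling down:

```r
result$nested       # leave-one-out log-likelihood comparison, 6 regions
#> # A tibble: 6 x 5
#>   region           delta_ll       z        p    p_adj
#> 1 parahippocampal  0.000668  0.0365 9.71e- 1 9.71e- 1
#> 2 thalamus         0.383     0.875  3.81e- 1 7.63e- 1
#> 3 putamen          0.585     1.08   2.80e- 1 7.63e- 1
#> 4 hippocampus      0.0578    0.340  7.34e- 1 8.81e- 1
#> 5 amygdala         0.0963    0.439  6.61e- 1 8.81e- 1
#> 6 accumbens       96.8      13.9    5.02e-44 3.01e-43
```

Only the accumbens — where the generator plants its region-unique effect —
contributes uniquely beyond the shared limbic signal. The parous versus
nulliparous contrast on the strongest subcluster gives β = −0.65 ± 0.08
years (d = −0.27 ± 0.03): parous women show less apparent brain aging in
this synthetic scenario.

Result objects are tibble-friendly: `tidy(result)` stacks the association
tables, `glance(result)` gives the one-row run summary,
`autoplot(result$clustering)` draws the dendrogram,
`plot_comparison_matrix(result$comparisons)` the pairwise Z matrix, and
`write_results(result, "out/")` emits all tables as CSV with a JSON
provenance record. `replicate_split()` reproduces the train/new-participants
replication design with the weighted polynomial fits, and
`inst/scripts/run_pipeline.R` wraps the pipeline for shell use.

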