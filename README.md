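# scnet — structural covariance network analysis of ROI cortical thickness

scnet compares the brain-network organization of two subject groups from
nothing more than subject-by-ROI cortical thickness tables. It is aimed at
morphometry studies (e.g. a patient group vs matched controls) that ask
whether *structural covariance* — the tendency of regional thickness values
to rise and fall together across subjects — is topologically reorganized,
even when no single region differs much in mean thickness.

## The method

A structural covariance network (SCN) has atlas ROIs as nodes; for each
group separately, the edge weight between ROIs *m* and *n* is the Pearson
correlation r<sub>mn</sub> of their (covariate-adjusted) thickness across
that group's subjects. The analysis chain is:

1. **Adjust**: each ROI column is replaced by OLS residuals on
   intercept + age + gender + education, fitted on the pooled sample.
2. **Threshold**: the correlation matrix is binarized at every density *d*
   of a grid by connecting the k = round(d·N(N−1)/2) pairs with largest
   |r<sub>mn</sub>|. The grid starts at 2·log₁₀(N)/(N−1), rounded up to the
   grid step (0.02 for N = 360), and ends at 0.47 by default or where the
   control group's small-worldness drops below 1.1.
3. **Measure**: per ROI — degree, betweenness centrality, nodal efficiency;
   per network — global efficiency, local efficiency, clustering
   coefficient C<sub>p</sub>, characteristic path length L<sub>p</sub>, and
   small-worldness σ = (C<sub>p</sub>/C<sub>p</sub><sup>rand</sup>)/(L<sub>p</sub>/L<sub>p</sub><sup>rand</sup>)
   against degree-preserving rewired reference graphs.
4. **Compare**: each property is reduced to its area under the curve (AUC)
   across the density grid; the observed group difference is referred to a
   permutation null built by relabeling subjects (group sizes preserved)
   and recomputing the entire pipeline. p-values use the add-one estimator
   (1 + #{|Δ<sup>null</sup>| ≥ |Δ<sup>obs</sup>|})/(1 + P); a 95% CI rule is
   reported alongside, and per-ROI statistics get Benjamini–Hochberg FDR
   across ROIs.

A latent-factor synthetic-data generator (`scn_simulate()`) with planted
covariance structure, thickness deficits and a correlated clinical score
makes the whole chain testable without any imaging data.

## Worked example

Simulate a study-sized dataset (45 subjects per group, 24 ROIs) in which one
ROI's covariance with its community is weakened in group 2, then run the
comparison:

```r
library(scnet)
cfg <- scn_sim_config(n_per_group = 45, n_rois = 24, n_factors = 2,
                      factor_loading = 0.9, planted_hub_rois = 8L,
                      hub_loading_delta = -0.6, seed = 3)
ds  <- scn_simulate(cfg)
rt  <- residualize(ds$thickness, ds$covariates)
cmp <- scn_compare(rt, grid = density_grid(24),
                   metrics = c("eglob", "eloc", "cp", "lp", "degree"),
                   n_perm = 500, seed = 7)
cmp
#> Structural covariance network comparison: group1 (n=45) vs group2 (n=45)
#>   densities 0.13-0.47 (35 points), 500 permutations, alpha = 0.05
#>   global AUC differences (group1 - group2):
#>     eglob  +0.006904  (p = 0.2535)
#>     eloc   +0.01935  (p = 0.3333)
#>     cp     +0.00966  (p = 0.497)
#>     lp     +0.002188  (p = 0.8922)
#>   regional: 1 of 24 ROI statistics FDR-significant

summary(cmp)$regional[, c("metric", "roi", "diff", "p", "fdr_significant")]
#>    metric      roi  diff           p fdr_significant
#> 12 degree L_ROI008 2.865 0.001996008            TRUE
```

The global metrics show no group difference (all p > 0.05) — the planted
effect is purely nodal — while the degree AUC flags exactly the planted ROI
(`L_ROI008`): its degree-versus-density curve integrates 2.87 units higher
in group 1 than in group 2, a difference more extreme than all 500
permutation nulls (p = 1/501), surviving FDR across the 24 ROIs.

The generator also plants a clinical pain score whose correlation with
deficit-ROI thickness targets −0.533; the partial correlation given age,
gender and education recovers it:

```r
g2 <- ds$thickness$group == "group2"
pc <- partial_correlation(
  rowMeans(ds$thickness$values[g2, ds$truth$deficit_rois]),
  ds$clinical$plp, ds$covariates,
  subject_id = ds$thickness$subject_id[g2])
#> partial r = -0.619 (p = 1.2e-05)
```

`run_scn_pipeline()` chains simulate/load → flip → residualize → grid →
compare from one config list (or YAML file) and writes result TSVs plus a
manifest with checksums; see `?run_scn_pipeline`.

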