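---
title: "Structural covariance network analysis with scnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural covariance network analysis with scnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scnet)
```

## The analysis

A structural covariance network (SCN) is a group-level brain graph: nodes are
atlas regions of interest (ROIs), and an edge between ROI $m$ and ROI $n$
reflects the Pearson correlation, across the subjects of one group, between
their mean cortical thickness values. Because one network describes one
*group* (not one subject), comparing SCNs between a patient group and a
control group requires permutation inference over subjects rather than
ordinary per-subject statistics. scnet implements that full chain for
subject-by-ROI thickness tables:

1. **Covariate adjustment** (`residualize()`): each ROI column is replaced by
   the residuals of an OLS fit on intercept + age + gender + education.
2. **Covariance** (`scn_covariance()`): the ROI-by-ROI Pearson correlation
   matrix $R$ per group, diagonal defined as zero.
3. **Binarization over a density grid** (`density_grid()`,
   `scn_binarize()`): the $k = \mathrm{round}(d \cdot N(N-1)/2)$ pairs with
   largest $|r_{mn}|$ are connected at each density $d$ of the grid.
4. **Graph metrics** (`regional_metrics()`, `global_metrics()`): degree,
   betweenness centrality and nodal efficiency per ROI; global efficiency
   $E_{glob}$, local efficiency $E_{loc}$, clustering coefficient $C_p$,
   characteristic path length $L_p$, and small-worldness
   $\sigma = (C_p/C_p^{rand})/(L_p/L_p^{rand})$ against degree-preserving
   rewired reference graphs (`reference_ensemble()`).
5. **Permutation inference** (`scn_compare()`): each property is summarized
   by its trapezoidal area under the curve (AUC) across the density grid;
   the group-1 minus group-2 AUC difference is referred to a null
   distribution obtained by relabeling subjects (group sizes preserved) and
   recomputing the entire pipeline; per-ROI statistics get
   Benjamini–Hochberg FDR correction across ROIs.

## Parameters that matter

* **Density grid.** The minimum density is $2\log_{10}(N)/(N-1)$ rounded up
  to the next multiple of the grid step (default 0.01). Base-10 log plus
  ceiling is used because, for $N = 360$ ROIs, it gives
  $2\log_{10}(360)/359 = 0.0142 \rightarrow 0.02$, the conventional
  starting density for a 360-ROI SCN, whereas a natural log would give
  0.033. The base is configurable. The default upper end is 0.47;
  `sigma_bounded_dmax()` can instead truncate the grid at the largest
  density where the *control* group's network keeps $\sigma \ge 1.1$ — the
  rationale being that beyond that range the brain graph no longer shows
  small-world organization and topological comparison becomes
  uninformative.
* **Exact-density thresholding.** Densities are realized exactly (top-$k$
  selection on $|r|$) rather than via a fixed correlation cutoff, so both
  groups' networks always have identical edge counts at every grid point —
  a prerequisite for comparing topology rather than mean correlation. Ties
  in $|r|$ are broken by (row, column) order so the edge set is
  deterministic; edge sets are nested across densities. By default the
  absolute correlation is used (strong negative covariance also forms an
  edge); `positive_only = TRUE` restricts to positive correlations.
* **Path-length convention.** $L_p$ averages hop distances over *connected*
  pairs only. Sparse SCNs are routinely disconnected, and any
  infinite-distance convention would make the AUC statistic undefined;
  efficiency-type metrics already handle disconnection through
  $1/\infty = 0$. A largest-component $L_p$ would be the main alternative;
  the connected-pairs version is used because it keeps every node's
  contribution.
* **Betweenness** is reported unnormalized (raw pair counts). Group
  inference is unaffected because both groups share $N$.
* **Small-world null.** $\sigma$ needs a random reference; the package uses
  Maslov–Sneppen double-edge-swap ensembles (default 100 graphs, 10
  attempted swaps per edge) which preserve each node's degree exactly.
  Inside permutation inference the ensemble is regenerated for every
  permuted group (`sigma_null = "regenerate"`); `"reuse"` normalizes all
  permutations by the observed groups' ensemble means, which is much
  cheaper and adequate when only the observed curves are of interest.
* **Permutations.** The study-scale default is `n_perm = 5000` with
  $\alpha = 0.05$. The p-value uses the add-one estimator
  $p = (1 + \#\{|\Delta^{null}| \ge |\Delta^{obs}|\})/(1 + P)$, which never
  returns zero; its floor is therefore $1/(P+1)$. Significance is also
  reported by the 95% confidence-interval rule (observed difference outside
  the null's 2.5–97.5 percentile band); both conventions appear in the
  results table, as does per-ROI FDR (`fdr_significant`) alongside
  uncorrected permutation significance, so either reporting convention can
  be reproduced.
* **Welch vs pooled t.** `roi_group_test()` defaults to Welch's
  unequal-variance test (`var_equal = TRUE` switches to pooled), a safer
  default when group variances may differ.
* **Pooled residualization.** Covariate adjustment is fitted once on both
  groups together, with no group term, *before* permutation. Under the
  null this keeps subjects exchangeable, so each permutation only relabels
  rows; per-group adjustment would have to be refitted inside every
  permutation and would break exchangeability. Gender coding is irrelevant
  (any affine recoding of a covariate leaves residuals unchanged; this is
  asserted in the tests).

## The synthetic-data generator

`scn_simulate()` draws two groups of subject-by-ROI thickness tables from a
latent-factor covariance model: ROIs are partitioned into `n_factors`
contiguous communities and

$$x_{si} = \mu_i + \sigma\left(\lambda_i z_{s f(i)} +
  \sqrt{1-\lambda_i^2}\,\epsilon_{si}\right) + \beta^\top c_s,$$

with per-ROI baselines $\mu_i \sim N(2.5, 0.25^2)$ mm, factor scores
$z \sim N(0,1)$, total fluctuation $\sigma$ = `noise_sd` = 0.15 mm, and
loadings on the correlation scale, so the within-community ROI–ROI
correlation is `factor_loading`² (default 0.36 — the magnitude typical of
thickness covariance). Group 2 receives a mean deficit of `deficit_mm` on
designated ROIs (default 0.1 mm on two sensorimotor-designated ROIs) and a
loading change `hub_loading_delta` on planted hub ROIs, which alters those
ROIs' covariance with their community and hence their nodal network profile.
Defaults mirror a two-group amputee/control thickness study: 45 subjects per
group, 360 ROIs, age ≈ 45 ± 9 y, education ≈ 7.5 ± 4.3 y, about one quarter
female, pain scores ≈ 3.9 ± 2.7 on a 0–10 scale.

The clinical pain score for group-2 subjects is built by the standard
construction $\mathrm{score} = r z^* + \sqrt{1-r^2}\eta$ with target
$r$ = `clinical_target_r` (default −0.533), where $z^*$ is the standardized
*structural* component of the subject's mean deficit-ROI thickness — i.e.
the part not driven by age, gender or education. The partial correlation
given covariates therefore estimates $r$ itself, while the plain correlation
with raw thickness is mildly attenuated. The score is mapped linearly to a
0–10-style scale and left unclipped so the correlation is preserved exactly.

All randomness derives from one master seed through fixed per-stage
substreams, so adding a later stage never changes earlier draws, and
identical configs give byte-identical written tables.

What the generator does **not** emulate: images, surfaces or vertex maps;
spatial autocorrelation between neighbouring ROIs; scanner or site effects;
non-Gaussian thickness distributions; missing data. Passing tests therefore
validate the *pipeline's statistics* — calibration, recovery, determinism —
not robustness to those real-data features.

## Validation design and problem sizes

The test suite validates each stage against independent references, at
problem sizes chosen to keep the whole suite in the tens of minutes on one
core:

* Every graph metric is checked to $10^{-12}$ relative accuracy against an
  exhaustive path-enumeration oracle on 200 random graphs of up to 7 nodes
  (and betweenness additionally against igraph on larger graphs).
* A Watts–Strogatz ring lattice (n = 100, k = 6, p = 0.05) must give
  $\sigma > 1.1$, and matched Erdős–Rényi graphs a mean $\sigma$ within
  0.2 of 1 over 20 seeds: random graphs are their own null.
* Type-I error: 200 synthetic null datasets (20 subjects/group, 60 ROIs,
  nothing planted), 500 permutations each — global-metric rejection at
  $\alpha = 0.05$ must land in [0.03, 0.08] and the null FDR
  false-discovery proportion must average ≤ 0.05.
* Recovery: a planted nodal covariance difference must be FDR-significant
  for degree-AUC in ≥ 80% of 25 seeds at 45 subjects/group.
* The generator's clinical correlation target must be recovered within
  ±0.25 in ≥ 95% of seeds at n = 45.

Two design points in the recovery test deserve explanation. First, with
$P = 500$ permutations the p-value floor is $1/501 \approx 0.002$, while
Benjamini–Hochberg rank-1 significance across $m$ ROIs requires
$p \le 0.05/m$; for $m \ge 26$ a single affected ROI can never survive FDR
at that permutation count. The recovery test therefore uses a 24-ROI
network. Second, a hub whose loading is *raised* is weakly identifiable at
$n = 45$: loadings are capped at 1 and the sampling noise of a correlation
scales with $1-r^2$, so across the entire admissible range the planted
degree effect stays within about three null standard deviations. The
planted difference is instead a hub whose community covariance is *lowered*
in group 2 (baseline loading 0.9, delta −0.6) — the same direction as
thickness-network decreases typically reported in patient groups — where
the tight baseline community makes edge ranks nearly deterministic and the
effect unambiguous. Inference is two-sided throughout, so the statistic is
identical for increases and decreases.

## Degenerate inputs and numerical corners

Constant ROI columns make the correlation undefined and raise an error
naming the ROI; constant covariates raise an error naming the covariate. A
density below one edge errors rather than returning an empty graph. Degree
sequences that admit no rewiring (a star) degrade the reference ensemble to
copies of the original graph with a warning flag. Zero-variance ROIs in the
group comparison are flagged and reported with $p = 1$. Subject order never
matters: `scn_compare()` canonicalizes row order internally before drawing
permutations.

## Limitations

The package starts from ROI-level thickness tables; image-space processing
(segmentation, surface estimation, smoothing, vertex-wise statistics,
cluster-level corrections) is out of scope, and hemisphere flipping is
supported only as a table-level homologue swap (`flip_homologues()`), an
approximation to flipping images before thickness extraction. Networks are
binary, undirected and unweighted; weighted or directed variants, modularity
and hub classification are not provided. Permutation inference recomputes
the full pipeline per permutation; with sigma included and
`sigma_null = "regenerate"` this is expensive, which is the price of an
exact null for the normalized index.
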