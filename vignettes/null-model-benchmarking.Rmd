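---
title: "Benchmarking small-world parameters of structural correlation networks against three null-network families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking small-world parameters of structural correlation networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A structural correlation network represents brain regions as nodes and
across-subject Pearson correlations of a morphometric measure (here,
regional gray-matter volume) as edges. Thresholded at a fixed density, such
networks look strikingly "small-world": clustering well above degree-matched
random graphs, path lengths close to them. But part of that clustering is an
artifact of how the network was built. Correlation is transitive — if
regions A and B correlate strongly and B and C correlate strongly, A and C
cannot avoid correlating — so *any* correlation-derived network carries
inflated clustering relative to a topology-randomized reference. The choice
of null network therefore decides how much small-worldness one reports, and
can change the outcome of group comparisons.

`swnull` implements the full benchmarking pipeline around that question:
build the networks, normalize their metrics against three null families,
and test within-group (between-family) and between-group differences with a
functional-data-analysis (FDA) area statistic under resampling. Because the
motivating cohort data are private, the package ships a synthetic generator
that reproduces the *structure* of the problem, and every result in this
vignette, the tests and the acceptance script is computed on synthetic data.

## Pipeline and model

1. **Covariate correction.** Per region, ordinary least squares of volume on
   intercept + age + sex + total brain volume; residuals ("corrected RGV")
   replace raw values. The intercept is always included so residual columns
   are mean-zero, which makes the downstream Pearson step well defined.
   Regression is fitted per group; the pooled alternative is available by
   passing pooled data, but per-group fitting avoids leaking group mean
   differences into the residuals.
2. **Network construction.** The region-by-region Pearson matrix is
   thresholded at each density `d` of a grid (default `[0.22, 0.02, 0.50]`):
   keep the `round(d * n(n-1)/2)` pairs with the largest *signed*
   correlation. The grid's lower bound is `D_min`, the smallest grid density
   at which every group's network is a single connected component.
3. **Null families.**
   - **TOP** — connected double-edge-swap randomization preserving the
     exact degree sequence (and simplicity and connectedness). Destroys all
     correlation structure including transitivity.
   - **HQS** — random covariance matrices moment-matched to the observed
     one via a Gram construction `C = B B'`, thresholded (after conversion
     to correlation) at the matched density. Preserves transitivity;
     destroys the specific empirical structure.
   - **COR** — each subject's region vector is independently permuted, the
     Pearson matrix recomputed and thresholded at the matched density.
4. **Normalized metrics.** With `C_null`, `L_null` the means over an
   ensemble of `m = 20` nulls: `gamma = C / C_null`,
   `lambda = L / L_null`, `sigma = gamma / lambda`. Small-worldness is the
   pattern `gamma > 1`, `lambda ≈ 1`, `sigma > 1`.
5. **Inference.** Two curves (metric versus density) are compared by the
   FDA area `A = Σ_i |y2(x_i) − y1(x_i)|`, cumulatively and within four
   density windows (`[0.22,0.30]`, `[0.30,0.38]`, `[0.38,0.46]`,
   `[0.46,0.50]`). Null-family differences use a dependent-samples design:
   300 bootstrap resamples of the subjects, family labels shuffled within
   each bootstrap sample, 5000 shuffles. Group differences use an
   independent-samples design: subjects reassigned to pseudo-groups of the
   original sizes, 1000 permutations, association matrices and curves
   rebuilt each time. Bonferroni correction is offered across family pairs
   and metrics.
6. **Auxiliary analyses.** Replicability: 50 sets of 20 nulls per family at
   `D_min`, one-way ANOVA on per-set means (stability) and Levene's test on
   per-member dispersion across families. Skewness: Pearson correlations
   between the degree skewness of bootstrap networks at `D_min` and the
   between-family differences in normalized clustering / small-worldness,
   and the clustering of the matched TOP nulls.

## The HQS construction

From the observed covariance matrix, let `dbar` be the mean diagonal entry,
`e > 0` and `v > 0` the mean and variance of the off-diagonal entries. With

```
m_f     = max(2, round((dbar^2 - e^2) / v))
mu      = sqrt(e / m_f)
sigma^2 = sqrt(mu^4 + v / m_f) - mu^2
```

and `B` an `n × m_f` matrix of i.i.d. `Normal(mu, sigma^2)` entries,
`C = B B'` is positive semidefinite by construction and satisfies exactly

- `E[C_ij] = m_f mu^2 = e`,
- `Var[C_ij] = m_f ((mu^2 + sigma^2)^2 - mu^4) = v`,
- `E[C_ii] = sqrt(e^2 + m_f v) ≈ dbar` (equality up to the integer rounding
  of `m_f`).

The unit tests verify these identities symbolically on fixture data; the
acceptance suite also verifies them by Monte Carlo over 200 draws against a
90-region block-model covariance. Because empirical correlation values need
not be normally distributed, HQS networks are matched to the target
*density* (rank thresholding on the correlation scale) rather than cut at a
fixed correlation; thresholding on the correlation rather than covariance
scale is this package's documented choice — the two differ only through the
random diagonal, and the correlation scale mirrors the empirical pipeline.

## The synthetic generator: what it emulates and what it does not

`simulation_config()` draws each group from a multivariate normal whose
correlation matrix is block-constant: `within_block_r` inside each of
`n_blocks` communities, `between_block_r` elsewhere. Defaults are two
cohorts of 31 and 28 subjects, 90 regions in 6 blocks, `within = 0.5`,
`between = 0.1`, noise SD 1. The block design was chosen over a factor
model because positive semidefiniteness is easy to verify analytically and
the community structure gives thresholded networks controllable
small-worldness — at the default settings all three null families report
`gamma > 1` and `sigma > 1` across the whole grid, the qualitative premise
of the whole analysis. The group effect is a multiplicative attenuation of
group 2's between-block correlation (`group_effect = 0.8` in the analysis
scripts: a 20% weakening of between-community coupling).

Covariates are age (uniform on 4–20 years), sex (Bernoulli(0.5)) and a
total-volume proxy (normal, mean 1200, SD 100); their effects are strictly
linear with one slope per covariate applied to every region, matching the
linear correction step. One seed governs all draws of a dataset, with
per-group and per-stage child seeds derived deterministically
(`derive_seed()`), so every fixture is bit-reproducible.

What the generator does *not* emulate: anatomical geometry (no atlas
coordinates, no lobar structure, no distance-dependent correlations),
non-Gaussian morphometry, heteroscedastic regions, scanner or site effects,
and subject-level outliers. Passing tests on this generator therefore show
that the *procedures* behave correctly (invariants, calibration,
direction of known effects), not that real gray-matter networks have any
particular parameter value.

## Numerical choices

- **Edge ranking** is by signed correlation (largest first), not absolute
  value: the windowed analysis equates "lower densities" with "stronger
  correlations", which presumes signed ordering. Ties break
  deterministically (higher r, then lexicographic node pair), so edge sets
  are nested across densities and `D_min` search can exploit monotone
  connectivity.
- **Density quantization** rounds half away from zero on the edge count;
  the achieved density is recorded and used downstream.
- **Path length on fragmented graphs** is the connected-pairs-only mean
  (infinite distances excluded, their count reported). HQS and COR nulls
  can fragment, and the ensemble mean has to remain finite. Largest
  component and harmonic-mean conventions were rejected to keep a single
  auditable rule.
- **Fragmentation policy** for ensembles defaults to `keep` (fragmented
  members enter the mean under the rule above, with a fragmentation count
  reported); `discard` (bounded redraws) and `error` are available.
- **TOP on a disconnected input**: the per-swap reachability rule never
  splits a component (it can only preserve or merge them), so rewiring a
  fragmented bootstrap network is well defined; the output records its
  connectivity. On connected inputs the classic guarantee — connected,
  simple, degree-preserving — holds, and is exercised exhaustively in the
  tests (on 6-node paths, every rewired output is provably a relabeled
  path). The swap budget is 10 accepted swaps per edge, standard rewiring
  practice.
- **p-values** use the add-one convention `(count ≥ observed + 1) /
  (n_perm + 1)`, guaranteeing `p ∈ (0, 1]`; the test statistic is the
  upper tail of the non-negative area, with direction reported separately
  through the signed area.
- **Dependent-test statistic**: the FDA area between the two families'
  *mean* curves (label shuffles flip per-bootstrap difference signs). The
  absolute signed-area variant is available via `statistic =
  "signed_area"`.
- **Independent test with normalized metrics** offers two modes.
  `regenerate` rebuilds null ensembles for every pseudo-group in every
  permutation — faithful but expensive. `reuse` (default in the pipeline)
  normalizes all curves by fixed null-mean curves computed once from the
  pooled data; it is labeled approximate in every report it touches.

## Problem sizes used in the shipped analyses

The `analysis/` scripts and `scripts/acceptance.R` run at a demonstration
scale chosen so a complete end-to-end pass stays in the minutes range on a
single core: 30–31 subjects per group, 90 regions, ensembles of 8–20 nulls,
30–50 bootstrap samples, 300–2000 shuffles/permutations. The study-scale
defaults (300 bootstraps, 5000 shuffles, 1000 permutations, 20 nulls) are
the package defaults and can be restored through `pipeline_config()`.
Calibration tests run 200 replicate experiments at 40 regions with 500
permutations each and check the empirical rejection rate at `alpha = 0.05`
against its binomial confidence band.

## Known limitations

- The `reuse` mode's fixed normalizers make the normalized-metric group
  test approximate; for publication-grade inference use `regenerate`.
- HQS is undefined when the mean off-diagonal covariance is non-positive
  (the Gram construction needs `e > 0`); very weakly correlated or
  sign-mixed data will error, by design, rather than silently return a
  reference family that does not match the data.
- The dependent-samples design assumes both families' curves were computed
  on the *same* bootstrap samples; `bootstrap_model_curves()` enforces
  this by construction.
- Bootstrap resampling with replacement inflates correlations, so bootstrap
  curve levels deviate from the original network's; comparisons across
  families on the same bootstrap samples are unaffected, and the effect is
  asserted (not just assumed) in the test suite.
- Small-world indices are relative measures: everything reported here is
  conditional on the chosen null family, which is precisely the package's
  point.
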