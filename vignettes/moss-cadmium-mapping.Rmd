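---
title: "Mapping cadmium in forest mosses with a bounded-response regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping cadmium in forest mosses with a bounded-response regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mossmap)
```

## The problem

Terrestrial mosses accumulate atmospheric metals and are sampled by national
biomonitoring networks as proxies for deposition. Mapping a metal such as
cadmium from a few hundred forest sites onto a national grid raises three
linked statistical problems that this package addresses as one pipeline:

1. concentrations are bounded — an untransformed linear model happily
   predicts negative or implausibly large values on grid cells whose
   covariates lie far from the sampled forests;
2. candidate covariates are many and strongly redundant — land-use
   percentages computed in nested buffers (1/5/10/15 km) around each site
   are near-copies of each other;
3. the added value of covariates over a purely spatial interpolation
   (ordinary kriging) must be demonstrated, not assumed.

## The model

Let $Y_i$ be the Cd concentration (µg/g) at site $i$ and $Cd_{max}$ a fixed
upper bound for concentrations in mosses (default 1.5 µg/g). The package
fits the complementary log–log (CLL) linear model

$$\ln\!\big(\ln(Cd_{max}/Y_i)\big) \;=\; \alpha + \sum_{j=1}^N \beta_j X_i^j
  + \epsilon_i, \qquad \epsilon_i \sim N(0, \sigma^2),$$

by ordinary least squares on the transformed response
$z_i = \ln(\ln(Cd_{max}/Y_i))$. The double logarithm maps $(0, Cd_{max})$
onto the whole real line, so any fitted linear predictor back-transforms to
a concentration strictly inside the physical range:
$\hat y = Cd_{max}\exp(-\exp(\hat\eta))$. The transform is monotone
*decreasing*: positive coefficients on the transformed scale mean lower
concentrations. Because the back-transform of the conditional median is the
median of the back-transform, the mapped surface is a **median-scale** map;
no smearing or lognormal-style bias correction is applied, and the package
does not produce mean-scale maps.

Categorical design variables — moss species, tree-cover class,
biogeographical zone — are dummy-coded against fixed reference levels
(`Hc`, `deciduous`, `Alpine`), so maps read as "Hc mosses under deciduous
cover" unless another profile is requested in `predict_grid()`.

## Covariate screening and selection

Selection is staged, mirroring how redundant buffered covariates are
handled in biomonitoring practice:

* **Zero filter** (`zero_filter()`): a quantitative covariate is dropped
  when its proportion of *exact* zeros on the analysis scope is strictly
  greater than 0.95 ("more than 95 %" is read literally, so a variable with
  exactly 95 % zeros survives). For a nation-wide model the proportion is
  pooled across all rows by default; `by_zone = TRUE` instead drops a
  variable that is sparse in any single zone. Both readings are defensible
  for a nation-wide fit; pooling is the default because the nation-wide
  scope is "all rows".
* **Spearman filter** (`spearman_filter()`, threshold 0.75 on $|\rho|$,
  average ranks for ties): within a buffer family, connected components of
  over-threshold pairs collapse to the smallest-radius member (the most
  local signal); across families, while any pair exceeds the threshold
  (worst pair first), the member with the larger mean absolute correlation
  to everything else is removed. This tie-break keeps the *less* redundant
  variable and makes the procedure deterministic; re-evaluation after each
  removal prevents over-pruning. Zero-variance variables are removed up
  front since their rank correlation is undefined.
* **Backward–forward AIC** (`stepwise_aic()`): best-first search — at each
  iteration every single-variable drop and every eligible add is scored and
  the move with the largest AIC decrease is taken; the search stops when no
  move decreases the AIC, which guarantees termination. Categorical
  variables move as whole dummy blocks. The AIC uses the Gaussian
  likelihood with the ML variance and counts the variance parameter
  ($AIC = -2\ell + 2(k+1)$, the `stats::AIC()` convention); model rankings
  are unaffected by the additive constant. Covariates are never
  standardised: effects are reported in native units, and AIC selection is
  scale-invariant. Non-significant covariates that reduce the AIC stay in
  the model; no significance-based pruning is added.

## Residual spatial diagnostics

`moran_i()` computes Moran's $I$ on the transformed response and on the
residuals of the selected model, with spatial weights built as symmetrised
binary $k$-nearest-neighbour matrices ($k = 8$ by default — robust to the
irregular density of real networks; inverse-distance or user matrices can
be supplied). The p-value comes from random permutations of the values over
the sites (999 by default), which remains valid at the smallest zone sizes
where normal approximations are doubtful. The reported test is one-sided
for *clustering* (proportion of permuted statistics at or above the
observed one): that is the question the before/after-covariates diagnostic
asks, and it keeps the test exact at its nominal level, which the test
suite verifies by simulation. Dispersion and two-sided alternatives are
available. A `halve` flag reproduces, off by default, the convention of
reporting $I/2$ used in some analyses; no interpretation of that convention
is attempted.

## Prediction and uncertainty

`predict_grid()` evaluates $\hat\eta(s)$ on a grid with categorical levels
fixed at the reference profile, takes the standard error of the fitted mean
from the coefficient covariance, and propagates it to the concentration
scale by the delta method:

$$sd_y(s) = \left|\frac{d\hat y}{d\eta}\right| se_\eta(s),
 \qquad \frac{d\hat y}{d\eta} = -Cd_{max}\,e^{\eta - e^{\eta}}.$$

The default SD describes the fitted median surface; a flag adds the
residual variance for the SD of a new observation. The delta approximation
is accurate to a few percent for $se_\eta \lesssim 0.2$ (checked against a
$10^6$-draw Monte-Carlo oracle in the test suite). Grid cells with any
covariate outside the training range are *flagged* as extrapolation rather
than masked — urban cells predicted from forest-calibrated models are a
real and acknowledged limitation of this kind of mapping, and hiding them
would overstate confidence. Per-zone maps are combined with
`mosaic_zone_maps()`, which enforces that every cell is claimed by exactly
one zone model.

## The kriging baseline

`fit_variogram()` computes the classical Matheron semivariogram of log
concentrations and fits an exponential model (spherical and Gaussian are
available) by weighted least squares with pair counts as weights; the
exponential family is the default because it is the least structured of
the common choices. `ok_predict()` solves the ordinary-kriging system with
the unbiasedness constraint per cell (one global neighbourhood up to 500
sites, nearest 64 beyond that), back-transforms point predictions by
exponentiation and propagates the log-scale kriging SD by the delta method.
No lognormal bias correction is applied, so kriged maps are median-type
maps, consistent with the regression maps; the small systematic
underestimation of the mean that this implies is a documented property, not
a bug. Singular systems (duplicate sites with zero nugget) get one
jitter-and-retry before failing.

A caution from the package's own simulations: parameters fitted to a
single realisation of ~300 sites carry large ergodic fluctuation — the
nugget/sill split especially can easily be off by more than 30 % even when
the variogram family is correct. Kriged surfaces are much more stable than
the parameters themselves, but fitted variogram parameters should be read
as descriptive, not as precise estimates.

## Predictive comparison

`loocv()` scores both predictors by leave-one-out cross-validation **on the
concentration scale**: each site is predicted from a refit on the other
$M-1$ sites and $RMSE = \sqrt{\sum_i (y_i - \hat y_i)^2 / M}$. Two design
decisions matter:

* The variable set (regression) and the variogram (kriging) are fixed
  once, on the full data, and *not* re-selected inside folds. This matches
  the single reported variable list per scope, at the cost of a modest
  optimism bias that is documented rather than corrected.
* On the transformed scale the per-fold refits coincide with the
  closed-form leave-one-out identity for linear smoothers
  ($e_i/(1-h_{ii})$) — the suite uses that identity as an internal oracle —
  but the concentration-scale RMSE genuinely requires the refits, because
  RMSE does not commute with the nonlinear back-transform.

Folds whose refit cannot honour the held-out site (a factor level present
only there, or a reduced fold with as many parameters as observations)
fall back to the reference profile or the intercept-only refit and are
flagged and counted, surfacing small-zone instability instead of failing.
`compare_scopes()` assembles the scope × model table and pools per-zone
scores through the identity
$\sqrt{\sum_k M_k\,rmse_k^2 / \sum_k M_k}$.

## What the synthetic generator emulates — and what it does not

`study_config()` + `generate_sites()` + `simulate_response()` +
`generate_grid()` reproduce the *statistical structure* the pipeline
assumes:

* 445 sites over four zones (allocation 220/147/49/29), five moss species
  with frequencies 227/186/27/4/1 and four tree-cover classes. Tree-cover
  frequencies are not published for the emulated design; the defaults
  (0.45/0.30/0.15/0.10) were fixed once as a plausible forest mix.
* Quantitative covariates are smooth latent Gaussian fields realised as
  random-Fourier-feature surrogates: deterministic functions of location
  given the seed, so sites and grid cells sample literally the same
  surface and a grid cell coincident with a site reproduces its covariates
  exactly. Buffer families are monotone transforms of one shared field
  plus small radius-specific jitter, which guarantees the high within-family
  Spearman correlations (target 0.8) the filter must detect. Zero-inflated
  classes (e.g. sea) zero out the lowest latent values per zone, giving
  spatially coherent zeros. Land-use members are mapped to percentages in
  $[0, 100]$, altitude and the modelled concentration covariates to
  positive scales; units are native and never standardised.
* Responses come from the CLL model itself with defaults
  $\alpha = 0.9$, $\sigma = 0.3$ and a handful of non-zero slopes
  ($Cd_{max} = 1.5$ µg/g), chosen so the simulated concentration
  distribution (median ≈ 0.13 µg/g, maxima well below the bound) looks
  like a realistic background-pollution campaign.

Not emulated: real French geometry and coastlines (zones are axis-aligned
rectangles — the simplest layout that exercises per-zone modelling and
mosaicking); real land-use maps; preferential sampling; measurement error
structure beyond the lognormal-like noise induced by the transform; and —
deliberately — any residual spatial correlation beyond what the covariate
fields induce, so on synthetic data the after-covariates Moran test should
accept at its nominal level. Passing tests therefore demonstrate the
machinery is correct under the stated model, not that real moss surveys
satisfy that model.

## Numerical choices and problem sizes

* All randomness flows from one master seed expanded into per-stage
  substreams, so stages are individually reproducible.
* Coordinates are planar metres in an abstract CRS; only distances are
  ever used, so no geodesy is needed.
* The strict inequalities in both filters, the worst-pair-first order and
  the mean-|ρ| tie-break in screening, average ranks for Spearman ties,
  and type-7 quantiles in `summarize_batch()` (configurable — thresholds
  recomputed from rounded published quartiles can differ in the last digit)
  are all fixed and documented so reruns are bit-identical.
* `run_study()` demonstrations use a 20 km grid (~2 000 cells) and
  `n_perm` a few hundred; a production 2 × 2 km national grid
  (~140 000 cells) uses the same code path via
  `generate_grid(cfg, 2000)`.
* Degenerate designs fail loudly: rank-deficient fits name their aliased
  columns, constant values are rejected by the Moran test, and
  under-sampled designs ($n < 2\times$ covariates, as in the smallest
  zone) carry an overfitting flag.

## Known limitations

The median-scale maps understate means; LOOCV with a fixed variable set is
mildly optimistic; extrapolation flags mark but do not correct
out-of-support prediction; the kriging baseline is ordinary (no external
drift or co-kriging), and no spatial random effect is added to the
regression — the residual-Moran diagnostic is the tool for judging when
such an extension would be needed.
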