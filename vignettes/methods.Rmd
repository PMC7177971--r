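---
title: "Methods: decay-weighted local use, spatial Durbin estimation, and the measurement-error bootstrap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decay-weighted local use, spatial Durbin estimation, and the measurement-error bootstrap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(localuse)
```

## The problem

Public pesticide-use reports record pounds of active ingredient geocoded to
one-mile survey sections; the census publishes demographic estimates, with
margins of error, for tracts and places. A distributional
environmental-justice analysis asks whether demographic composition predicts
how much pesticide is applied near where people live. `localuse` implements
that analysis as a chain of four models, each with explicit, testable
assumptions.

## The exposure surface

Use records are summed per section (`aggregate_sections()`), either as a
study-period total (the default, since the local-use sum is defined over
total use at a section) or as an annual mean. A geographic unit's
*distance-weighted local use* is

$$ q_i = \sum_u q_u\, 0.37^{\,d_{iu}/\mathrm{CTD}} $$

where the characteristic travel distance (CTD, km) is the distance at which
63% of a volatilized chemical's mass is degraded or deposited — hence the
base 0.37 — and $d_{iu}$ is the planar Euclidean distance in km from the
unit's population-weighted centroid to the section centroid. Whenever a
section centroid falls *inside* the unit polygon the weight is forced to 1,
a coarse acknowledgement that residents are not all located at the centroid.
The dependent variable is $\log_{10} q_i$, chosen because local use spans
many orders of magnitude and base 10 keeps the units interpretable (pound
orders of magnitude).

Assumptions worth stating plainly: decay is isotropic exponential in
distance — no wind, hydrology, or deposition chemistry — so $q_i$ is a
*potential exposure proxy*, not exposure. No cutoff radius is applied; every
section contributes to every unit (cost is O(units × sections)), with
weights below 1e-300 treated as exactly 0 to avoid denormal arithmetic.
Point-in-polygon uses an even-odd ray cast with an inclusive boundary
(tolerance 1e-9 km), so a centroid exactly on a shared border counts as
inside deterministically.

Tunables: `ctd_km` (default sweep 1, 10, 30, 60, 90 km — a
robustness-of-researcher-choices sweep, not a claim that any single value is
physically right; the 1 km surface is kept even though section-centroid
geocoding makes it unreliable, because reproducing that limitation is part
of the design); aggregation `mode` (`period_total` default).

## Census preparation

Derived proportions use the census-handbook propagation
$\mathrm{MOE}_p = \sqrt{\mathrm{MOE}_{num}^2 - p^2\,\mathrm{MOE}_{den}^2}/den$,
falling back to the ratio form (with a `+`) when the radicand is negative;
the fallback guarantees a real, nonnegative MOE. Units reporting zero
population or zero employment are excluded (their proportions and density
are undefined); the filter is idempotent and logs each exclusion. Reported
subgroup counts can exceed the reported population after survey noise;
they are clamped so proportions stay in $[0,1]$, with a warning. Density
is $\log_{10}$ of residents per km². County controls are count-aggregates
over the retained member units (sum of population over sum of area; sum of
agricultural workers over sum of employment) — what a county-level census
pull would return — rather than means of unit-level values. Tracts and
places are always analysed in parallel, never pooled: places cover most of
the population but little of the area, so the two classes trade coverage
against accuracy differently.

## Spatial weights

Weights are k-nearest-neighbor (default k = 3) on the population-weighted
centroids, row-standardized to 1/k, self excluded, with distance ties broken
by ascending unit identifier so runs are reproducible. kNN was chosen over
contiguity because place polygons are mutually disjoint — under contiguity
most places have no neighbors at all. The kNN relation is asymmetric and is
*not* symmetrized; everything downstream (log-determinant, feasible
interval) handles complex eigenvalues of W. Moran's I uses the standard
row-standardized form $I = (n/S_0)\,\tilde z^\top W \tilde z / \tilde
z^\top \tilde z$ and errors on constant input.

## Spatial Durbin estimation

The model is $y = \rho W y + X\beta + W X \theta + \varepsilon$. For a
candidate $\rho$, $y - \rho Wy$ is regressed on $Z = [1, X, WX]$, giving a
profile log-likelihood
$\ln|I - \rho W| - (n/2)\ln(\mathrm{RSS}(\rho)/n) + c$. Because
$\mathrm{RSS}(\rho)$ is an exact quadratic in $\rho$ (from the residuals of
$y$ and $Wy$ on $Z$), each profile evaluation is O(1) after one QR
decomposition. The log-determinant uses the eigenvalues of dense W,
computed once and cached — at study scale (≈ 400–1100 units per class) a
dense eigendecomposition is trivial, so no sparse-Cholesky machinery is
needed. The feasible interval for $\rho$ is $(1/\lambda_{\min}, 1)$ when the
spectrum is real, $(-1, 1)$ otherwise; optimization is golden-section
(`optimize`) on the interval shrunk by a relative margin of 1e-6, and a
solution within 10 margins of a boundary is an error rather than a silently
pinned estimate. Collinear $[X, WX]$ designs are rejected with the
offending columns named — this matters in practice because a covariate that
is constant within spatial clusters (e.g. a county-level control with few
counties) has a spatial lag nearly equal to itself.

The variance-covariance matrix over $(\beta, \theta, \rho)$ is the inverse
of the negated numeric Hessian (central differences, relative step 1e-5) of
the *full* log-likelihood, with $\sigma^2$ included in the differentiation
and marginalized by inversion. Two numerical details: the $\sigma^2$ step is
strictly relative (a fixed floor would step a small $\sigma^2$ negative),
and the Hessian is Jacobi-preconditioned before inversion because the
curvature scales of coefficients and $\sigma^2$ can differ by many orders of
magnitude when the fit is nearly exact.

Impacts: for covariate k, $S_k = (I-\rho W)^{-1}(I\beta_k + W\theta_k)$;
direct = mean diagonal, total = mean row sum, indirect = total − direct.
`impacts_dense()` computes this exactly and serves as the oracle.
`impacts_mc()` draws $(\beta, \theta, \rho)$ from the asymptotic normal
(rejecting and redrawing $\rho$ outside the feasible interval, at most 1000
attempts) and evaluates the direct impact by the truncated power series
with cached trace ratios $\mathrm{tr}(W^j)/n$, $j = 0..q$ (default q = 30);
the total uses the closed form $(\beta_k+\theta_k)/(1-\rho)$, exact for
row-standardized W. For row-standardized kNN weights the trace ratios decay
to $\approx 1/n$, so the q = 30 truncation error is far below 1e-3 relative
for $|\rho| \le 0.8$ — asserted against the dense oracle in the tests. A
non-positive-semidefinite vcov (possible from numeric differentiation) is
repaired by clipping negative eigenvalues, with a warning.

## Measurement-error bootstrap

Survey margins of error are treated as the standard deviation of a Gaussian
measurement-error model: each resample redraws every covariate value at its
fixed location from `Normal(estimate, moe_to_sd × MOE)` — resampling *at*
rather than *from* locations, so W, the outcome, centroids and county
controls never change. Defaults: 500 resamples × 100 impact draws = 50,000
pooled draws per cell, `moe_to_sd = 1` (the MOE itself as the sd; set
1/1.645 to read the MOE as a 90% half-width instead), clamping of resampled
proportions to $[0,1]$ on. The spatial lags $WX$ are recomputed from the
resampled covariates each time — they are part of the Durbin design, so this
is forced by the model definition even though it is easy to overlook.
Variables with no defined MOE (log density, county controls) are not
resampled unless the caller supplies MOEs. Per-resample fit failures are
skipped and counted; more than 10% failures aborts the cell. Everything is
reproducible bit-for-bit given the run seed, from which each resample and
draw stage derives its own substream seed.

The motivation is attenuation bias: classical measurement error shrinks the
naive slope by $\sigma_x^2/(\sigma_x^2+\sigma_e^2)$, so ignoring MOEs makes
disparities look smaller than they are. `attenuation_demo()` reproduces this
in the non-spatial limit and shows the bootstrap interval widening with the
error scale. Total impacts ζ are reported transformed as
$\zeta_{trans} = 10^{\zeta/10}$: the multiplicative change in local use per
10-percentage-point covariate increase (1.5 ⇒ +50%).

## What the synthetic generator does and does not emulate

`gen_landscape()` builds an abstract planar landscape in km: rectangular
tracts tiling a square extent, places as inner rectangles of a random half
of the cells (small, mutually separated population centers), block points
with Poisson-like populations, and section centroids on the 1.6 km lattice.
`gen_demographics()` draws latent logistic-normal proportions around
magnitudes typical of an agricultural valley (e.g. Hispanic ≈ 0.42,
poverty ≈ 0.22), with population density log-normal over roughly four
orders of magnitude, then reports them with Gaussian error of sd
`moe_scale` (default 0.03, a realistic tract-level MOE scale of a few
percentage points); the latent truth is retained for recovery tests.
`gen_outcome()` solves the spatial Durbin process exactly, so parameter
recovery, interval coverage and attenuation can all be tested against known
truth.

Deliberately *not* emulated: geodetic coordinates (all distances are planar,
as the decay model assumes), crop-specific or seasonal use patterns,
spatially clustered demographic segregation beyond what the smooth density
field induces, and non-Gaussian survey error. Passing tests therefore show
that the estimators and the bootstrap behave correctly under the model's own
assumptions — not that those assumptions hold for any particular real
landscape, where heteroscedasticity and residual spatial autocorrelation
(which the pipeline reports via per-fit residual Moran's I but does not
remedy) are to be expected.

## Problem sizes and study conditions used in the tests

The test suite exercises parameter recovery on 100 simulated datasets of
n = 400 units (ρ = 0.4, nominal-90% Wald coverage required to land in
[0.83, 0.97] for ρ, β and θ); bootstrap interval coverage on 50 replicates
of n = 200 units with 100 resamples × 20 draws each; the attenuation demo at
n = 10,000; impact-oracle agreement at n up to 200; and the full 10-cell
design on a 49-unit, 100 km landscape with a trimmed bootstrap. The 100 km
extent keeps the largest CTD (90 km) from flattening the exposure surface
into a near-constant — on a toy extent much smaller than the CTD every
weight approaches 1 and the regression degenerates, which is a genuine
property of the model, not an implementation artifact.

## Known limitations

* The exposure proxy inherits every limitation of section-centroid
  geocoding; the 1 km CTD surface in particular is noise-dominated.
* The SDM assumes homoskedastic Gaussian errors; the pipeline reports
  residual Moran's I per fit but offers no spatial-error or random-effects
  remedy.
* The measurement-error bootstrap propagates covariate uncertainty only; it
  is not a case-resampling bootstrap and does not capture sampling
  variability of the locations themselves.
* Dense eigendecomposition bounds practical problem size to a few thousand
  units per geography class.
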