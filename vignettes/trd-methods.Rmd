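---
title: "Methods: marginal modelling of tobacco retailer density disparities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: marginal modelling of tobacco retailer density disparities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trdcar)
```

## The problem

Tobacco retailer density (TRD, retailers per 1000 residents) varies
systematically across neighborhoods: divested tracts — high-poverty,
high-minority-prevalence, rural — tend to carry more retailers per
resident, and that disparity is itself changing over time as retailers
open, close, and local tobacco retailer licensing (TRL) policies appear.
`trdcar` treats the census tract as the unit of analysis, observed at two
timepoints (2017 and 2022), and asks three questions: does a disparity
exist in each year, did it decline *equitably* (faster for the divested
group), and how is TRD associated with tract characteristics once
spatial and temporal dependence are accounted for?

## Tract preparation rules

Dichotomization uses fixed a-priori cutoffs: high African American or
Hispanic prevalence at ≥15% of residents, high prevalence of children at
≥25% under age 18, and high poverty at strictly >15.4% below the poverty
level (the baseline statewide poverty rate; note the strict comparator —
a tract at exactly 15.4% is low poverty, while a tract at exactly 15%
African American is high prevalence). The same cutoffs apply in both
years so the groups are comparable over time. County NCHS urban–rural
levels map to urban (1), suburban (2–3), rural (4–6).

Tracts are excluded — in both years, to preserve the paired design — when
either year has zero population, population below 500 (a guard against
unstable rates in tiny denominators; exactly 500 is retained), or a
missing poverty percentage. One reason is logged per tract with priority
zero population > below minimum > missing poverty; the filter is
idempotent.

Licensing status is a geometric rule: a tract is covered when it is fully
contained in a licensing city or at least 50% (inclusive) of its area
intersects one. Area weighting was chosen over population weighting
because city boundaries are areal objects; the package computes the
overlap exactly for axis-aligned rectilinear geometry (the synthetic
geometry is always rectilinear) and by convex clipping otherwise.
Points-in-tract tallies resolve boundary points deterministically to the
lowest tract id so results are independent of input order.

## Descriptive layer

Group summaries report the median TRD per level and year; the median is
the midpoint of the two central order statistics for even counts (R's
default), fixed here because the convention affects printed percent
changes. Percent changes are carried unrounded and rounded only for
display; a zero base yields an undefined (NA) change rather than a
number. A *disparity* in a year means the divested level's median TRD
exceeds the reference's. An *equitable decline* means the divested
level's signed percent change is smaller (more negative) than the
reference's: comparing signed changes rather than magnitudes of decline
handles the mixed case (one group rising, the other falling) without a
special rule. The statewide percent change is a ratio of aggregate
totals (total retailers over total population per year), not a mean of
tract-level changes — the two differ substantially whenever small tracts
move more than large ones.

## The marginal model

For tract $i$ and year $t$, counts $Y_{it}$ are specified through three
components:

* **Mean**: $\mu_{it} = (\mathrm{pop}_{it}/1000)\,
  \exp(x_{it}^\top \beta_t)$. The offset
  $\log(\mathrm{pop}_{it}/1000)$ puts coefficients on the log
  TRD-per-1000 scale, so $e^{\beta}$ is a rate ratio between tract
  groups. Every covariate gets a separate coefficient per year (a full
  year interaction); the licensing indicator, when included, applies to
  the later year only because no local licensing existed at baseline.
* **Variance**: $\mu(1 + \alpha\mu)$, the quadratic negative-binomial
  form, with $\alpha \ge 0$ estimated by moments. It nests Poisson at
  $\alpha = 0$ and keeps the Pearson residual scale interpretable.
* **Working correlation**: separable,
  $R = R_{AR}(\phi) \otimes R_{CAR}(\gamma)$. The spatial factor is a
  proper CAR correlation: precision $Q = D - \gamma W$ on the rook/queen
  adjacency ($W$ binary, $D$ degree-diagonal), inverse rescaled to unit
  diagonal. This parameterization is positive definite for all
  $|\gamma| < 1$, has the analytic check that a single-edge pair has
  correlation exactly $\gamma$, and handles isolated tracts (unit
  variance, zero correlation). The temporal factor is AR(1); with two
  timepoints it reduces to a single cross-year correlation $\phi$, one
  5-year lag apart.

Coefficients have a population-averaged interpretation; no conditional
(random-effect) data-generating story is asserted.

### Fitting algorithm and numerical choices

1. Initialize $\beta$ by an independence Poisson IRLS fit.
2. Update $\alpha$ by the moment estimator
   $\hat\alpha = \max\{0, \sum[((y-\mu)^2 - \mu)/\mu^2]/(N - p)\}$.
3. Update $(\gamma, \phi)$ by maximizing the scale-profiled Gaussian
   pseudo-log-likelihood of the Pearson residuals,
   $-\tfrac12\{\log|R| + 2n\log(r^\top R^{-1} r)\}$, with L-BFGS-B on
   $[-0.99, 0.99]^2$, warm-started from the previous iterate.
4. Update $\beta$ by one Fisher-scoring step of the weighted estimating
   equation with $V = A^{1/2} R A^{1/2}$,
   $A = \mathrm{diag}(\mu(1+\alpha\mu))$.
5. Iterate 2–4 until the relative change in $\beta$ drops below
   $10^{-6}$ (at most 100 iterations; non-convergence returns the fit
   with `converged = FALSE` and a warning).

All linear algebra exploits structure: one symmetric eigendecomposition
of $D^{-1/2} W D^{-1/2}$ per graph gives $\log|Q|$, $\mathrm{diag}(Q^{-1})$
and sampling at any $\gamma$ in $O(n^2)$; the inverse *correlation* is
the sparse matrix $V_d^{1/2} Q V_d^{1/2}$, and the Kronecker structure
reduces every $R^{-1}v$ product to sparse operations on an $n \times 2$
reshape. At $\gamma = 0$ a fast path skips the spectral machinery
entirely, which also makes the degenerate Poisson check exact: with
$\gamma = \phi = \alpha = 0$ the scheme *is* Poisson IRLS and matches
`glm.fit` to near machine precision.

### Coefficient covariance

The whole state is a single correlated cluster, so the textbook
cluster-robust sandwich degenerates: its middle matrix is the outer
product of one cluster score, which is rank-1 and numerically zero at
convergence. The package therefore uses the moment-estimated structured
covariance $A^{1/2}\hat R A^{1/2}$ as the middle matrix, which collapses
the sandwich to $\hat\sigma^2 H^{-1}$ with $H = D^\top V^{-1} D$ and
$\hat\sigma^2$ the profiled Pearson scale (near 1 when the variance
model is right). `cov_type = "model"` drops the scale factor. The
recovery study below shows this covariance is well calibrated when the
working structure matches the generator; when it does not, standard
errors inherit the usual quasi-likelihood caveats.

### Inference and simplification

`wald_test()` computes $(C\beta)^\top (C \Sigma C^\top)^{-1} (C\beta)$
against $\chi^2_{\mathrm{rank}(C)}$; `wald_z()` audits printed
estimate/SE pairs. `simplify_model()` runs backward elimination over
candidate interactions only (main effects are never dropped): each
candidate is tested jointly across its two year columns (2 df), the
least significant non-significant candidate is removed (ties broken by
term name for determinism), and the model is refit until all retained
candidates pass at 0.05. `predict_groups()` returns
$\exp(x^\top \beta_t)$ per profile with delta-method intervals on the
log scale, and flags profiles whose between-year change
$x_{2022}^\top\beta_{2022} - x_{2017}^\top\beta_{2017}$ is significant
under the joint covariance.

## The synthetic-state generator

The generator emulates the statistical structure the model assumes, at
the scale of the motivating study frame (~3149 tracts, median tract
population 3535):

* **Graph**: a rook-contiguity lattice (57×56 by default, truncated
  row-major to the requested tract count) standing in for a tract
  adjacency graph.
* **Covariates**: each flag thresholds a one-pass graph-smoothed
  Gaussian field (average of self and neighbors) at its target
  quantile, so flags are spatially clustered and empirical prevalences
  match the targets to rounding. Default targets: 26.7% high African
  American, 4.1% high Hispanic, 31.7% high children, 42.9% high
  poverty; 31.0/45.1/23.9% urban/suburban/rural. The smoothing strength
  is fixed (not a knob) to keep the prevalence calibration exact.
  Percentages consistent with each flag are synthesized so the
  classification rules can be audited on generator output.
* **Populations**: log-normal with median 3535 and log-sd 0.45 — only
  the median is anchored to the study frame; the spread is a realistic
  choice for tract populations. The same draw serves both years.
* **Licensing**: 13 contiguous patches grown by seeded breadth-first
  search from urban/suburban tracts (licensing localities are urban or
  suburban; rural tracts are never covered) until 13.7% of tracts are
  flagged, in the later year only. Unreachable coverage produces a
  warning and the achieved fraction.
* **Counts**: a Gaussian copula. A latent normal vector with
  correlation $R_{AR}(\phi) \otimes R_{CAR}(\gamma)$ is pushed through
  the standard normal CDF and inverted through the NB quantile with the
  model's own $\mu_{it}$ and $\alpha$ (Poisson quantile when
  $\alpha \le 10^{-10}$, preserving continuity in $\alpha$). The copula
  imposes exactly the marginal mean/variance plus a separable latent
  correlation without asserting a conditional generative story, and it
  is invertible, which makes the generator directly testable against
  its own specification. Default true coefficients are the fitted
  two-year values of the motivating analysis; defaults
  $\gamma = 0.3$, $\phi = 0.4$, $\alpha = 0.3$.

What the generator does **not** emulate: real street geography or
retailer point processes, tract-boundary changes between census
vintages, covariate drift between years, and count-scale correlation
exactly equal to the latent correlation (quantile transforms attenuate
it — fitted $\hat\gamma, \hat\phi$ are working parameters, expected to
sit below the latent values). Passing tests therefore demonstrate
internal consistency and estimator calibration under the assumed
structure, not agreement with any real state's retailer data.

## Verification strategy and problem sizes

The test suite checks closed forms (CAR pair/path correlations by direct
dense inversion, the intercept-only score solution
$\beta_0 = \log(\sum y / \sum \mathrm{pop}/1000)$), degenerate
equivalences (independence Poisson vs `glm.fit` at $10^{-8}$),
moment recovery at $n = 10^4$ tract-years, Moran's-I monotonicity of
residual autocorrelation in $\gamma$ (20-replicate means on a 20×20
lattice), and a 100-replicate parameter-recovery study on a 30×30
lattice at the default generating values — per-coefficient mean bias
under 0.03 and 95%-interval coverage within [90%, 98%]. These sizes give
stable Monte-Carlo error while keeping a full run around two minutes on
one CPU; the spectral setup of the lattice is shared across replicates.

## Known limitations

* Two timepoints are exercised throughout; the AR machinery is written
  generally but untested beyond lag one.
* The CAR form, estimation scheme, and covariance are the package's own
  choices for a marginal spatiotemporal NB model; other proper-CAR
  parameterizations or GEE software will give numerically different
  working-correlation estimates on the same data.
* Standard errors assume the structured-covariance collapse described
  above; with a single cluster there is no empirical robustness to
  correlation misspecification.
* The geometry backend covers rectilinear and convex polygons only —
  sufficient for the synthetic geometry and simple city tracings, not
  for arbitrary multipolygon shapefiles.
* Dichotomized covariates discard within-group gradients; the model
  measures group contrasts, not dose–response.
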