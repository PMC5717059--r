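---
title: "Standardizing capture-recapture densities: models, corrections, and projections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standardizing capture-recapture densities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tigertrend)
```

## The problem

Camera-trap surveys of individually identifiable carnivores have been
analyzed with two generations of methods. Older studies used non-spatial
capture-recapture (CR): estimate the abundance $\hat N$ of animals exposed
to the trap grid with a closed-population model, then divide by an
"effective area sampled" $\hat A$ — the minimum convex polygon (MCP)
around the cameras plus a buffer, traditionally half the mean maximum
distance moved between recaptures (1/2 MMDM). Because small grids truncate
observed movements, 1/2 MMDM underestimates how far sampled animals range,
$\hat A$ is too small, and $\hat D = \hat N / \hat A$ is inflated — often
by tens of percent. Newer spatial capture-recapture (SCR) models estimate
density directly from the spatial pattern of detections and avoid the
buffer entirely.

This package implements a full pipeline for putting both generations on a
common footing: (i) a spatially explicit survey simulator, (ii) the M0
closed-population estimator and MCP/buffer geometry, (iii) a
maximum-likelihood SCR model, (iv) the buffer-standardization correction,
(v) a weighted mixed-model meta-regression of log standardized densities,
and (vi) projection of habitat-specific densities onto landscape
forest-area tables.

## Models

### Detection and the SCR likelihood

Detection follows the half-normal kernel
$p(d) = g_0 \exp(-d^2 / 2\sigma^2)$, where $g_0$ is the per-occasion
detection probability at distance zero and $\sigma$ (km) is the movement
scale. Detectors are binary proximity detectors: each animal x detector x
occasion is an independent Bernoulli trial, so several animals can be
recorded at one camera on one occasion, and no behavioural response is
modeled (single camera stations give no handling event to respond to).

The SCR likelihood is the full (unconditional) Poisson-$n$ form. Activity
centers form a Poisson process with intensity $D(s)$ over a discretized
habitat mask; for a center at cell $s$ the probability of the observed
trap-level binomial counts is $P(\omega_i \mid s)$, and the probability of
being detected at all is $p_\cdot(s) = 1 - \prod_j (1 - p_j(s))^K$. With
$\Lambda = \sum_s D(s)\, p_\cdot(s)\, a$ (cell area $a$), the
log-likelihood is

$$\ell = -\Lambda + \sum_{i=1}^n \log \sum_s D(s) P(\omega_i \mid s)\, a
  \;-\; \log n! \;+\; \text{const.}$$

The conditional-likelihood-plus-Horvitz-Thompson route is a standard
alternative; the unconditional form was chosen because it yields density
SEs through one canonical information matrix rather than a two-stage
variance composition. Parameters are maximized on the working scale
($\log D$, $\mathrm{logit}\, g_0$, $\log \sigma$) by Nelder-Mead polishing
into BFGS; SEs come from the numerically differentiated observed
information and the delta method. Multi-session data share whichever of
$D, g_0, \sigma$ the caller lists — duplicating a session with all
parameters shared exactly doubles the log-likelihood and therefore leaves
the maximizer unchanged, which is the device used when left- and
right-flank photo sets of the same survey must be entered as separate
sessions.

Masks default to 0.5 km cells extending 4 sigma beyond the trap hull.
Halving the cell size moves the log-likelihood by less than $10^{-2}$ on
the test fixtures; the Monte-Carlo experiments below use 1.0 km cells,
which is still well under $\sigma/2$ at the simulated $\sigma = 2.5$ km
and four times faster. Cells labeled `"excluded"` (open water, say) carry
zero density and drop out of every sum exactly; other stratum labels give
stratified densities (e.g. forest vs non-forest).

### Two quantile constants, deliberately distinct

Both constants are exposed explicitly because they answer different
questions. The **standardization buffer** is $1.96\sigma$ — the 95th
percentile of the *one-dimensional* half-normal movement kernel
(`standard_buffer()`). The **home-range radius** is $2.45\sigma \approx
\sqrt{\chi^2_{2,0.95}}\,\sigma$ — the 95% radius of a *circular bivariate*
normal (`home_range_area()`). At $\sigma = 4.59$ km these give a 9.0 km
buffer and a 397 km^2 home range. Neither is ever silently substituted
for the other.

### The correction

`correct_cr_density()` keeps a CR study's published $\hat N$ and
$SE(\hat N)$ but replaces its buffer: $\hat A^*$ is the trap-hull dilation
at the standard buffer and $\hat D^* = \hat N / \hat A^*$,
$SE(\hat D^*) = SE(\hat N)/\hat A^*$, so the relative SE is preserved
exactly. For a convex hull with area $A$ and perimeter $P$ the dilated
area is exact: $A + Pb + \pi b^2$ (Steiner formula); degenerate collinear
grids are covered by the same formula with $A = 0$ and $P$ twice the
segment length. When only summary geometry is published, records carry
`mcp_area_km2` and `mcp_perimeter_km` instead of coordinates — the common
case for compiled datasets. Clipping $\hat A^*$ to a land polygon is
available but off by default (computed by grid integration at
`buffer/50` resolution); published corrected areas are typically
unclipped, and the convex closed form is exact. Hull outlines are always
convex; concave outlines for irregular grids would need the original
coordinates, which compiled tables do not provide.

### Meta-regression

Standardized densities are compared on the log scale. Because the number
of distinct individuals saturates, $\hat N$ (and so $\hat D$) is
approximately log-normal, and the relative SE
$s_i = SE(\hat D_i)/\hat D_i$ is the sampling SE of $y_i = \log \hat
D_i$. The default variance model is the *scaled-weights* convention used
by lmer-style weighted mixed models:

$$\mathrm{Var}(y_i) = \sigma^2_\varepsilon s_i^2 + \tau^2, \qquad
  \mathrm{Cov}(y_i, y_{i'}) = \tau^2 \text{ for records in the same
  landscape},$$

i.e. known weights $1/s_i^2$ scale a common estimated residual variance,
plus a landscape random intercept against spatial pseudo-replication. The
classical meta-analytic convention with *fixed* known variances
($\mathrm{Var} = s_i^2 + \tau^2$) is available via `variance = "fixed"`;
both conventions are exercised in the test suite against independent
implementations (`lme4` and `metafor` respectively). $\beta$ is profiled
out by GLS inside a one- or two-parameter variance optimization; the
$\tau^2 = 0$ boundary is checked explicitly and flagged.

Model choice uses ML likelihood-ratio tests and AICc, with $k$ counting
fixed effects *plus* variance parameters (so AICc deltas are
interpretable across both variance conventions); fit is summarized by
marginal $R^2$ = fixed-effect variance over fixed + $\tau^2$ + mean
residual sampling variance. Wald $z$ statistics are reported; at a few
dozen records these are mildly anti-conservative, which is the usual
caveat for meta-regressions of this size. Covariate encodings: forest
type baseline `lowland-hill`, disturbance baseline `primary`, calendar
year centered at 1996 (the first year in the compiled record). Effects
are reported multiplicatively via
`effect_percent()`: $(\exp\beta - 1) \times 100$, with a `rebase` helper
for quoting the contrast from the other side.

### Projection

`habitat_densities()` composes class densities multiplicatively from a
primary lowland/hill baseline: peat and montane classes get one
multiplier, degraded classes another, and degraded peat gets both — the
interaction is taken as multiplicative because the fitted model is
additive on the log scale and no interaction term is estimable from the
compiled data. `project_population()` prices a long-format
landscape x class area table: adults $= \sum_c \text{area}_c d_c / 100$,
per-landscape SE = relative SE x adults (SEs add linearly across
landscapes, reflecting the fully dependent shared-density errors),
breeding females = round-half-up(adults / 2.9). The secure-source-
population rule is the strict conjunction bf > 25, core forest >
1000 km^2, and nearby forests holding >= 25 bf; "nearby" is a
user-supplied adjacency judgement, not computed from geometry.

The packaged landscape tables transcribe the published 15-landscape
forest-cover and population tables. Two landscapes' per-class cells are
typographically ambiguous in the source and are stored as `NA` with
`ambiguous = TRUE`; they are excluded from class-level arithmetic (their
landscape totals and loss percentages are unambiguous and retained).
The habitat-specific densities behind the published projections were
never printed; `derive_baseline_density()` recovers the baseline by least
squares of printed adults on class-weighted areas over the 13 unambiguous
landscapes, giving $\approx 1.12$ animals / 100 km^2. With the published
multipliers (0.501 peat/montane, 0.681 degraded) this reproduces every
unambiguous landscape's printed adult count to within the source's own
rounding (12 of 13 exactly; one sits on a .5 boundary).

## The simulator, and what passing tests do and do not show

`simulate_population()` draws activity centers from a homogeneous Poisson
process on a rectangular state space; `simulate_captures()` applies the
half-normal Bernoulli detection model. One master seed derives a labeled
sub-seed per stage (`derive_seed()`), so each stage and replicate is
independently reproducible. The state space must extend at least
4 sigma beyond the trap hull or a warning is raised.

The bias experiment (`run_bias_experiment()`) uses an 8 x 8 grid at
1.5 km spacing, K = 90 occasions, $g_0 = 0.05$, $\sigma = 2.5$ km, and a
true density of 2 / 100 km^2 — a survey of the size and sparseness
typical of large-carnivore camera-trap studies, at a problem size (100
replicates, 1 km mask cells) that runs in a couple of minutes on one
core. Under these conditions the half-MMDM density is strongly positively
biased, the 1.96 sigma-hat correction shrinks the magnitude of that bias
several-fold (a residual positive bias remains — the correction borrows
an estimated buffer, it is not an SCR refit), and SCR itself is within a
few percent of truth with near-nominal 95% CI coverage.

The meta-simulator (`simulate_meta_dataset()`) generates 60 landscapes
with 1-3 estimates each, baseline $\log(1.12)$, effects
$\log 0.501$, $\log 0.681$, and $0.048$/yr (the values the real analysis
reports, used here as recoverable truth), landscape SD $\tau = 0.15$, and
relative SEs uniform on (0.3, 0.9) — bracketing the 0.47-0.88 relative
SEs of the real survey estimates. $\tau$ and the SE range are fixed
modeling choices, not fitted quantities; the paper-scale analysis offers
no direct estimate of between-landscape SD, so a moderate value was
chosen once.

What the simulations do *not* emulate: heterogeneous detection (sex,
behavior, trap placement on trails), animal movement within occasions,
misidentification, non-rectangular state spaces, real land-cover rasters,
or publication bias in which landscapes get surveyed. Passing tests
therefore show that the estimators are correct *under their own model*,
and that the correction removes the bias *generated by the buffer
mechanism* — they cannot certify the corrected historical estimates
themselves, whose raw data remain unavailable.

## Numerical choices

- M0 abundance: continuous-N MLE with $p$ profiled; $N \ge M_{t+1}$
  enforced; the $N = M_{t+1}$ boundary (high capture probability) and the
  $p = 1$ boundary are detected and reported with zero variance rather
  than a failed Hessian. SEs otherwise from the observed information in
  $(N, \mathrm{logit}\,p)$.
- SCR optimizer: relative tolerance $10^{-10}$, Nelder-Mead then BFGS;
  numerical Hessian via central differences (`pracma::hessian`); a
  singular information matrix returns the fit with SEs flagged
  unavailable rather than an error.
- Meta-regression: Cholesky-based GLS; three optimizer starts spanning
  the weighted-residual variance scale; explicit $\tau^2 = 0$ profile
  comparison for the boundary flag.
- Rounding of published-table quantities uses round-half-up
  (`round_half_up()`), matching how the source tables round; base R's
  banker's rounding would disagree on exact .5 cells.
- Degenerate inputs: empty capture histories are rejected by the
  validator; zero-capture simulator replicates are flagged and excluded
  from bias summaries with their count reported; collinear trap grids
  dilate as segments.

## Known limitations

- Only the M0 closed-population model is implemented; the heterogeneous
  models some original studies used cannot be reconstructed without their
  raw data, and the correction deliberately reuses published $\hat N$.
- No Bayesian SCR variant, no sex- or site-specific movement parameters,
  no trend surfaces beyond two-stratum density.
- Planar km coordinates throughout; longitude/latitude input is out of
  scope.
- The published effective areas of the three new surveys cannot be
  recomputed here because the camera coordinates are unpublished.
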