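---
title: "Graph-Laplacian penalized estimation of small-area effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-Laplacian penalized estimation of small-area effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arealrank)
```

## The model and its assumptions

`arealrank` models an individual-level bounded outcome score (0–100) as

$$y_{si} = \mathbf{x}_{si}^\top \boldsymbol\beta + \alpha_s + \epsilon_{si},
\qquad \epsilon_{si} \sim N(0, \sigma^2),$$

with dummy-coded categorical covariates $\mathbf{x}_{si}$ and a per-region
intercept $\alpha_s$. Three assumptions matter:

1. **Linearity on the score scale.** The outcome is bounded but modeled
   linearly with Gaussian errors. This is adequate away from the bounds;
   heavily skewed scores near 0 or 100 would call for a bounded-response
   model, which is outside this package's scope.
2. **Spatial smoothness of the region effects.** Regions whose population
   centroids are close in travel time are assumed to have similar effects.
   This is encoded, not estimated: it enters through the penalty below.
3. **Covariate effects common across regions.** $\boldsymbol\beta$ is
   shared; only the intercept varies spatially.

The design deliberately carries **no intercept column**: the region term
$Z\boldsymbol\alpha$ spans the intercept, and including both would make the
system rank-deficient. The overall level $\alpha_0$ is recovered afterwards
as the unweighted mean of the estimable $\hat\alpha_s$, so that the
deviations $\tilde\alpha_s = \hat\alpha_s - \alpha_0$ satisfy the reported
sum-to-zero constraint exactly over the regions. (An observation-weighted
mean — "the average across all observations" — is available as an option,
but it does not satisfy the region-level sum-to-zero constraint unless the
design is balanced, so the region mean is the default.)

## The neighborhood graph and penalty

Two regions are neighbors when the symmetrized travel time between their
centroids is at most a threshold $\tau$ (default 30 minutes, a typical
one-way commute or care-seeking drive). Within the ball the default edge
weight is a truncated Gaussian,

$$A_{ss'} = \exp\!\left(-\frac{t_{ss'}^2}{2h^2}\right) \cdot
\mathbf{1}\{t_{ss'} \le \tau\},$$

so influence decays with travel time; a binary 0/1 kernel is available as
the unweighted alternative. The bandwidth default $h = \tau/2$ puts weight
$e^{-2} \approx 0.135$ at the cutoff — close neighbors dominate, but
threshold-edge neighbors still contribute. Raw kernel weights are used
without row normalization. Self-loops are forbidden, drive-time asymmetry
is resolved by averaging the two directions before graph construction
(Laplacian theory requires symmetry, and direction differences in drive
times are small relative to $\tau$), and a missing travel time means "no
route", i.e. not neighbors. With degree $D$ and Laplacian $L = D - A$, the
estimator minimizes

$$\lVert \mathbf{y} - X\boldsymbol\beta - Z\boldsymbol\alpha \rVert^2 +
\lambda\,\boldsymbol\alpha^\top (L + \gamma I)\,\boldsymbol\alpha,$$

and the Laplacian quadratic form equals
$\tfrac12 \sum_{s,s'} A_{ss'} (\alpha_s - \alpha_{s'})^2$ — a weighted
squared-difference penalty between neighbors. (With double-counted
neighbor pairs this absorbs a factor of 2 into $\lambda$; since $\lambda$
is tuned by cross-validation the convention is immaterial, and the
half-sum identity above is asserted in the tests.) The closed form

$$(\hat{\boldsymbol\beta}, \hat{\boldsymbol\alpha}) =
(\tilde X^\top \tilde X + M)^{-1} \tilde X^\top \mathbf{y},
\qquad \tilde X = [X\ Z],\quad
M = \mathrm{blockdiag}(0,\ \lambda L + \lambda \gamma I),$$

is computed by Cholesky factorization of the augmented normal matrix —
never an explicit inverse. At the default problem sizes (tens to hundreds
of regions) dense factorization is fast and exact; sparse methods would
only matter at national scale.

## Empty regions and estimability

A region with no respondents but with observed neighbors gets its estimate
entirely from the penalty; its stationarity condition is the harmonic
identity

$$\hat\alpha_s = \frac{\sum_{s'} A_{ss'} \hat\alpha_{s'}}{D_{ss} + \gamma},$$

a degree-plus-ridge weighted average of its neighbors. This is why the
effect spread among empty regions is never larger than among observed ones:
averages contract. Two situations defeat estimation: a region with no
respondents and no neighbors, and a region whose entire connected component
is unobserved. Such regions are excised from $Z$ and $L$ before solving and
reported `NA` — a pure-ridge solve would return 0, which would be an
arbitrary number, not an estimate. When smoothing ($\lambda > 0$) is
requested with empty-but-smoothable regions present, $\gamma > 0$ is
required: $L$ is singular by construction and the pure-Laplacian system is
then numerically fragile even when technically solvable.

## Tuning, degrees of freedom, inference

$(\lambda, \gamma)$ are selected by $k$-fold cross-validation (default
$k = 5$) over log-spaced grids ($\lambda \in 10^{-2..4}$,
$\gamma \in 10^{-4..1}$) minimizing out-of-fold RMSE, the sole criterion.
Folds split individuals, stratified by region when a region has at least
$k$ records, so every fold keeps data in the well-sampled regions. Ties
break deterministically toward smaller $\lambda$, then smaller $\gamma$ —
preferring less smoothing when it costs nothing. A grid pair that produces
a singular training system in any fold is marked failed and excluded.

The effective degrees of freedom are the trace of the hat matrix
$\tilde X (\tilde X^\top \tilde X + M)^{-1} \tilde X^\top$, the standard
choice for ridge-type smoothers; they interpolate between $p$ (infinite
penalty) and $p + S$ (no penalty) and feed
$\hat\sigma^2 = \mathrm{RSS}/(n - \mathrm{edf})$ and the adjusted $R^2$.
Coefficient intervals use the sandwich covariance
$\hat\sigma^2 (\tilde X^\top\tilde X + M)^{-1} \tilde X^\top\tilde X
(\tilde X^\top\tilde X + M)^{-1}$ with normal quantiles. These are
approximate: they account for the penalization of $\boldsymbol\alpha$ but
ignore smoothing bias, and they collapse to the classical OLS covariance at
$\lambda = 0$ (asserted in the tests).

## Reporting conventions

Rankings sort the sum-to-zero deviations $\tilde\alpha_s$ descending (rank
1 = best region; ranking by $\hat\alpha_s$ is identical since the two
differ by a constant), with lexicographic region-id tie-breaks so repeated
runs and permuted inputs give byte-identical tables. Quintile bins are
rank-based with near-equal sizes; when $S$ is not divisible by 5 the larger
bins are allocated from the top. For display, effects are winsorized at
mean $\pm 3$ sd of the estimable effects (population-sd denominator,
computed before clipping); the clip bounds travel with the winsorized
vector so the transform is exactly idempotent, and the underlying estimates
are never altered.

## What the synthetic generator emulates

Because individual-level well-being data of this kind are restricted, the
package ships a first-class generator with embedded truth:

- **Geography.** A square grid of region centroids (default $S = 64$,
  18-mile rural spacing) with a compact urban corner block at 6-mile
  spacing. Driving speed is 24 mph in urban regions and 60 mph in rural
  ones; travel time is great-circle distance over the mean speed of the
  pair. A 30-minute drive therefore covers fewer miles in the urban block
  while urban centroids sit closer together — reproducing the
  density-dependent neighbor asymmetry of real drive-time graphs (urban
  regions: more neighbors per square mile). One isolated region is
  appended far from the grid (non-estimable by construction) and one
  interior region is deterministically emptied of respondents (empty but
  smoothable), so both degenerate cases are always present.
- **Effects.** $\tilde{\boldsymbol\alpha}_{\mathrm{true}}$ is one draw
  from the Gaussian Markov random field with covariance
  $\kappa (L + \gamma_0 I)^{-1}$, centered to sum to zero — the conjugate
  prior under which the penalized estimator is the posterior mode, which
  makes recovery experiments well-specified. Defaults $\kappa = 50$,
  $\gamma_0 = 0.5$ give a true-effect sd of about 5 score units, matching
  region-effect spreads of roughly $\pm 20$ on a 0–100 scale.
- **Individuals.** Per-region counts are zero-inflated Poisson (default
  10% structurally empty, mean 30 otherwise — small-area sample sizes).
  Covariate levels are drawn independently per variable from configured
  marginal frequencies. The default scenario uses a compact two-variable
  design — gender (64.2% female) and urban/rural residence (83.2% urban),
  with true effects $-0.8$ and $+17.5$ score units — chosen so that
  coefficient standard errors at $n \approx 1900$, $\sigma = 10$ are about
  0.5 units and recovery experiments are informative about estimator
  correctness rather than dominated by sampling noise in rare cells. The
  full seven-variable nationwide demographic profile (including levels
  with 1–2% frequency) is available via `demographic_profile()` for
  emulation studies; with such rare reference cells, per-coefficient
  errors of 2+ units are expected at these sample sizes and recovery must
  be judged per cell size.
- **Outcomes.** $y = \alpha_0 + \mathbf{x}^\top\boldsymbol\beta_{\mathrm{true}}
  + \tilde\alpha_{\mathrm{true},s} + N(0, \sigma^2)$ with $\alpha_0 = 60$
  and $\sigma = 10$. Clipping to $[0, 100]$ exists but is off by default,
  because clipping biases linear recovery; the default level and scale keep
  essentially all scores inside the bounds anyway.

What passing tests on these data do **not** show: robustness to covariates
that are correlated with each other or with the region (the generator draws
them independently), to outcome distributions that pile up at the bounds,
to informative sampling (who responds is independent of everything here),
or to misspecified smoothness (real effects need not follow the GMRF
prior — a piecewise "patchy" robustness scenario can be built by passing a
custom effect vector to `simulate_individuals()`).

## Numerical choices and degenerate inputs

- Travel-time threshold comparisons are inclusive ($t \le \tau$).
- Haversine distances use the mean Earth radius (3958.756 miles), so one
  degree of longitude at the equator is 69.09 miles.
- The augmented normal matrix is solved via `chol()`; a factorization
  failure surfaces as an actionable error naming the usual causes
  ($\lambda = 0$ with an empty region; $\gamma = 0$ with smoothing).
- Region ids are opaque strings everywhere (ZCTA codes keep leading
  zeros); numeric coercion is never applied.
- Recovery experiments in the tests run at $S = 64$–$100$ regions and
  $n \approx 1800$–$2500$ individuals with 5-fold CV over a $7 \times 6$
  grid — sizes at which the whole suite completes in seconds while leaving
  the estimator's behavior (smoothing benefit, empty-region identities,
  limit cases) clearly visible.

## Known limitations

- Inference on $\boldsymbol\beta$ is approximate (see above); intervals
  for $\hat\alpha_s$ are not reported because smoothing bias dominates in
  sparsely observed regions.
- The adjusted $R^2$ of demographic-plus-region models on individual
  scores is genuinely low; most individual variance is idiosyncratic. The
  model's value is in the region-level estimates, not individual
  prediction.
- Effects for regions with one or two respondents can be extreme; the
  display winsorization exists precisely because such estimates are
  legitimate but visually dominating.
- Dense linear algebra bounds practical problem sizes to a few thousand
  regions.
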