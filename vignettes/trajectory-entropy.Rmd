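---
title: "Measuring trajectory unpredictability with maximum-entropy densities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring trajectory unpredictability with maximum-entropy densities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajentropy)
```

## The problem

A prey animal that moves unpredictably is hard to intercept. Classical
biomechanical summaries — mean speed, turning-angle variance — do not measure
unpredictability: a sinusoidal weave with doubled amplitude has four times
the lateral variance but is exactly as predictable as the original. The
information-theoretic notion of entropy does measure it. trajentropy
estimates the *differential entropy* of an animal's per-frame 3-D
displacement distribution from tracked field trajectories, and provides the
statistical machinery to compare that entropy between species or
conditions.

## The model

Let $d_1,\dots,d_N$ be per-frame displacement vectors, normalized so every
component lies in $[-1,1]$ (the cube bounds represent the largest
single-frame movement along any axis). We model them as draws from a
continuous density $f$ on the cube and summarize unpredictability as

$$H[f] = -\int_{[-1,1]^3} f(x)\,\ln f(x)\,dx \quad \text{(nats)}.$$

A finite sample does not determine $f$; it determines sample moments
$\hat m_\alpha = N^{-1}\sum_i d_i^\alpha$ for monomial multi-indices
$\alpha$ with $|\alpha| \le 2k$. Among all densities matching those
moments, we follow the principle of maximum entropy and pick the one
maximizing $H[f]$ — the least-assuming density consistent with the data.
The maximizer is an exponential family
$f(x) = \exp\big(\sum_{\alpha\neq 0}\lambda_\alpha x^\alpha - \psi\big)$,
and the coefficients solve the strictly convex dual problem

$$\min_\lambda\; \ln \int_{[-1,1]^3}
   e^{\sum_\alpha \lambda_\alpha x^\alpha}\,dx
   \;-\; \sum_\alpha \lambda_\alpha \hat m_\alpha ,$$

whose gradient is the vector of model-minus-empirical moments and whose
Hessian is the (positive definite) covariance of the constraint monomials
under the current density. `fit_maxent_density()` runs a damped Newton
iteration from $\lambda = 0$ (the uniform density) with Armijo
backtracking; every integral is a tensor Gauss–Legendre rule, so a fit is
deterministic and bit-for-bit reproducible at a fixed node count. The
uniform density attains the maximum possible value $H = \ln 8 \approx
2.079$; strongly concentrated displacement clouds go far negative.

## Parameters that matter

* **Moment order `k`** (default 2, maximum 4): constraints through total
  order $2k$. Order 2 captures anisotropy, skew and kurtosis of the
  displacement cloud while keeping 34 free coefficients; order 3 and 4 are
  available but rarely change the ranking of datasets and cost rapidly
  more. Entropy is non-increasing in `k` (more constraints can only lower
  the maximum), so compare datasets only at a fixed order.
* **Quadrature nodes** (default 24 per axis, i.e. 13,824 points):
  integrates the constraint monomials essentially exactly and resolves
  densities whose narrowest feature is wider than roughly the central node
  spacing ($\approx 0.13$ for 24 nodes). Concentrated data — a dataset
  whose per-frame steps are tiny relative to the shared normalization
  scale — may need 32–48 nodes; the convergence flag and the
  dual/quadrature entropy cross-check (agreement demanded to 1e-8, scaled
  by the dynamic range of the log-density) both guard against
  under-resolution. Fits at two node counts should agree; halving/doubling
  the count is the built-in convergence check.
* **Convergence tolerance** (default 1e-6 on the maximum moment
  residual): a fit is only reported `converged` when every model moment
  matches its empirical value this closely. Moment vectors on the boundary
  of the moment cone (for example a coordinate with exactly zero sample
  variance) admit no continuous density; the solver detects the stalling
  residual with diverging coefficients and raises a "moments infeasible"
  error rather than returning a silently wrong fit.

## Normalization conventions

Differential entropy is not scale-free: rescaling displacements by $s$
shifts $H$ by $-3\ln s$. The package therefore makes the convention
explicit:

* **Shared (pooled) scale** — the default for comparisons.
  `shared_scale()` pools the maximum absolute displacement component over
  all datasets in a comparison and every dataset is divided by that one
  number, putting all entropies on a common support.
  `modified_entropy_test()` refuses datasets whose recorded scales differ.
* **Per-trajectory, per-axis scale** (`normalize_to_cube(per_axis =
  TRUE)`) — divides each axis by its own maximum. This makes the result
  invariant to independent linear rescalings of the axes, so geometrically
  similar paths (a weave and the same weave at twice the amplitude) have
  equal entropy: the "shape, not size" reading of unpredictability. A
  scalar per-trajectory normalization cannot deliver that property when
  only one axis is scaled — the other axes shrink relative to the shared
  scalar and the entropy shifts by the corresponding log-ratio — which is
  why the per-axis convention is the one the package uses for
  pattern-equality checks.

## Segmentation, trimming, and degenerate inputs

Tracking dropouts split a recording into continuous segments; segments
shorter than 20 frames (configurable) are discarded and displacements are
never taken across a gap, and missing coordinates are dropped rather than
interpolated (interpolation would fabricate displacement structure). To
bound the influence of tracking glitches, `trim_outliers()` keeps the most
similar 97% of displacement vectors, ranked by Mahalanobis distance from
their sample mean — a scale-invariant notion of "similar" that treats
speed and direction jointly; the retained count uses the ceiling, so 97%
of 1000 is exactly 970. When the sample covariance is singular the
distance falls back to a per-axis standardized Euclidean distance with a
warning. Note that re-trimming already-trimmed data removes a further 3%
by construction — trimming is a one-shot preprocessing step, not a fixed
point.

## Marginals

The fitted 3-D density is visualized through two projections, both
computed from the fitted density rather than raw histograms: the
distribution of speed $r = \lVert x\rVert$ (spherical-shell quadrature
over directions, clipped to the cube) and the distribution of movement
direction on the unit sphere (radial quadrature along each direction
pixel, on an antipodally symmetric Gauss–Legendre latitude grid with
exact area weights). One geometric caveat: on a cube support the direction
marginal of even a perfectly uniform density is corner-weighted
($\propto R(u)^3$ where $R(u)$ is the distance to the cube boundary), so
isotropy on the sphere is only expected for densities concentrated inside
the inscribed ball. Axis convention: +y is the forward direction, +z
vertical.

## The resampling test

To ask whether two datasets differ in entropy, the observed entropies are
compared against a null in which both are draws from one mixed repertoire:
the pooled displacements are resampled without replacement into
pseudo-samples of the original sizes, each refitted (warm-started from the
previous solution) and its entropy recorded. Each observed entropy is
ranked two-sidedly by distance from its null mean — either inflated or
deflated entropy is evidence of dataset-specific structure. P-values are
floored at $1/(n_\text{resamples}+1)$ and flagged as bounds rather than
reported as zero. Frames are autocorrelated within a trial, so a
block-resampling option that resamples whole tracking segments is
provided and recommended when segments are long relative to the
correlation time; the frame-level default matches the exchangeability
assumption of the calibration checks in the test suite.

## The synthetic generators

No public tracking data accompany the method, so the package ships
generators that emulate the statistical structure of field trajectories:

* `generate_sinusoid()` — the canonical predictable path; used to verify
  that amplitude scaling changes variance but not entropy.
* `generate_walk()` — a correlated random walk: von Mises turning angles
  (own Best–Fisher sampler), truncated-normal per-frame speeds, and
  ballistic vertical leaps with symmetric rise and fall (so synthetic
  spherical marginals are equator-symmetric, as real leaping produces).
  An optional isotropic position jitter emulates digitization error.
* Three presets (`species_preset()`) emulate a slow, forward-biased,
  planar quadruped ("jird-like"), a fast low-turning leaper
  ("dipus-like"), and a fast, broad-speed, strong-turning leaper
  ("allactaga-like"). Parameters were chosen once for field realism at
  30 fps — speeds of 0.35/0.85/0.95 m/s with increasing spread, turning
  concentrations 25/10/1.5, leap propensities 0/0.05/0.07 with apex
  heights up to 0.12 m — and include a 5 mm digitization-noise floor,
  the jitter inherent in two-camera HD tracking of a meters-scale volume.
  Without that floor a non-leaping species would have exactly zero
  vertical displacement variance, a moment vector on the boundary of the
  moment cone that correctly fails to fit. The presets are calibrated to
  ordinal structure only: they reproduce the ranking
  H(allactaga-like) > H(dipus-like) > H(jird-like) under pooled-scale
  normalization, not any particular absolute entropy.

What the generators do **not** emulate: gait-cycle periodicity within a
stride, speed–turn coupling, wall-following behavior, heteroscedastic
tracking error near the arena edges, and predator-stimulus
responsiveness. Passing the synthetic checks therefore demonstrates that
the estimator and test behave correctly on data with known structure, not
that any particular field dataset would yield a given entropy value.

## Numerical choices

* Natural logarithms throughout; entropies are in nats.
* Multi-indices are enumerated in graded lexicographic order; coefficient
  names (`x100` for $x_1$, `x010` for $x_2$, ...) follow the exponent
  triple.
* The Newton step solves via Cholesky with a tiny jitter, escalated if the
  Hessian is near-singular; step acceptance is Armijo with up to 40
  halvings.
* The entropy is evaluated both by quadrature of $-f\ln f$ and by the
  exponential-family identity $\psi - \sum\lambda_\alpha m_\alpha(f)$;
  disagreement beyond rounding aborts the computation, since it indicates
  an unhealthy quadrature.
* Rejection sampling from a fitted density bounds the envelope by
  $\exp(\sum_\alpha|\lambda_\alpha|)$ — rigorous because every monomial is
  bounded by 1 on the cube — and refuses acceptance rates below $10^{-4}$.
* Froude calculations use $g = 9.81\ \mathrm{m\,s^{-2}}$ by default and
  are exact algebra, no iteration.

## Problem sizes used in the shipped checks

The validation suite runs entirely on synthetic data at sizes chosen to
exercise the asymptotics while remaining desk-friendly: consistency at
$10^5$ uniform samples; preset comparisons at 20,000 frames per species
over five seeds; the resampling test at 500 resamples for separation and
200 replicate tests of 200 resamples each (order 1, 12 nodes per axis,
1000 frames per dataset) for null calibration; sinusoid checks at 8000
frames. The brute-force oracle for the entropy integral uses a midpoint
Riemann sum over $400^3$ cells.

## Known limitations

* Entropies depend on the declared normalization; absolute values from
  different studies are comparable only under the same convention and
  scale.
* Order $k > 4$ is refused: the coefficient count grows as
  $\binom{2k+3}{3}$ and the Hessian becomes ill-conditioned before any
  statistical benefit appears.
* Very concentrated densities (narrow features below the node spacing)
  require raising the node count; the package detects but does not
  automatically repair under-resolution.
* The frame-level resampling null assumes exchangeable frames;
  block resampling relaxes this but makes pseudo-sample sizes slightly
  irregular (whole segments are taken until the target size is reached).
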