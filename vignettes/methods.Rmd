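---
title: "Methods: interpolators, the network-densified survey, and how they are validated"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interpolators, the network-densified survey, and how they are validated}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gwmap)
```

This vignette explains the models behind `gwmap`, the conventions and
defaults it adopts where the underlying methods leave choices open, and
what the package's synthetic studies do and do not demonstrate.

## Surveys and coordinates

A survey is a tibble of stations with WGS84 longitude/latitude and one
numeric column per parameter. All interpolation happens in planar
meters: `project_utm()` maps to UTM (default zone 51N, which covers the
Marinduque survey domain). The island spans roughly 40 km, so planar
Euclidean distances in a single UTM zone introduce negligible error
relative to station spacing. The forward transverse Mercator map uses
the Krueger conformal-latitude series; the inverse runs Newton iteration
on the forward map, so `unproject_utm(project_utm(s))` is an identity to
solver tolerance (well below 1e-9 degrees). Missing cells stay `NA` and
are dropped per parameter, never imputed as zeros.

Two conventions matter downstream. First, prediction grids are
cell-center registered with the northernmost row first (ESRI ASCII
layout); a span of `w` meters at cell size `c` gives `ceiling(w/c) + 1`
cells. Second, stations closer than 10 m are averaged before fitting any
exact-system interpolator (RBF, kriging): the packaged well list
contains one pair ~7 m apart and one pair with identical printed
coordinates, and exact interpolation systems are singular on coincident
support points.

## Deterministic interpolators

**IDW** predicts `ẑ(x₀) = Σ wᵢ zᵢ / Σ wᵢ` with `wᵢ = d(x₀, xᵢ)⁻ᵖ` over
the `k` nearest stations (defaults p = 2, k = 15; with 36 stations the
neighbourhood is effectively global). A target within 1e-9 m of a
station returns that station's value, so the surface is exact and
bounded by the data range.

**GPI** fits one bivariate polynomial (degree 1–3) by ordinary least
squares on standardized coordinates. **LPI** fits the same polynomial
locally at every target under Gaussian kernel weights
`exp(-(d/bandwidth)²)`; the default bandwidth is half the survey
bounding-box diagonal. Local coordinates are normalised by the
neighbourhood spread rather than the bandwidth so that very wide kernels
stay well conditioned (in that limit LPI reproduces GPI of the same
degree). **KS** is LPI of degree 1 with a ridge penalty δ on the
non-intercept terms of the normal matrix — the intercept is never
shrunk, so large δ tends to the locally weighted mean rather than zero.
With barriers, distances become shortest polyline-avoiding paths
computed on the visibility graph over barrier endpoints. δ defaults to
1e-3; δ = 0 recovers plain LPI exactly.

**RBF** solves the exact interpolation system with polynomial drift: the
thin-plate spline `φ(r) = r² log r` (the minimum-curvature choice, and
the default) and the multiquadric carry an affine drift with the usual
orthogonality side conditions; the Gaussian and inverse multiquadric
carry a constant. Kernel distances are scaled by the median pair
distance purely for conditioning; this does not change exactness. The
default shape parameter is the reciprocal of the median pair distance.

## Variograms and kriging

The empirical semivariogram is the Matheron estimator
`γ̂(h) = (1/2N(h)) Σ (zᵢ − zⱼ)²` on 12 equal-width bins up to half the
maximum pair distance, with `(lo, hi]` bin edges. Model fitting profiles
the range: for a candidate range, nugget and partial sill solve a
non-negativity-clamped weighted linear least squares with Cressie
weights `N(h)/γ_model(h)²` (iterated three times from `N`-weights), and
a 1-D optimisation picks the range; the family (spherical, exponential,
gaussian) with the lowest weighted SSE wins. The exponential and
gaussian families use the plain distance-parameter convention
`γ = nugget + psill (1 − exp(−h/range))` (effective range about three
times the parameter). The unbounded power model is available for
evaluation but has no sill and therefore no covariance; it cannot drive
simulation or kriging.

Ordinary kriging solves the standard augmented system per target; the
weight constraint `Σwᵢ = 1` holds to 1e-10 by construction. Universal
kriging augments the constraint set with `{1, x, y}` (standardized), and
reduces exactly to OK with a constant-only drift. Neighbourhoods are
global: with 36 stations, moving windows would only discard information.
By default at-station predictions return the measured value even with a
positive nugget (the exact-interpolator convention); `exact = FALSE`
switches to nugget-filtered smoothing, where a zero-distance target sees
`γ = nugget` and kriging smooths through the measurement-error
component.

Empirical Bayesian kriging here is a documented simplification of the
proprietary original: fit a base variogram; repeatedly draw an
unconditional Gaussian realization at the station locations from that
base model and refit a variogram to the realization; treat the base fit
plus the refits as an equal-weight ensemble of size `K` (so `K = 1` is
exactly OK under the base model). The prediction is the ensemble mean of
member OK predictions and the variance adds the between-member spread to
the mean member variance — this is what accounts for variogram
uncertainty. Members that fail to fit are dropped (at least `K/2` must
survive). Surveys larger than `subset_size` (default 50) are split into
overlapping spatial subsets with per-subset ensembles; at n = 36 a
single subset is used. The ensemble is deterministic given its seed.

## The network and its training

The surrogate is a single-hidden-layer feedforward network with
hyperbolic tangent sigmoid activations on both the hidden and the output
layer. Inputs are min-max scaled to [−1, 1]; targets to [−0.9, 0.9] — a
deliberate margin, since a tansig output can only reach ±1
asymptotically and extreme training targets must stay representable.
Data are partitioned 70/15/15 into training, validation and test sets.

Levenberg–Marquardt minimises the training sum of squares in scaled
units with the Jacobian from backpropagation; damping multiplies by 10
on a rejected step and divides by 10 on acceptance; training stops at
the iteration cap, a gradient norm below 1e-7, or six consecutive
validation-MSE increases, and the weights with the best validation MSE
are kept. The swarm stage searches the flattened weight vector with
training MSE as fitness under the canonical update with
constriction-equivalent coefficients (inertia 0.729, cognitive = social
= 1.49445), positions clamped to a box (default ±2; ±1 suits
tanh-scaled problems) and velocities to half the box. The hand-off is
search-then-refine: LM starts from the swarm's global best, and the
returned model never has a worse training MSE than that best. Zero swarm
iterations degenerate to LM from random initialisation; a one-particle
swarm is legal (its personal and global best coincide).

A practical note from the package's own benchmarks: when the LM budget
is generous, LM from a random start and LM from a swarm start both
converge on desk-scale problems and the comparison is a wash; the swarm
initialisation earns its keep when local refinement is brief (around ten
LM iterations) or the loss is multi-modal. The regression tests encode
exactly that setting.

## The hybrid: survey densification

The hybrid's premise is that interpolation accuracy is limited by
sampling density, and that cheap covariates (location, temperature, pH,
EC, TDS) carry enough signal about a target parameter to manufacture
useful extra observations. `augment_with_nn()` trains the
covariates→target network on the measured stations, predicts the target
at auxiliary sites where the covariates are known, and appends those
sites as pseudo-stations flagged `is_pseudo = TRUE`. The interpolator
then runs on the densified survey. Weight-aware interpolators (LPI/KS)
can down-weight pseudo-stations by `lambda_pseudo`; kriging treats them
as ordinary data (a per-point error model would require a non-stationary
nugget, which is out of scope). An alternative reading of
"network-informed interpolation" — interpolate the network's residuals
and add the trend back — is a residual-hybrid variant; densification is
the default here because the sampling-density motivation points at the
data gap, not at trend removal. For heavy-metal targets the default
covariates are location plus all four physicochemical parameters; for
physicochemical targets, location only — their natural covariates would
be their own siblings, which is circular.

Cross-validation is leave-one-out over *measured* stations only.
Within each fold the entire pipeline is refit without the held-out
station — including network training and pseudo-station generation —
so no information from the held-out well can leak through the
densification (`refit_nn = FALSE` offers a faster, leakier mode that
reuses the full-data network, clearly not the default). A fold that
fails is recorded; more than 20% failures aborts the report. The
governing method minimises MAE, with Pearson R breaking ties — MAE
first, because an interpolator is judged primarily on the size of its
pointwise errors and R is scale-free.

## The synthetic generator

`make_survey()` draws a latent Gaussian random field (exact dense
Cholesky simulation, capped at 2500 points) at the stations and any
auxiliary sites, adds measurement noise at the stations, and derives
each covariate as `intercept + slope · latent + N(0, sd²)`. The default
latent field is spherical with range 10 km, partial sill 1 and nugget
0.05 — island-scale autocorrelation — with measurement noise sd 0.05.
The default links give target–covariate correlations of roughly
0.85–0.95, consistent with a setting where a well-trained surrogate
tracks the target closely (validation correlations in the high 0.9s);
an optional monotone nonlinearity (`sinh`) on the link exercises the
network's advantage over linear drift models. Setting slopes to zero
produces uninformative covariates, the guard case in which the hybrid
is *not* expected to win.

What the synthetic studies show: under spatially structured fields with
informative covariates on the real 36-well geometry, densification
lowers the median leave-one-out MAE of kriging and EBK, and a hybrid
variant is usually the governing method. What they do not show: anything
about the actual spatial distribution of contamination on the island
(the generator does not emulate it), robustness to covariate
measurement error beyond the modelled Gaussian noise, or behaviour at
survey sizes far from a few dozen stations.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly rather than silently: constant
samples have undefined skewness/kurtosis and no normality verdict; CV%
is only defined for positive-mean parameters; zero-variance columns
yield undefined correlations with a warning; rank-deficient polynomial
designs and collinear kriging drifts raise errors naming the cause. The
coefficient-of-variation classes use the printed bins with both
boundaries resolved conservatively (15% is still low, 35% is already
high); correlation-strength bins assign the gaps between printed bin
edges (e.g. 0.895) to the higher bin and include each bin's lower edge.
The Kolmogorov–Smirnov normality test defaults to the Lilliefors
correction, which is what statistical packages apply when the normal's
parameters are estimated from the sample; the uncorrected variant is
available as an option.

The test-suite and acceptance-script problem sizes are chosen for a
desk-scale single-CPU run: variogram recovery uses 400-point fields and
10 seeds; the hybrid comparison uses the 36-well geometry, 40 auxiliary
sites, a swarm of 10 for 200 iterations, 60 LM iterations, and an EBK
ensemble of K = 12 restricted to the spherical family, over 10 seeds.
These sizes are stated here as the package's validation conditions;
larger ensembles and swarms only sharpen the same comparisons.

## Known limitations

- EBK is a simplification: equal-weight ensemble, no likelihood
  weighting, no local model blending; it propagates variogram
  uncertainty but is not the proprietary algorithm.
- Anisotropy is not modelled anywhere (isotropic kernels, isotropic
  variograms); the survey offers no evidence to fit it.
- Barrier distances are exact for polyline barriers but the
  cost-surface diffusion family of interpolators is out of scope.
- The network is a fixed one-hidden-layer tansig architecture; hidden
  width is the only capacity knob.
- Kriging treats pseudo-stations as real observations; their prediction
  uncertainty is not propagated into the kriging variance.
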