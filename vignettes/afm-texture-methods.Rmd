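---
title: "Quantifying AFM surface texture: models, estimators and design choices"
author: "afmtexture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying AFM surface texture: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afmtexture)
```

## The problem

Atomic force microscopy produces a height map `z(x, y)` of a surface at
nanometre resolution. When nanodrug carriers (e.g. dendrimer aggregates) are
deposited on biological tissue, the question of *where and how strongly they
aggregate* becomes a question about surface texture: deposition changes the
amplitude statistics of the height distribution, the multiscale (fractal)
organisation of the relief, and the morphology of thresholded regions. This
package implements the three complementary descriptions used for that kind
of analysis — amplitude roughness parameters, fractal-dimension estimators,
and threshold-sweep Minkowski functionals — together with a morphological
tip-correction step and a synthetic-surface generator that supplies ground
truth for validating all of them.

All heights are in nanometres, row 1 of a `HeightMap` is the top of the
image, and heights increase away from the substrate. Fractal and Minkowski
operations require square pixels (relative anisotropy at most `1e-6`) because
the estimators assume isotropic sampling.

## Amplitude statistics

For heights `Z_i`, `i = 1..N`, the report contains

* `Zbar = mean(|Z_i|)` — the mean absolute height. For zero-referenced maps
  (minimum shifted to 0, the usual AFM convention, and the pipeline default
  before the roughness stage) this equals the plain mean, which is reported
  alongside as `Zmean`.
* `Ra = mean(|Z_i - Zbar|)`, `Rq = sqrt(mean((Z_i - Zbar)^2))`,
* `Rt = |Zmax - Zmin|`, `Rmvd = |min(Z_i - Zbar)|`, `Rmph = max(Z_i - Zbar)`
  (so `Rt = Rmvd + Rmph` whenever `Zbar` lies inside the height range, which
  is guaranteed for non-negative maps),
* skewness and kurtosis in *two* conventions. The absolute-moment forms
  `RskAbs = mean(|Z_i - Zbar|^3)/Rq^3` and `RkuAbs = mean(|Z_i - Zbar|^4)/Rq^4`
  follow the convention of the AFM nanotexture literature this package
  mirrors; note `RskAbs` is non-negative by construction (a Gaussian surface
  gives `2*sqrt(2/pi) ~ 1.596`, not 0). The conventional signed moments about
  the plain mean are reported as `RskSigned`/`RkuSigned` for comparability
  with standard practice (Gaussian: 0 and 3).

All deviation statistics are computed about `Zbar` rather than the plain
mean, verbatim from the defining formulas; the two agree for zero-referenced
data. On a constant surface `Rq = 0` and the skewness/kurtosis are reported
as `NA` with an explicit `undefined` flag instead of propagating NaN.

The height PDF is a normalized histogram over `[Zmin, Zmax]` (default 256
bins for a 512 x 512 scan); the mode `Zmode` is the centre of the maximal
bin with ties broken towards the lowest bin, a deterministic convention
chosen because the estimator is otherwise unspecified. A caveat documented
here deliberately: on strongly correlated surfaces (any fBm-like background)
the argmax mode of an empirical histogram wanders by several bins between
realizations even though the underlying marginal is exactly Gaussian, so
mode-based agreement checks must be read against `Rq`, not against the bin
width. `unimodalityCheck()` therefore accepts a surface as unimodal when
mean, median and mode agree within `0.5 * Rq` *and* the smoothed density has
a single prominent peak (Gaussian smoothing with bandwidth 1/24 of the
range, peaks filtered at 10% topographic prominence — plain local-maxima
counting misclassifies genuinely unimodal correlated surfaces).

## Fractal dimension

A self-affine surface with Hurst exponent `H` in (0, 1) has fractal
dimension `Df = 3 - H`, between 2 (smooth) and 3 (extremely rough). Each
estimator builds a log-log scaling curve and fits a straight line by
ordinary least squares; the slope maps to `Df` per method:

| method | statistic | mapping |
|---|---|---|
| cube counting | box count N(l), dyadic l | `Df = -slope` |
| triangulation | triangulated area A(l) | `Df = 2 - slope` |
| variance | within-box variance s2(l) | `Df = 3 - slope/2` |
| power spectrum | averaged 1D periodogram P vs scale 1/f | `Df = (7 - slope)/2` |
| structure function | mean squared increment S(tau) | `Df = 3 - slope/2` |
| variation | sampled oscillation V(l) | `Df = 3 - slope` |

Numerical choices that matter, all validated against the `Df = 3 - H`
ground truth of the spectral generator rather than taken on faith:

* **Scale ladder and fit range.** Dyadic scales from 2 px (1 px for
  triangulation and the structure function) up to a quarter of the side
  length; the automatic fit range drops the largest-scale octave, where box
  statistics average over too few boxes, and any point whose statistic is
  zero. Explicit index ranges can be supplied instead.
* **Height normalization.** Cube counting normalizes heights so the full
  range spans the lateral extent (cubes are cubes regardless of units);
  triangulation normalizes the sample `Rq` to eight times the lateral
  extent so the probed octaves sit firmly in the self-affine regime — a
  pre-build calibration showed that without this the area excess of
  moderate-relief surfaces vanishes at coarse scales and drags `Df` towards
  2. Both estimators are thereby invariant under height rescaling, as are
  variance, structure function and variation; only the power spectrum's
  intercept moves.
* **Lattice-resolution suprema.** Cube counting and variation evaluate the
  per-cell height span from the grid subsampled at the lattice constant
  (the 4 cell corners) rather than the supremum over all interior pixels.
  The supremum of a Gaussian field over a box grows with the number of
  sampled points, which adds a slowly varying factor to the scaling curve
  and biased `Df` by -0.2 to -0.3 in calibration; corner spans scale
  exactly self-affinely and brought all estimators within +-0.08 of
  `3 - H` for `H` in {0.3, 0.5, 0.7} at 1024^2.
* **Power spectrum.** Periodograms of all rows and all columns are averaged;
  frequencies above 1/16 of the sampling rate are excluded (discrete-sum
  truncation distorts the highest octave). This estimator is not height-
  scale-free and legitimately returns `Df < 2` on non-fractal surfaces;
  such values are flagged, never clamped — an out-of-range flag is itself a
  diagnostic that the surface is not self-affine.
* **Degenerate inputs.** A zero-variance surface has `Df = 2` by definition
  for cube counting, triangulation and variation; variance and structure
  function raise a degenerate-surface error because their statistics are
  identically zero. A noise-free inclined plane gives exactly 2 for
  triangulation (triangle areas are scale-independent).
* **B-spline resampling** (`bsplineResample()`, separable natural cubic
  splines) is available because such preprocessing is common before fractal
  analysis, but it is off by default: interpolation smooths below the
  original pixel scale and shifts fine-scale estimates (up to a few tenths
  at factor 2 on rough surfaces), and it should be a deliberate choice.

## Minkowski functionals

Sweeping a threshold `z` over the height range (evenly spaced grid, both
endpoints included) and binarizing with white = `height >= z` yields three
discrete functionals: the white fraction `V(z)` (monotone from 1 to 0), the
boundary density `S(z)` (4-neighbour white/black pairs per pixel) and the
connectivity `chi(z) = (C_white - C_black)/N` with 8-connected white and
4-connected black components. The 8/4 pairing avoids the digital-topology
paradox (a diagonal line must not both connect and disconnect the
background); components touching the border count as components, which
breaks exact complement duality only at the border. Curves are normalized
per pixel so scans of different sizes are comparable; raw counts are kept.

The `>=` binarization makes `V` exactly 1 at the minimum height and exactly
0 above the maximum on every input; the price is that the extreme
thresholds carry a trivial `chi` of +-1/N (one all-white or all-black
component), so landmark extraction searches `chi` only over non-trivial
thresholds (0 < V < 1). Landmarks: the thresholds of the `chi` minimum and
maximum, of the `S` maximum, the interpolated `V = 0.5` crossing, the first
vanishing of `chi` after its maximum, and tolerance-based plateau runs.
`volumeSymmetryScore()` quantifies the point symmetry of `V` about its 0.5
crossing (1 = perfectly point-symmetric); one-sided deposition lowers it.

## Tip correction

An AFM image is approximately the grayscale morphological dilation of the
true surface by the tip shape. The tip model is the upper envelope of a
spherical apex cap (default radius 12 nm, the value commonly used for
contact-tip reconstruction models) and a four-sided pyramid rotated by 45
degrees; the sidewall half-angle defaults to 17.5 degrees — typical probe
geometry, deliberately exposed as a parameter because it is rarely
certified — and the sphere governs out to a lateral distance
`R * sin(2 * theta)` before the facets take over. Erosion by the reflected
tip gives the canonical upper-bound reconstruction; the certainty map marks
pixels where the apex was the unique touching point, and there the
reconstruction is exact. The morphological laws (`rec >= true`, equality on
the certainty set, idempotence of the opening) are property-tested on
random surfaces. Borders are edge-replicated so a 512^2 map stays 512^2;
the conservative alternative (cropping by the tip half-extent) can be had
by cropping the input beforehand. In the pipeline the reconstruction feeds
the fractal stage by default and is optional for roughness/Minkowski,
mirroring the usual processing order in which only fractal analysis is
preceded by dilation correction.

## Synthetic scenes and what they do (not) show

No real scans ship with the package; the generator stands in for them with
known ground truth.

* **Background**: spectral synthesis of a 2D fractional Brownian surface —
  Gaussian white complex spectrum shaped by the radial law
  `P(f) ~ f^(-2(H+1))` (the 2D-surface convention for which `Df = 3 - H`;
  conventions differing by one between profile and surface definitions are
  a classic source of off-by-one-half dimension errors, hence the explicit
  statement), zero-frequency removed, inverse FFT, then exact rescaling to
  sample mean 0 and sample `Rq = rmsTarget`. Defaults emulate a 2 x 2 um,
  512 x 512 px tissue scan: `H = 0.55`, `Rq = 16` nm, the amplitude scale
  of diseased-tissue scans at that size; a smoother healthy-like background
  uses `H = 0.75`, `Rq = 20` nm.
* **Particles**: spherical caps with truncated-normal lateral radii
  (clipped at 1 px and 3 sd), apex height a fixed fraction of the radius,
  seated on the background at the centre-pixel height and combined by
  pointwise maximum — solids never interpenetrate and no pixel is ever
  lowered, so mean height is monotone in the particle count. The default
  field (60 caps of 35 +- 8 nm radius, height fraction 0.35, ~6% coverage)
  keeps the height PDF unimodal with mean, median and mode close on the
  `Rq` scale, matching how moderately dendrimer-loaded tissue scans are
  described; the heavy field used for asymmetric scenes (120 caps of
  80 +- 20 nm, height fraction 0.8) pushes enough mass into the upper tail
  to break the volume curve's point symmetry. Radii and centres of particle
  `i` derive from sub-seed `i`, so raising the count never moves earlier
  particles.
* **Fixtures**: plane, half-plane step, disjoint disk fields and a
  single-pixel checkerboard give closed-form Minkowski and roughness
  oracles (e.g. the checkerboard is one 8-connected white net against N/2
  isolated black pixels).

What passing tests on these scenes does *not* show: real tissue is neither
Gaussian nor stationary (plaque introduces structured, anisotropic relief),
real aggregates are not spherical caps, and instrument artifacts (drift,
line noise, feedback overshoot) are absent. The synthetic validation
certifies the estimators, not any biological conclusion; leveling and
flattening of raw scans are likewise out of scope and assumed done
upstream.

## Pipeline determinism and problem sizes

`analyzeSample()` runs zero-reference (optional) -> tip reconstruction
(optional) -> roughness + PDF -> fractal suite -> Minkowski curves, records
any stage failure with its reason while the remaining stages still run, and
embeds the config in the report. Reports serialize with numbers at 10
significant digits, so identical input and config give byte-identical
files. `compareSamples()` produces descriptive long/difference/sign tables
only — each report summarizes a single scan, so hypothesis testing across
samples would misrepresent n = 1 and is deliberately absent.

The validation suite exercises ground-truth recovery at 1024^2 over 10
seeds per Hurst value (the size at which all six estimators converge
within +-0.15 of `3 - H`), morphological laws on 20 imaged 128^2 surfaces,
and Minkowski exactness against an independent flood-fill oracle on 50
random binary images; the accompanying summary script reports the same
quantities at 512^2 over 5-10 seeds. These sizes are the package's
validation conditions; estimates on smaller maps carry visibly more
variance (the fit has fewer octaves) and below 128 px the automatic fit
range may not retain the four points it requires.
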