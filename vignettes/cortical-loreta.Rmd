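---
title: "Cortical LORETA and the choice of a discrete Laplace-Beltrami operator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cortical LORETA and the choice of a discrete Laplace-Beltrami operator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

EEG source reconstruction asks for a current-density distribution `J`
(three Cartesian dipole-moment components at each of `m` cortical
nodes, so `3m` unknowns) that explains the potentials `D` measured at
`n` scalp electrodes through the leadfield matrix `L` (`n x 3m`).
With `n` in the tens and `3m` in the thousands the problem is heavily
underdetermined, and `cloreta` solves the Tikhonov-type functional

    min_J  || L J - D ||^2  +  alpha J' W J ,

whose minimizer is the linear inverse operator applied to the data,
`J_hat = T D` with

    T = W^-1 L' [ L W^-1 L' + alpha I_n ]^-1           (direct form)
    T = W^-1 L' pinv(L W^-1 L', beta * mu)             (truncated SVD)

where `mu` is the largest singular value of `L W^-1 L'` and the
pseudoinverse zeroes all singular values strictly below `beta * mu`.
The two forms are alternatives; the truncated-SVD form is the one used
throughout the benchmark because the regularization strength can be
tied to the singular spectrum through the SVD cutoff index (below).

The choice of `W` encodes the prior:

* `W = I` -- classical minimum norm;
* `W = diag(Omega)^2 (x) I_3` -- depth-weighted minimum norm, the
  "no-Laplacian" reference (`(x)` is the Kronecker product over the
  three orientation components);
* `W = [Omega (B'B + sigma I_m) Omega] (x) I_3` -- cortical LORETA:
  depth weighting combined with a discrete Laplace-Beltrami smoothness
  prior on the cortical surface.

`B` is the stiffness matrix of a discrete Laplace-Beltrami operator on
the triangulated cortex,

    (B f)_i = (1 / d_i) * sum_{j in N(i)} w_ij (f_i - f_j),

with 1-ring neighborhoods `N(i)`, edge weights `w_ij` and vertex
masses `d_i`.  Four schemes are implemented (`laplacian_schemes()`):

| scheme     | `w_ij`                          | `d_i`                     |
|------------|---------------------------------|---------------------------|
| `uw-graph` | 1                               | 1                         |
| `w-graph`  | `1 / dist(p_i, p_j)`            | `sum_j dist(p_i, p_j)`    |
| `uw-geom`  | `(cot a_ij + cot b_ij) / 2`     | 1                         |
| `w-geom`   | `(cot a_ij + cot b_ij) / 2`     | `A_mixed(i)`              |

`a_ij`, `b_ij` are the two angles opposite the edge; `A_mixed` is the
mixed Voronoi vertex area (circumcenter decomposition in non-obtuse
triangles, half / quarter triangle areas when the triangle is obtuse
at / away from the vertex), so the per-vertex areas tile the surface
exactly -- a property the test suite asserts at 1e-10 relative.
Triangle areas are computed with Kahan's stabilized rearrangement of
Heron's formula so that needle-like triangles do not lose precision.

Every `B` annihilates constants, `diag(d) B` is symmetric, the
spectrum (of the mass-symmetrized similar matrix `D^{1/2} B D^{-1/2}`)
is real and non-negative, and the kernel dimension equals the number
of connected mesh components.  Because `B'B` is therefore singular,
the prior uses `B'B + sigma I_m`; `sigma > 0` makes `W` positive
definite and doubles as a smoothing dial discussed next.

## Tunable parameters

**`sigma`** (dimensionless, useful range `(0, eta^2]` with `eta` the
largest singular value of `B'B`).  Large `sigma` makes the prior
behave like a scaled identity -- the Laplacian's influence vanishes
and the solution approaches the depth-weighted minimum norm.  Small
`sigma` smooths aggressively until distinct sources fuse and the data
fit degrades.  `sigma_scan()` automates the published trade-off
procedure: scan `sigma` over a log grid (optionally refined linearly),
and keep the values whose solutions retain a goodness of fit of at
least 90% *and* deviate from the no-Laplacian solution by at least
10%, for every tested `alpha`; `sigma*` is the arithmetic mean of the
satisfying set.  The scan data set is a bilateral two-dipole
simulation with additive white noise at SNR 20.  Because each scheme's
`B` has a different spectral scale, the scan grid is anchored at the
scheme's own `eta^2` and spans ten decades below it; quoting a single
`sigma` across schemes or meshes is meaningless.  When no `sigma`
satisfies both conditions the scan is retried with `alpha <= 0.0025`
only, then falls back to the best-deviating `sigma` among those
keeping the fit, deterministically.

**`alpha` / `beta` / SCI.**  In the truncated-SVD operator the
regularization is the relative tolerance `beta`.  For noiseless data
`beta` is derived from the SVD cutoff index (SCI): zero the SCI
smallest singular values of `L W^-1 L'`, place the cutoff value (SCV)
at the geometric mean of the two bracketing singular values (the
geometric mean is scale-invariant and guarantees strict betweenness),
and set `beta = alpha = SCV / mu`.  The benchmark defaults to
SCI = 1 -- only the smallest singular value is removed -- the
noiseless-data choice of the published procedure;
`alpha_selection()` automates the per-dataset comparison of candidate
SCIs by MA localization error, with ties broken by fewer local maxima
and then by the smaller index.

**Depth weighting `Omega`.**  `depth_weights()` defaults to the
leadfield column energy `Omega_jj = sum_i l_ij' l_ij`.
`sqrt_weights = TRUE` gives the column norm instead, and the benchmark
uses that variant: in `W^-1` the energy form amplifies low-gain nodes
by the fourth power of the inverse gain, and combined with the
smoothness prior this drags estimates into poorly covered regions
(empirically, the power maximum collapsed to the sensor-free pole of
the test sphere).  The norm form -- the convention of the original
LORETA literature -- compensates depth once and behaves as published.

**Forward model.**  `spherical_leadfield()` evaluates the closed-form
potential of a current dipole inside a homogeneous conducting sphere
(insulating exterior), derived from the Legendre-series solution of
the interior Neumann problem, with electrodes on the sphere and
average reference applied to every column.  Units are fixed: positions
mm, moments nA m, potentials microvolts, conductivity 0.33 S/m.  The
tests cross-check the closed form against an independently coded
Legendre series differentiated numerically, and assert linearity,
rotational equivariance and monotone depth attenuation.

## The synthetic study conditions

`make_cortex_surface()` emulates a segmented cortical surface only in
the respects that matter to the operators: a closed, irregular
triangulated 2-manifold at cortex scale.  It is a spherified cube
(vertex valence 6 away from the eight cube corners, matching
segmentation meshes; node count `6 n^2 + 2` near any requested
target), tangentially jittered with a seeded RNG, radially corrugated
by a smooth sinusoid to mimic folds, and anisotropically scaled.  The
default 55 mm base radius under the 85 mm sensor sphere reproduces the
~2 cm anatomical scalp-to-cortex clearance; the earlier the folds
approach the electrodes, the more pathological the gain dynamic range
of a single-shell model becomes.  `make_montage()` is a deterministic
Fibonacci spiral on a 140-degree spherical cap (64 sensors by
default), reaching about 0.81 of the ideal hexagonal spacing.

What the generator does *not* emulate: true sulcal geometry (deep
narrow folds with opposing walls), the skull's low-conductivity layer
(a multi-shell or BEM model would smooth all topographies), spatially
correlated physiological noise, and mesh defects of real
segmentations.  Passing benchmarks therefore demonstrate the
*relative* behavior of the operators under controlled conditions, not
clinical-grade localization accuracy.

Simulated datasets each activate exactly one dipole placed at a
triangle barycenter of the inverse mesh -- on the discrete surface but
never on a source-space node, which avoids the inverse crime -- with a
random orientation and a 10 nA m moment.  Noise, when requested, is
white Gaussian re-referenced to the average and rescaled so the
channel-pooled RMS signal-to-noise ratio is met exactly.

## Numerical choices

* Vertex indices are 1-based in R; OFF/PLY/plain-text files keep their
  0-based conventions.
* Obtuseness in the mixed-area branches uses the cosine sign with a
  1e-12 tolerance; angles within tolerance of 90 degrees take the
  Voronoi branch (the branches agree in the limit).
* Negative cotangent weights on obtuse triangles are kept as they are;
  clipping would destroy the symmetry of `diag(d) B`.
* Eigenanalysis of the non-symmetric `B` goes through the similarity
  transform with `diag(d)^{1/2}`; zero eigenvalues are counted below
  `1e-8 * lambda_max`.
* `W` is never formed densely: solves use the Kronecker block
  structure via a sparse Cholesky factorization of the `m x m` core,
  applied once per orientation coordinate.
* Maximum-amplitude ties break to the lowest node index; the 50%
  activity mask uses strict "below", so values at exactly half the
  maximum survive; the mask feeds the COM/MA localization measures
  while the local-maxima count uses the unmasked power (the mask is
  part of the localization measures only).
* The sigma-scan acceptance conditions are applied per `alpha` and
  required for all `alpha` in the grid.  The deviation-versus-`sigma`
  curve is monotone only up to small jumps where the truncated-SVD
  rank changes with `sigma`; the tests assert monotonicity with a 2%
  slack of the curve's range plus a tenfold attenuation across the
  grid rather than literal monotonicity.
* Benchmark problem sizes: ~1,000-node cortex, 64 sensors, 1,000
  noiseless datasets -- the full published dataset count, which this
  implementation completes in about a minute.  Summaries report both
  Pearson and Spearman correlations between simulated and estimated
  source depth; the Pearson form is the published comparison.

## A worked run

```{r, eval = FALSE}
library(cloreta)
cfg <- benchmark_config(n_datasets = 100, seed = 1)
bench <- run_benchmark(cfg)
bench$summary
```

The summary table has one row per method (`no-laplacian` reference
plus the four schemes) with mean localization errors (COM and MA, mm),
mean depth shifts (mm, positive = estimate too superficial), mean
local-maxima counts, mean residual variance, and the depth
correlations.  At the benchmark's full problem size (1,000 datasets;
the acceptance suite runs exactly this) every Laplacian variant
reduces the mean MA localization error and the local-maxima count
relative to the reference and raises the COM depth correlation, while
the reference keeps the lowest residual variance -- the smoothness
term buys its stability at a small cost in data fit.  At the
100-dataset preview above a single variant can sit within sampling
noise of the reference on one measure.

## Limitations

The forward model is a single homogeneous sphere; externally computed
leadfields can be supplied through `read_leadfield()` but multi-shell
or realistic head models are out of scope.  Orientation-constrained
source models, noise-covariance whitening, time-frequency processing
and inferential statistics on the benchmark tables (ANOVA, post-hoc
tests) are deliberately not implemented -- the per-dataset tables are
written so any statistics package can consume them.  The volumetric
regular-grid Laplacian is excluded; the package is strictly the
cortical (surface) variant.
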