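# cloreta

Cortical LORETA: distributed EEG source reconstruction constrained to
a triangulated cortical surface, with four discrete Laplace–Beltrami
operators as interchangeable spatial smoothness priors and a
simulation benchmark for comparing them.

## The problem and who this is for

An EEG montage measures tens of scalp potentials; a cortical source
space has thousands of unknown dipole moments.  The ℓ2-regularized
(LORETA-type) inverse picks the source distribution that fits the data
while minimizing a weighted quadratic penalty,

```
min_J ‖L·J − D‖² + α·JᵀWJ,          Ĵ = T·D,
T = W⁻¹Lᵀ·pinv(LW⁻¹Lᵀ, β·μ)
```

where `L` is the leadfield, `W = [Ω(BᵀB + σI)Ω] ⊗ I₃` combines
diagonal depth weighting `Ω` with a discrete Laplace–Beltrami
stiffness matrix `B` on the cortical mesh, and the pseudoinverse
truncates singular values below `β·μ` (`μ` = largest singular value).
On a triangulated, irregular surface there is no single canonical
Laplacian; this package implements the four standard discretizations

```
(Bf)_i = (1/d_i) Σ_{j∈N(i)} w_ij (f_i − f_j)
```

* unweighted graph Laplacian — `w_ij = 1`, `d_i = 1`
* weighted graph Laplacian — `w_ij = 1/dist(p_i,p_j)`, `d_i = Σ dist`
* unweighted geometric (cotangent) Laplacian — `w_ij = (cot α_ij + cot β_ij)/2`, `d_i = 1`
* geometric Laplacian with mixed Voronoi vertex areas — cotangent
  weights, `d_i = A_mixed(i)`

together with everything needed to compare them the way a methods
study would: synthetic cortex-like surfaces and electrode montages, an
analytic spherical-head leadfield, the σ-selection scan, the
SVD-cutoff-index (SCI) rule for the regularization parameter, and
per-dataset evaluation measures (localization error by center-of-mass
and maximum-amplitude, source depth and depth shift, local-maxima
count, residual variance / goodness of fit, solution similarity).

It is aimed at EEG/MEG methods researchers who want a transparent,
fully scriptable reference implementation of surface-constrained
LORETA and of the operator trade-offs, not at clinical use.

## Worked example

```r
library(cloreta)

mesh <- make_cortex_surface(750, seed = 1)   # corrugated cortex stand-in
mesh
#> trimesh: 728 vertices, 1452 triangles, 2178 edges

st <- assemble_stiffness(mesh, "w-geom")
spectral_report(st)$n_zero                   # one zero eigenvalue: connected
#> [1] 1

bench <- run_benchmark(benchmark_config(n_datasets = 100, seed = 1))
bench
#> benchmark: 100 datasets x 5 methods on 1016 nodes
#>         method localization_error_com localization_error_ma depth_shift_com
#> 1 no-laplacian                  7.644                11.328          1.7146
#> 3     uw-graph                  6.778                 9.142         -0.4354
#> 5      w-graph                  7.904                11.483         -0.7391
#> 2      uw-geom                  8.177                10.028         -0.1671
#> 4       w-geom                  6.992                10.506         -0.2673
#>   depth_shift_ma n_local_maxima        rv gof depth_cor_com depth_cor_ma
#> 1         4.1310          21.70 3.538e-28 100        0.6679       0.6892
#> 3         0.4102          15.68 7.678e-27 100        0.7705       0.6199
#> 5         0.5656          13.94 1.315e-25 100        0.7226       0.5037
#> 2         1.3331          15.54 3.429e-25 100        0.7347       0.6225
#> 4         1.6197          15.37 6.341e-27 100        0.7684       0.6229
```

Reading the table: each row is one inverse operator — the
depth-weighted minimum norm without Laplacian (`no-laplacian`) and
cortical LORETA with each of the four schemes.  Localization errors
(mm) are distances between the simulated dipole and the estimate's
center of mass / maximum-amplitude node after 50%-of-maximum masking;
`depth_shift` (mm) is positive when the estimate is too superficial;
`n_local_maxima` counts nodes exceeding all 1-ring neighbors (a proxy
for false-positive blobs); `rv`/`gof` measure the data fit;
`depth_cor_*` correlate simulated with estimated source depth.  Here
the Laplacian priors cut the number of spurious maxima by a third and
shrink the depth bias from about +4 mm to under 2 mm relative to the
plain depth-weighted inverse, at a (numerically tiny) cost in residual
variance — the reference always fits the data best.  Three of the four
schemes also reduce the maximum-amplitude localization error in this
100-dataset preview (the weighted graph Laplacian sits within sampling
noise of the reference); at the full problem size of 1,000 datasets
every scheme reduces both localization errors and raises the COM depth
correlation.

The σ-selection procedure itself is exposed:

```r
L  <- spherical_leadfield(make_montage(64), mesh)
ds <- simulate_datasets(mesh, make_montage(64), 1, seed = 1, snr = 20)
sc <- sigma_scan(L, mesh, "uw-graph", ds[[1]]$data,
                 sigma_grid = 10^seq(-4, 2), alpha_grid = c(0.01, 0.0025),
                 omega = depth_weights(L, sqrt_weights = TRUE))
sc$sigma_star   # mean of the sigma values passing the GOF/deviation trade-off
```

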