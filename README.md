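# sinodeform

Sparse-view tomography by **displacement-function sinogram interpolation**.

In sparse-view CT the number of measured projection views falls far below
the Shannon requirement (about one view per detector bin over 180°), and
filtered backprojection (FBP) of the raw data is full of angular-aliasing
streaks. Filling the unmeasured views with any *linear* interpolator —
nearest-view copy, two-view averaging, band-limited sinc along the view
axis — reconstructs to the sparse-data image plus rotated ghost copies of
itself, because each estimated view is a fixed linear combination of views
measured at other angles.

`sinodeform` implements the nonlinear alternative for parallel-beam data:
for each detector bin `n`, estimate an integer displacement `u(n)` that
deforms one measured view into its neighbour,

```
p(n, m2) ≈ p(n + u(n), m1),
u(n) = argmin_{|u| ≤ N}  [p(n, m2) − p(n + u, m1)]²
         + λ [sign(∇p(n, m2)) − sign(∇p(n + u, m1))]²,   λ = 0.01,
```

found by exhaustive search over the `2N + 1` integer candidates, and then
interpolate the *displacement* instead of the projection values: the view at
fraction `f` of the gap is the measured view deformed by `f · u(n)`, with
linear interpolation splitting the non-integer target between adjacent bins,

```
p(n, m) ≈ (1 − α) p(n1, m1) + α p(n1 + 1, m1),
n1 = ⌊n + f u(n)⌋,  α = n + f u(n) − n1 .
```

Forward, backward and (default) proximity-weighted bidirectional variants
are provided. Because features *move* along the detector between nearby
angles far more than they change value, the deformed estimate tracks them
instead of averaging them into double images.

The package ships everything needed to compare the method end to end on
synthetic data:

* analytic (noiseless, closed-form) parallel-beam projection and
  rasterization of ellipse phantoms, with a default body-plus-marker-doublet
  phantom;
* the linear baselines: view copy, two-view linear interpolation, and
  periodic DFT zero-padding sinc interpolation;
* parallel-beam FBP (spatial-domain Ram–Lak kernel) and Landweber iterative
  reconstruction `X ← X + α Aᵀ(P − A X)` with a matched Joseph
  projector/backprojector pair (exact adjoints, compiled with Rcpp);
* error metrics: reconstruction RMSE, sinogram absolute-error maps with
  max/sum statistics, and the Shannon view-count requirement;
* float-TIFF + text-sidecar I/O, an experiment runner, and a command-line
  front end (`exec/sinodeform`).

## Worked example

Expand 120 measured views to 360 with all four estimators and reconstruct:

```r
library(sinodeform)
cfg <- experiment_config(views_measured = 120, views_target = 360)
res <- run_experiment(cfg)
print(res$summary, digits = 4)
#>         method views_in views_out sino_max_abs sino_sum_abs recon_rmse
#> 1          raw      120       120           NA           NA    0.06763
#> 2         copy      120       360        37.59        36649    0.06709
#> 3       linear      120       360        18.94        15591    0.04985
#> 4         sinc      120       360        15.45        19280    0.04968
#> 5 displacement      120       360        17.58         9760    0.04099
```

Reading the table: `sino_sum_abs` / `sino_max_abs` compare each expanded
sinogram against the analytic 360-view truth (line integrals in pixel
units); `recon_rmse` compares the FBP reconstruction against the rasterized
phantom (density units). Displacement interpolation cuts the summed
sinogram error by ~37% versus two-view linear interpolation and gives the
best reconstruction (RMSE 0.041 vs 0.050/0.050 for the linear baselines and
0.068 for raw under-sampled FBP) — the rotated-ghost error of the linear
methods is what it removes. The same protocol at 60→180 views shows the
gap widening as the per-gap feature motion grows.

Lower-level entry points: `project_phantom()`, `estimate_displacement()`
(returns the per-bin field, exportable via `write_displacement_csv()`),
`estimate_missing_views()`, `upsample_sinogram()`, `fbp_reconstruct()`,
`landweber_reconstruct()`. See
`vignette("displacement-interpolation")` for the model, parameter defaults
and known limitations.

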