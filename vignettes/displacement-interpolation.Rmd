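---
title: "Displacement-function interpolation for sparse-view sinograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Displacement-function interpolation for sparse-view sinograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Sparse-view CT acquires far fewer projection views than the Shannon
criterion asks for (about one view per detector bin over 180 degrees,
`shannon_required_views()`), and filtered backprojection of such data is
riddled with angular-aliasing streaks. A tempting repair is to fill in the
unmeasured views by interpolating the sinogram along the view axis. Any
*linear* fill-in — nearest-view copy, two-view averaging, band-limited sinc —
reconstructs to a superposition of the sparse-data image with slightly
rotated copies of itself, because each estimated view is a fixed linear
combination of measured views acquired at other angles. The rotated ghosts
are worst far from the rotation center.

This package implements the nonlinear alternative: estimate, per detector
bin, an integer **displacement function** `u(n)` that deforms one measured
view into its neighbour, and interpolate the *displacement* rather than the
projection values. The premise is physical: between nearby angles, sinogram
features *move* along the detector (a point at radius `r` traces
`t = r cos(theta - theta0)`) much more than they change value.

## The estimator

Given measured views `p(., m1)` and `p(., m2)`, the displacement satisfies
`p(n, m2) ~ p(n + u(n), m1)`. For each bin `n` independently, `u(n)` is the
integer in `[-N, N]` minimizing

```
F_n(u) = [p(n, m2) - p(n + u, m1)]^2
       + lambda * [sign(dp(n, m2)) - sign(dp(n + u, m1))]^2
```

where `dp` is the backward finite difference along the detector. The search
is exhaustive over the `2N + 1` candidates ("min-search"), deterministic,
and needs no iteration. The sign term (weight `lambda = 0.01`) rewards
matching local slope direction; it is what lets the matcher track features
whose amplitude changes between views, and it disambiguates matches on
shallow gradients.

Numerical choices that the objective alone does not fix:

* **Scale normalization.** The two rows are jointly scaled to unit peak
  before the search. The argmin of the data term is invariant to this, and
  it puts the data on the order-one scale at which `lambda = 0.01` actually
  balances the two terms — on raw line integrals in pixel units (hundreds),
  the sign term would be numerically void.
* **Tie-breaking.** Ties resolve to the smallest `|u|`, negative candidate
  first — a least-deformation prior. This makes all-zero and identical rows
  return `u = 0` exactly, and makes repeated runs bit-identical.
* **Boundary rule.** Samples outside the detector read as zero. Line
  integrals vanish outside the object support, so for untruncated data these
  are exact zeros; the `sinogram()` constructor warns when edge bins carry
  signal.
* **Search radius.** A feature at radius `r` moves at most
  `2 r sin(gap/2)` bins between views one gap apart, so the field of view
  bounds the physical motion at `2 R sin(gap/2) / bin_spacing`. The default
  `N = 7` is this bound for the default protocol (3-degree measured gaps,
  367 bins spanning a 256-pixel FOV). We deliberately do not enlarge the
  default for sparser protocols: candidates far beyond the motion of real
  features only offer spurious value matches on shallow slopes, which
  measurably degrade the estimate. Set `search_radius` explicitly when your
  geometry moves features farther.

## Synthesizing views

A missing view at fraction `f` of the gap is the source view deformed by
`f * u`: with `n1 = floor(n + f u(n))` and `alpha` the fractional part, the
estimate is `(1 - alpha) p(n1, m1) + alpha p(n1 + 1, m1)` — a convex
combination, so nonnegative data stay nonnegative. For `M` missing views
between two measured ones the fractions are `k / (M + 1)`, `k = 1..M`;
the gap after the last view wraps to the first (360-degree periodicity),
which is what makes 120 measured views expand to exactly 360.

Three directions are available. *Forward* deforms the earlier view,
*backward* the later one with the reverse field, and the default
*bidirectional* blends the two one-sided estimates with angular-proximity
weights `(1 - f)` and `f`. At the midpoint (view doubling) this is the plain
average of the two half-displaced views. The proximity weighting matters off
the midpoint: wherever both displacement fields vanish, the blend reduces
exactly to two-view linear interpolation, so static regions are never
estimated worse than the linear baseline — an equal-weight average would
degenerate to nearest-view-copy error there.

## Baselines

`copy_view_upsample()`, `linear_upsample()` and `sinc_upsample()` implement
the linear-convolution competitors. Sinc interpolation is realized as
discrete-Fourier zero padding of each bin's 360-degree-periodic view signal
(the natural band-limited interpolator for uniform full-turn sampling; the
Nyquist coefficient of even-length signals is split between the positive and
negative frequency to keep the interpolant real). All three are linear
operators — the property-based tests verify superposition to `1e-9` — while
displacement interpolation demonstrably violates it; that nonlinearity is
the whole point.

## Reconstruction

`fbp_reconstruct()` is standard parallel-beam FBP: the discrete
spatial-domain Ram–Lak kernel (`h[0] = 1/(4 d^2)`,
`h[k] = -1/(pi^2 k^2 d^2)` for odd `k`, zero otherwise — the spatial-domain
form avoids the DC bias of sampling the frequency ramp), no apodization
window, pixel-driven backprojection with linear detector interpolation, and
angular weight `pi / V` so the two redundant half-turns of a 360-degree
acquisition average. On the analytic disk the interior density is recovered
within 3%.

`landweber_reconstruct()` iterates `X <- X + alpha * At (P - A X)` with a
matched Joseph projector pair: `A` steps each ray along its dominant image
axis with linear cross-axis interpolation, and `At` is its exact transpose,
so the adjoint identity the convergence analysis assumes holds to rounding
error (tested at `1e-6`). The update is written in descent form — the
residual decreases — since the ascent sign diverges for any positive step.
The system is expressed on the unit-radius field of view (`c = 2 /
image_size` per pixel; equivalently the pixel-unit pair with effective step
`alpha c^2`): on that scale the operator norm is of order one for the
geometries targeted here and the default relaxation `alpha = 0.01` sits
safely below the classical bound `2 / sigma_max^2`. It is also deliberately
small, which is why Landweber images stay visibly blurrier than FBP at 1000
iterations. Residuals are recorded per iteration, and growth over 10
consecutive iterations raises a warning rather than passing silently.

## The synthetic phantom

`default_phantom()` is a deterministic stand-in: a large body ellipse
(density 0.25), four moderate-contrast internal structures, and two tight
black/white marker doublets — density −/+1 at the center, −/+3 near the
bottom periphery, radius about 3.5 px. Design rationale:

* The markers are the measuring instrument. View-interpolation error is
  governed by how far features move per angular gap relative to their width.
  The bottom doublet (orbit radius ~80 px) moves ~4 bins per 3-degree gap
  and ~8 bins per 6-degree gap — past its own width at 60 views, which is
  the regime where linear averaging produces fully separated double-bumps
  (the rotation-artifact mechanism) while displacement tracking still
  follows the motion. The central doublet barely moves and serves as the
  well-resolved control.
* Each pair is an *adjacent* doublet, not two diametrically opposed dots:
  a tight doublet projects to a dipole that translates near-rigidly, whereas
  opposed placement makes the two traces cross at full speed and annihilate
  mid-gap — a morphing of projection values that no single-valued
  displacement can represent and that punishes every estimator alike.
* Body and structure contrasts are kept smooth and moderate so view
  profiles resemble soft tissue plus markers; there is no thin
  high-contrast shell, whose sqrt-singular, slowly-moving rim would dominate
  the error budget with a term unrelated to view sparsity.

What the generator does *not* emulate: noise (estimation runs on noiseless
analytic integrals, so results isolate interpolation error), fan-beam or
cone-beam geometry, detector blur, and truncated projections. Passing tests
therefore demonstrate the interpolation mechanism, not clinical
performance.

### Known limitation: crossing features

Where two moving features' traces intersect, their projections add and the
summed profile *morphs* rather than translates; per-bin value matching then
produces locally wrong displacements and errors on the order of the feature
amplitude over a few views. This is inherent to the method (any per-bin,
single-valued `u` shares it) and shows up as the displacement method's
maximum sinogram error being comparable to or slightly above linear's at 60
views even while its summed error and reconstruction RMSE are clearly the
best. The summary statistics in the package's experiment runner make the
trade-off visible rather than hiding it.

## Problem sizes and runtimes

The package's own studies use the full default conditions — 256-by-256
image, 367-bin detector, 360-degree acquisitions, 120-to-360 and 60-to-180
expansions — throughout the tests and the acceptance script; a full
four-method FBP comparison completes in a few seconds thanks to the
compiled projectors. The Landweber convergence study uses a 64-pixel disk
geometry (95 bins, 60 views, 1000 iterations), which exercises the identical
operator code at a size where a thousand matched projections remain
interactive. The oracle-equivalence property runs 200 random 16-bin rows
against a scalar double-loop reference.

## Reproducing the comparison

```r
library(sinodeform)
cfg <- experiment_config(views_measured = 120, views_target = 360,
                         out_dir = "results/ex120")
res <- run_experiment(cfg)
res$summary
```

The summary table carries one row per method (plus the raw under-sampled
reconstruction): sinogram max/sum absolute error against the analytic truth
and reconstruction RMSE against the rasterized phantom. `plot()` methods on
sinograms and reconstructions give quick visual checks; displacement fields
export to CSV for profile plots.
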