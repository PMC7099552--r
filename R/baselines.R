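#' Linear-convolution view-interpolation baselines
#'
#' Three classical ways to fill unmeasured views of a uniformly sampled
#' 360-degree sinogram, all of them linear operators on the measured data (in
#' contrast to displacement interpolation, which is not):
#'
#' * `copy_view_upsample()` — each missing view is a copy of its next
#'   measured neighbour (nearest-view substitution in the increasing-angle
#'   direction, wrapping at 360 degrees).
#' * `linear_upsample()` — each missing view at fraction `f` of a gap is the
#'   per-bin weighted average `(1 - f) * previous + f * next`; at factor 2
#'   this is the classic midpoint average of the two adjacent measured
#'   views.
#' * `sinc_upsample()` — per detector bin, the view-direction signal is
#'   treated as periodic over the full turn and upsampled by discrete-Fourier
#'   zero padding (band-limited sinc interpolation); measured samples are
#'   reproduced to floating-point accuracy.
#'
#' All three copy measured rows to their original angles unchanged.
#'
#' @param sino A [sinogram()] with uniformly spaced views over 360 degrees.
#' @param factor Integer upsampling factor, at least 2.
#' @return A [sinogram()] with `factor` times as many views.
#' @name baselines
NULL

#' @rdname baselines
#' @export
copy_view_upsample <- function(sino, factor) {
  next_row <- function(i1, i2, M) rep(list(sino$data[i2, ]), M)
  upsample_frame(sino, factor, next_row)
}

#' @rdname baselines
#' @export
linear_upsample <- function(sino, factor) {
  fill <- function(i1, i2, M) {
    a <- sino$data[i1, ]; b <- sino$data[i2, ]
    lapply(seq_len(M) / (M + 1), function(f) (1 - f) * a + f * b)
  }
  upsample_frame(sino, factor, fill)
}

#' @rdname baselines
#' @export
sinc_upsample <- function(sino, factor) {
  stopifnot(inherits(sino, "sinogram"))
  factor <- as.integer(factor)
  if (factor < 2L) stop("'factor' must be at least 2")
  g <- sino$geometry
  if (!is_uniform_360(g))
    stop("view angles must be uniformly spaced over 360 degrees")
  v <- nrow(sino$data)
  vf <- v * factor
  step_out <- 360 / vf
  if (g$angles[1L] >= step_out - 1e-9)
    stop("first view angle must be below the upsampled angular step")
  X <- stats::mvfft(sino$data)                 # per bin, along views
  Y <- matrix(0 + 0i, vf, g$n_bins)
  half <- v %/% 2L
  if (v %% 2L == 0L) {
    # even length: split the Nyquist coefficient between +/- frequencies so
    # the interpolant is real-valued
    Y[seq_len(half), ] <- X[seq_len(half), ]
    Y[half + 1L, ] <- X[half + 1L, ] / 2
    Y[vf - half + 1L, ] <- X[half + 1L, ] / 2
    if (half >= 2L)
      Y[(vf - half + 2L):vf, ] <- X[(half + 2L):v, ]
  } else {
    Y[seq_len(half + 1L), ] <- X[seq_len(half + 1L), ]
    if (half >= 1L)
      Y[(vf - half + 1L):vf, ] <- X[(half + 2L):v, ]
  }
  out <- Re(stats::mvfft(Y, inverse = TRUE)) * factor / vf
  geom <- ct_geometry(g$n_bins,
                      g$angles[1L] + (seq_len(vf) - 1L) * step_out,
                      g$bin_spacing, g$image_size)
  sinogram(out, geom, check_support = FALSE)
}
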