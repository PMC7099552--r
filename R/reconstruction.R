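# Discrete spatial-domain Ram-Lak (ramp) filter applied along detector rows.
# Kernel (bin spacing d): h[0] = 1/(4 d^2), h[k] = 0 for even k != 0,
# h[k] = -1/(pi^2 k^2 d^2) for odd k.  Defined in the spatial domain to avoid
# the DC bias of sampling the continuous frequency ramp.  The discrete
# convolution approximates the continuous filter as q = d * (p * h).
ramp_filter_rows <- function(data, bin_spacing) {
  nb <- ncol(data)
  L <- 2L^ceiling(log2(2L * nb))
  k <- seq_len(nb - 1L)
  h <- numeric(L)
  h[1L] <- 1 / (4 * bin_spacing^2)
  odd <- k[k %% 2L == 1L]
  h[1L + odd] <- -1 / (pi^2 * odd^2 * bin_spacing^2)
  h[L + 1L - odd] <- -1 / (pi^2 * odd^2 * bin_spacing^2)
  H <- stats::fft(h)
  padded <- cbind(data, matrix(0, nrow(data), L - nb))
  Q <- stats::mvfft(t(padded))
  q <- Re(stats::mvfft(Q * H, inverse = TRUE)) / L
  t(q)[, seq_len(nb), drop = FALSE] * bin_spacing
}

#' Filtered backprojection reconstruction
#'
#' Classic parallel-beam FBP: each view is ramp-filtered with the discrete
#' spatial-domain Ram-Lak kernel (no apodization window) and backprojected
#' pixel-wise with linear interpolation in the detector coordinate. Views
#' must be uniformly spaced over the full 360-degree turn; the angular
#' weighting `pi / n_views` averages the two redundant half-turns.
#'
#' @param sino A [sinogram()] with at least 2 uniformly spaced views over
#'   360 degrees and untruncated projections.
#' @param image_size Side length of the reconstruction grid in pixels;
#'   defaults to the geometry's `image_size`.
#' @return A [recon_image()].
#' @examples
#' g <- ct_geometry(95, seq(0, 354, by = 6), image_size = 64)
#' sino <- project_phantom(ellipse_phantom(0, 0, 20, 20, 0, 1), g)
#' rec <- fbp_reconstruct(sino)
#' mean(rec$data[29:36, 29:36])  # ~1 inside the disk
#' @export
fbp_reconstruct <- function(sino, image_size = NULL) {
  stopifnot(inherits(sino, "sinogram"))
  g <- sino$geometry
  if (is.null(image_size)) image_size <- g$image_size
  image_size <- as.integer(image_size)
  if (nrow(sino$data) < 2L)
    stop("FBP needs at least 2 views")
  if (!is_uniform_360(g))
    stop("view angles must be uniformly spaced over 360 degrees")
  q <- ramp_filter_rows(sino$data, g$bin_spacing)
  bp <- cpp_pixel_backproject(q, g$angles, image_size, g$bin_spacing)
  recon_image(bp * pi / nrow(sino$data), pixel_spacing = 1)
}

#' Matched projector / backprojector pair
#'
#' `forward_project()` computes discrete line integrals of an image with
#' Joseph's method (stepping each ray along its dominant image axis with
#' linear interpolation across the other); `back_project()` is its exact
#' transpose, so the pair satisfies the adjoint identity
#' `<A x, y> == <x, At y>` to rounding error. This is the system operator
#' used by [landweber_reconstruct()]. All lengths are in pixel units.
#'
#' @param img A [recon_image()].
#' @param geometry A [ct_geometry()] giving the view angles and detector.
#' @param sino A [sinogram()].
#' @param image_size Reconstruction grid side in pixels; defaults to the
#'   sinogram geometry's `image_size`.
#' @return `forward_project()` a [sinogram()]; `back_project()` a
#'   [recon_image()].
#' @export
forward_project <- function(img, geometry) {
  stopifnot(inherits(img, "recon_image"), inherits(geometry, "ct_geometry"))
  p <- cpp_joseph_forward(img$data, geometry$angles, geometry$n_bins,
                          geometry$bin_spacing)
  sinogram(p, geometry, check_support = FALSE)
}

#' @rdname forward_project
#' @export
back_project <- function(sino, image_size = NULL) {
  stopifnot(inherits(sino, "sinogram"))
  g <- sino$geometry
  if (is.null(image_size)) image_size <- g$image_size
  b <- cpp_joseph_backward(sino$data, g$angles, as.integer(image_size),
                           g$bin_spacing)
  recon_image(b, pixel_spacing = 1)
}

#' Landweber iteration settings
#'
#' @param alpha Relaxation parameter (step size) of the Landweber update,
#'   applied to the system operator expressed on the unit-radius field of
#'   view (see [landweber_reconstruct()]). Default 0.01. Must satisfy
#'   `alpha < 2 / sigma_max^2` of that operator for convergence; the
#'   iteration monitors the residual and warns when it grows, which is the
#'   empirical signature of a violated bound.
#' @param iterations Number of iterations to run.
#' @return An object of class `landweber_config`.
#' @export
landweber_config <- function(alpha = 0.01, iterations = 1000L) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0)
  iterations <- as.integer(iterations)
  stopifnot(iterations >= 1L)
  structure(list(alpha = alpha, iterations = iterations),
            class = "landweber_config")
}

#' Landweber iterative reconstruction
#'
#' Gradient-descent-type iteration
#' `X_(k+1) = X_k + alpha * At (P - A X_k)` with the matched Joseph pair as
#' `A` / `At`. The system is expressed on the unit-radius field of view:
#' lengths are scaled by `c = 2 / image_size` per pixel, so `A_fov = c * A`
#' and `P_fov = c * P`, which leaves the least-squares solution unchanged
#' while keeping the spectral norm of the operator of order one — there the
#' default relaxation `alpha = 0.01` sits safely below the classical
#' convergence bound `2 / sigma_max^2` for the geometries this package
#' targets. Equivalently, the update applied to the pixel-unit operator uses
#' the effective step `alpha * c^2`.
#'
#' The per-iteration residual `||A_fov X - P_fov||` (Frobenius norm) is
#' recorded in the result's `residuals` attribute; growth over 10 consecutive
#' iterations triggers a step-size warning instead of being silently
#' accepted.
#'
#' @param sino A [sinogram()]; the measured (or interpolated) data `P`.
#' @param config A [landweber_config()].
#' @param initial Optional starting [recon_image()]; defaults to zero.
#' @return A [recon_image()] with attribute `residuals` (numeric vector,
#'   one value per iteration).
#' @export
landweber_reconstruct <- function(sino, config = landweber_config(),
                                  initial = NULL) {
  stopifnot(inherits(sino, "sinogram"), inherits(config, "landweber_config"))
  g <- sino$geometry
  S <- g$image_size
  X <- if (is.null(initial)) matrix(0, S, S) else {
    stopifnot(inherits(initial, "recon_image"), nrow(initial$data) == S)
    initial$data
  }
  cs <- 2 / S                      # pixel -> unit-radius FOV length scale
  step <- config$alpha * cs^2
  P <- sino$data
  residuals <- numeric(config$iterations)
  grow <- 0L
  for (k in seq_len(config$iterations)) {
    R <- P - cpp_joseph_forward(X, g$angles, g$n_bins, g$bin_spacing)
    residuals[k] <- cs * sqrt(sum(R^2))
    X <- X + step * cpp_joseph_backward(R, g$angles, S, g$bin_spacing)
    if (k > 1L && residuals[k] > residuals[k - 1L]) {
      grow <- grow + 1L
      if (grow >= 10L) {
        warning("Landweber residual grew over 10 consecutive iterations; ",
                "relaxation parameter likely exceeds the stability bound")
        grow <- 0L
      }
    } else grow <- 0L
  }
  out <- recon_image(X, pixel_spacing = 1)
  attr(out, "residuals") <- residuals
  out
}

#' Residual history of a Landweber reconstruction
#'
#' @param img A [recon_image()] returned by [landweber_reconstruct()].
#' @return Data frame with columns `iteration` and `residual`.
#' @export
residual_history <- function(img) {
  r <- attr(img, "residuals")
  if (is.null(r)) stop("no residual history attached to this image")
  data.frame(iteration = seq_along(r), residual = r)
}
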