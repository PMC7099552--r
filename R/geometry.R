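#' Parallel-beam acquisition geometry
#'
#' Describes a parallel-beam detector and the set of view angles at which
#' projections are (or will be) taken. The detector has `n_bins` bins spaced
#' `bin_spacing` apart; the radial coordinate of bin `n` (1-based) is
#' `t = (n - (n_bins + 1)/2) * bin_spacing`, so the detector is centered on the
#' rotation axis. All lengths are in pixel units of the reconstruction grid
#' (one pixel = one unit).
#'
#' By default the detector exactly spans the diagonal of the image square
#' (`bin_spacing = image_size * sqrt(2) / n_bins`), so that the field-of-view
#' circle inscribed in the image square always projects strictly inside the
#' detector and projections are untruncated.
#'
#' @param n_bins Number of detector bins per view (positive integer).
#' @param angles View angles in degrees, strictly increasing, within
#'   `[0, 360)`.
#' @param bin_spacing Detector bin spacing in pixel units. Default spans the
#'   image diagonal.
#' @param image_size Side length of the square reconstruction grid in pixels.
#' @return An object of class `ct_geometry`.
#' @examples
#' g <- ct_geometry(367, seq(0, 359, by = 1))
#' g$bin_spacing
#' @export
ct_geometry <- function(n_bins, angles, bin_spacing = NULL,
                        image_size = 256L) {
  n_bins <- as.integer(n_bins)
  image_size <- as.integer(image_size)
  stopifnot(length(n_bins) == 1L, n_bins >= 1L,
            length(image_size) == 1L, image_size >= 2L)
  angles <- as.numeric(angles)
  if (length(angles) < 1L || any(!is.finite(angles)))
    stop("'angles' must be finite view angles in degrees")
  if (any(diff(angles) <= 0))
    stop("'angles' must be strictly increasing")
  if (angles[1L] < 0 || angles[length(angles)] >= 360)
    stop("'angles' must lie in [0, 360)")
  if (is.null(bin_spacing))
    bin_spacing <- image_size * sqrt(2) / n_bins
  stopifnot(is.numeric(bin_spacing), length(bin_spacing) == 1L,
            bin_spacing > 0)
  if (n_bins * bin_spacing < image_size)
    stop("detector (n_bins * bin_spacing) too short to cover the field of view")
  structure(list(n_bins = n_bins, bin_spacing = as.numeric(bin_spacing),
                 angles = angles, image_size = image_size),
            class = "ct_geometry")
}

#' @export
print.ct_geometry <- function(x, ...) {
  d <- diff(x$angles)
  sp <- if (length(d)) {
    if (max(d) - min(d) < 1e-9) sprintf("uniform %.4g deg", d[1L]) else "non-uniform"
  } else "single view"
  cat(sprintf("<ct_geometry> %d views (%s), %d bins x %.6g px, image %d x %d\n",
              length(x$angles), sp, x$n_bins, x$bin_spacing,
              x$image_size, x$image_size))
  invisible(x)
}

#' Radial detector coordinates of a geometry
#'
#' @param geometry A [ct_geometry()].
#' @return Numeric vector of length `n_bins`: the signed radial coordinate of
#'   each bin center.
#' @export
detector_coords <- function(geometry) {
  stopifnot(inherits(geometry, "ct_geometry"))
  (seq_len(geometry$n_bins) - (geometry$n_bins + 1) / 2) * geometry$bin_spacing
}

# TRUE when view angles are uniformly spaced over the full turn, i.e.
# angles = a0 + (0:(V-1)) * 360/V.  Displacement/baseline upsampling and FBP
# rely on this (the final interpolation gap wraps 360-degree periodically).
is_uniform_360 <- function(geometry, tol = 1e-6) {
  a <- geometry$angles
  v <- length(a)
  if (v < 2L) return(FALSE)
  step <- 360 / v
  all(abs(diff(a) - step) < tol)
}

uniform_step <- function(geometry) 360 / length(geometry$angles)
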