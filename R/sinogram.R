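#' Sinogram container
#'
#' A sinogram is a matrix of line integrals `p[view, bin]` together with its
#' acquisition geometry. Rows are views (one per angle in
#' `geometry$angles`), columns are detector bins.
#'
#' For valid (untruncated) data the object's support lies strictly inside the
#' detector, so the first and last bins of every view are essentially zero;
#' a warning is emitted otherwise because the displacement estimator and the
#' ramp filter both assume a zero boundary.
#'
#' @param data Numeric matrix, `length(geometry$angles) x geometry$n_bins`.
#' @param geometry A [ct_geometry()].
#' @param check_support Warn when edge bins carry signal. Default `TRUE`.
#' @return An object of class `sinogram` with elements `data` and `geometry`.
#' @export
sinogram <- function(data, geometry, check_support = TRUE) {
  stopifnot(inherits(geometry, "ct_geometry"))
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (nrow(data) != length(geometry$angles))
    stop("sinogram row count must equal the number of view angles")
  if (ncol(data) != geometry$n_bins)
    stop("sinogram column count must equal geometry$n_bins")
  if (any(!is.finite(data))) stop("sinogram values must be finite")
  if (check_support && ncol(data) >= 2L) {
    edge <- max(abs(data[, c(1L, ncol(data))]))
    peak <- max(abs(data))
    if (peak > 0 && edge > 1e-6 * peak)
      warning("sinogram carries signal in its edge bins; ",
              "projections may be truncated")
  }
  structure(list(data = data, geometry = geometry), class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("<sinogram> %d views x %d bins, range [%.4g, %.4g]\n",
              nrow(x$data), ncol(x$data), min(x$data), max(x$data)))
  print(x$geometry)
  invisible(x)
}

#' @export
dim.sinogram <- function(x) dim(x$data)

#' Display a sinogram or reconstruction
#'
#' Grey-level display via [graphics::image()]; views run along the vertical
#' axis for sinograms.
#'
#' @param x A `sinogram` or `recon_image`.
#' @param main Plot title.
#' @param ... Passed on to [graphics::image()].
#' @return Invisibly, `x`.
#' @export
plot.sinogram <- function(x, main = "sinogram", ...) {
  z <- t(x$data[rev(seq_len(nrow(x$data))), , drop = FALSE])
  graphics::image(z, col = grDevices::gray.colors(256), axes = FALSE,
                  main = main, xlab = "detector bin", ylab = "view", ...)
  invisible(x)
}

#' Reconstruction image container
#'
#' A square pixel grid comparable to the rasterized phantom: row 1 is the top
#' of the image, the grid is centered on the rotation axis.
#'
#' @param data Square numeric matrix of pixel values.
#' @param pixel_spacing Length per pixel (pixel units; default 1).
#' @return An object of class `recon_image`.
#' @export
recon_image <- function(data, pixel_spacing = 1) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (nrow(data) != ncol(data)) stop("reconstruction image must be square")
  if (any(!is.finite(data))) stop("image values must be finite")
  stopifnot(is.numeric(pixel_spacing), pixel_spacing > 0)
  structure(list(data = data, pixel_spacing = as.numeric(pixel_spacing)),
            class = "recon_image")
}

#' @export
print.recon_image <- function(x, ...) {
  cat(sprintf("<recon_image> %d x %d px, range [%.4g, %.4g]\n",
              nrow(x$data), ncol(x$data), min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.recon_image <- function(x) dim(x$data)

#' @rdname plot.sinogram
#' @export
plot.recon_image <- function(x, main = "reconstruction", ...) {
  z <- t(x$data[rev(seq_len(nrow(x$data))), , drop = FALSE])
  graphics::image(z, col = grDevices::gray.colors(256), axes = FALSE,
                  main = main, asp = 1, ...)
  invisible(x)
}

#' Keep a subset of views
#'
#' Extracts the sinogram restricted to the given view indices (e.g. every
#' third view to emulate sparse acquisition).
#'
#' @param sino A [sinogram()].
#' @param views Integer vector of view indices to keep (1-based, increasing).
#' @return A [sinogram()] with the reduced geometry.
#' @examples
#' # keep 120 of 360 views
#' # sub <- subsample_views(full, seq(1, 360, by = 3))
#' @export
subsample_views <- function(sino, views) {
  stopifnot(inherits(sino, "sinogram"))
  views <- as.integer(views)
  if (any(views < 1L) || any(views > nrow(sino$data)) || any(diff(views) <= 0))
    stop("'views' must be increasing indices into the measured views")
  g <- sino$geometry
  geom <- ct_geometry(g$n_bins, g$angles[views], g$bin_spacing, g$image_size)
  sinogram(sino$data[views, , drop = FALSE], geom, check_support = FALSE)
}
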