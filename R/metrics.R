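#' Root mean square error between a reconstruction and the truth
#'
#' `sqrt(mean((R - T)^2))` over all pixels, with no registration or intensity
#' normalization: both images must live on the identical centered grid (as
#' [fbp_reconstruct()] and [rasterize_phantom()] guarantee).
#'
#' @param recon,truth [recon_image()] objects (or plain matrices) of the same
#'   shape.
#' @return A single non-negative number; zero iff the inputs are identical.
#' @examples
#' rmse(recon_image(matrix(c(1, 2, 0, 0), 2)),
#'      recon_image(matrix(0, 2, 2)))  # sqrt(5/4)
#' @export
rmse <- function(recon, truth) {
  a <- if (inherits(recon, "recon_image")) recon$data else as.matrix(recon)
  b <- if (inherits(truth, "recon_image")) truth$data else as.matrix(truth)
  if (!identical(dim(a), dim(b))) stop("images must have the same shape")
  sqrt(mean((a - b)^2))
}

#' Absolute-error statistics between an estimated and a true sinogram
#'
#' Computes the absolute-error map `|estimated - truth|` over the full
#' expanded sinogram and summarizes it by its maximum and sum (plus the RMSE
#' for convenience). Statistics run over all entries, measured views
#' included — interpolators that copy measured views bit-exactly contribute
#' zero there, so the statistics isolate the estimation error.
#'
#' @param estimated,truth [sinogram()] objects of identical shape.
#' @param measured_view_mask Optional logical vector marking which views of
#'   the expanded sinogram were originally measured; stored in the report
#'   (and used for the per-subset breakdown) but does not change the summary
#'   statistics.
#' @return An object of class `error_report`: list with `rmse`,
#'   `max_abs_error`, `sum_abs_error`, `error_map` (matrix) and
#'   `measured_view_mask`.
#' @export
sinogram_error_report <- function(estimated, truth,
                                  measured_view_mask = NULL) {
  a <- if (inherits(estimated, "sinogram")) estimated$data else as.matrix(estimated)
  b <- if (inherits(truth, "sinogram")) truth$data else as.matrix(truth)
  if (!identical(dim(a), dim(b))) stop("sinograms must have the same shape")
  if (!is.null(measured_view_mask)) {
    measured_view_mask <- as.logical(measured_view_mask)
    if (length(measured_view_mask) != nrow(a))
      stop("'measured_view_mask' must have one entry per view")
  }
  em <- abs(a - b)
  structure(list(rmse = sqrt(mean((a - b)^2)),
                 max_abs_error = max(em),
                 sum_abs_error = sum(em),
                 error_map = em,
                 measured_view_mask = measured_view_mask),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("<error_report> rmse %.6g | max abs %.6g | sum abs %.6g\n",
              x$rmse, x$max_abs_error, x$sum_abs_error))
  invisible(x)
}

#' Shannon view-count requirement
#'
#' The sampling criterion for tomography: the number of views over 180
#' degrees should approximately equal `d_min`, the number of detector bins
#' needed to cover the object at one view. Over a full 360-degree turn the
#' requirement doubles.
#'
#' @param d_min Minimum number of detector bins covering the object
#'   (positive integer).
#' @param arc_degrees Angular coverage of the acquisition: 180 or 360.
#' @return Required number of views (integer).
#' @examples
#' shannon_required_views(896, 360) / 400  # 4.48x undersampled acquisition
#' @export
shannon_required_views <- function(d_min, arc_degrees = 180) {
  d_min <- as.integer(d_min)
  stopifnot(length(d_min) == 1L, d_min >= 1L)
  if (!arc_degrees %in% c(180, 360))
    stop("'arc_degrees' must be 180 or 360")
  if (arc_degrees == 180) d_min else 2L * d_min
}
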