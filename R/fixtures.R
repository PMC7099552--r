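#' Test-surface sinogram fixtures with known ground truth
#'
#' Generates small synthetic sinograms whose inter-view displacement is known
#' analytically, for validating the displacement estimator and the
#' interpolation error bounds:
#'
#' * `"shifted_bump"` — every view is the same compactly supported Gaussian
#'   profile, translated by a fixed integer `shift` bins per view. The
#'   ground-truth displacement deforming view `m` into view `m + 1` is the
#'   constant field `-shift`. (Not a physically consistent sinogram; a pure
#'   estimator test surface.)
#' * `"translating_dot"` — a small off-center disk projected analytically;
#'   its sinogram trace is the sinusoid `t(theta) = r cos(theta - theta0)`
#'   in the radial coordinate, giving a smoothly varying, physically exact
#'   displacement test case.
#' * `"default_phantom"` — the package's [default_phantom()] projected at
#'   the default geometry, with its spec file and ground-truth raster.
#'
#' @param kind One of `"shifted_bump"`, `"translating_dot"`,
#'   `"default_phantom"`.
#' @param out_dir Directory to write files into, or `NULL` to only return
#'   the objects.
#' @param n_bins,n_views Fixture sinogram size.
#' @param shift Integer bins of translation per view (`shifted_bump`).
#' @param sigma Gaussian profile width in bins (`shifted_bump`).
#' @param dot_radius_px,orbit_radius_px,theta0 Dot size, orbit radius and
#'   starting angle in degrees (`translating_dot`).
#' @param image_size Image side for `default_phantom`.
#' @return Invisibly, a list with the `sinogram` and kind-specific ground
#'   truth (`displacement` data frame for `shifted_bump`, `trace` data frame
#'   for `translating_dot`, `phantom` and `truth` for `default_phantom`).
#' @export
generate_fixtures <- function(kind = c("shifted_bump", "translating_dot",
                                       "default_phantom"),
                              out_dir = NULL,
                              n_bins = 64L, n_views = 8L, shift = 3L,
                              sigma = 2, dot_radius_px = 2,
                              orbit_radius_px = 50, theta0 = 0,
                              image_size = 256L) {
  kind <- match.arg(kind)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  res <- switch(kind,
    shifted_bump = {
      n_bins <- as.integer(n_bins); n_views <- as.integer(n_views)
      shift <- as.integer(shift)
      geom <- ct_geometry(n_bins, (seq_len(n_views) - 1L) * 360 / n_views,
                          bin_spacing = 1, image_size = n_bins %/% 2L)
      profile <- function(x) exp(-x^2 / (2 * sigma^2))
      center0 <- n_bins / 4
      rows <- t(vapply(seq_len(n_views) - 1L, function(v)
        profile(seq_len(n_bins) - center0 - v * shift), numeric(n_bins)))
      truth <- data.frame(n = seq_len(n_bins), u = -shift)
      list(sinogram = sinogram(rows, geom, check_support = FALSE),
           displacement = truth)
    },
    translating_dot = {
      geom <- ct_geometry(n_bins = 367L,
                          (seq_len(n_views) - 1L) * 360 / n_views,
                          image_size = image_size)
      th0 <- theta0 * pi / 180
      ph <- ellipse_phantom(orbit_radius_px * cos(th0),
                            orbit_radius_px * sin(th0),
                            dot_radius_px, dot_radius_px, 0, 1)
      sino <- project_phantom(ph, geom)
      th <- geom$angles * pi / 180
      trace <- data.frame(view = seq_along(th), angle = geom$angles,
                          center_t = orbit_radius_px * cos(th - th0))
      list(sinogram = sino, trace = trace, phantom = ph)
    },
    default_phantom = {
      geom <- ct_geometry(367L, seq_len(360L) - 1L, image_size = image_size)
      ph <- default_phantom(image_size)
      list(sinogram = project_phantom(ph, geom), phantom = ph,
           truth = rasterize_phantom(ph, geom))
    })
  if (!is.null(out_dir)) {
    write_sinogram(res$sinogram, file.path(out_dir,
                                           paste0(kind, "_sino.tif")))
    if (!is.null(res$displacement))
      utils::write.csv(res$displacement,
                       file.path(out_dir, paste0(kind, "_displacement.csv")),
                       row.names = FALSE)
    if (!is.null(res$trace))
      utils::write.csv(res$trace,
                       file.path(out_dir, paste0(kind, "_trace.csv")),
                       row.names = FALSE)
    if (!is.null(res$phantom))
      write_phantom(res$phantom,
                    file.path(out_dir, paste0(kind, "_phantom.txt")))
    if (!is.null(res$truth))
      write_image(res$truth, file.path(out_dir, paste0(kind, "_truth.tif")))
  }
  invisible(res)
}
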