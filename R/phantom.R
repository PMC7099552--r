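#' Ellipse phantoms
#'
#' An ellipse phantom is a list of constant-density ellipses; densities are
#' additive where ellipses overlap. It defines both a ground-truth raster
#' image ([rasterize_phantom()]) and an exact analytic parallel-beam sinogram
#' ([project_phantom()]), so simulation studies have a noiseless reference at
#' machine precision.
#'
#' Coordinates are in pixel units with the origin at the center of the image
#' square, x to the right and y upwards. Every ellipse must fit inside the
#' field-of-view circle inscribed in the image square (radius
#' `image_size / 2`); this guarantees untruncated projections, which the
#' displacement estimator's zero-boundary rule assumes.
#'
#' @param cx,cy Ellipse center coordinates (pixel units, origin at image
#'   center).
#' @param a,b Semiaxes along the ellipse's own x/y axes before rotation;
#'   strictly positive.
#' @param phi Counter-clockwise rotation angle of the ellipse in degrees.
#' @param rho Additive density; may be negative.
#' @return An object of class `ellipse_phantom`: a data frame with columns
#'   `cx, cy, a, b, phi, rho`, one row per ellipse.
#' @seealso [default_phantom()], [project_phantom()], [rasterize_phantom()]
#' @examples
#' ph <- ellipse_phantom(cx = 0, cy = 0, a = 40, b = 60, phi = 0, rho = 1)
#' @export
ellipse_phantom <- function(cx, cy, a, b, phi, rho) {
  df <- data.frame(cx = as.numeric(cx), cy = as.numeric(cy),
                   a = as.numeric(a), b = as.numeric(b),
                   phi = as.numeric(phi), rho = as.numeric(rho))
  if (nrow(df) > 0 && any(!is.finite(as.matrix(df))))
    stop("phantom parameters must be finite")
  if (any(df$a <= 0) || any(df$b <= 0))
    stop("semiaxes 'a' and 'b' must be strictly positive")
  class(df) <- c("ellipse_phantom", "data.frame")
  df
}

#' @export
print.ellipse_phantom <- function(x, ...) {
  cat(sprintf("<ellipse_phantom> %d ellipse(s)\n", nrow(x)))
  print.data.frame(x, row.names = FALSE, digits = 5)
  invisible(x)
}

# Conservative containment check: an ellipse fits inside the FOV circle of
# radius R if |center| + max(a, b) <= R.  Sufficient, not necessary; keeps
# validation independent of the rotation angle.
phantom_in_fov <- function(phantom, image_size) {
  if (nrow(phantom) == 0L) return(TRUE)
  r <- sqrt(phantom$cx^2 + phantom$cy^2) + pmax(phantom$a, phantom$b)
  all(r <= image_size / 2 + 1e-9)
}

#' Default soft-tissue phantom with diagnostic dot pairs
#'
#' A deterministic, versioned phantom used throughout the package's
#' simulation studies: a large uniform body ellipse (density 0.25) with four
#' moderate-contrast internal structures, plus two pairs of small black/white
#' (negative/positive density) marker dots — an adjacent doublet at the image
#' center and one near the bottom periphery. The markers are high-contrast
#' point probes, an order of magnitude above the body density, in the style
#' of ball-bearing QA markers; each pair is a tight doublet whose projection
#' translates as a near-rigid dipole through the rotation. They make
#' view-interpolation blur and rotation artifacts directly measurable: the
#' peripheral pair moves several detector bins per angular gap and degrades
#' first, while the central pair barely moves and acts as the well-resolved
#' control. The body and internal structures keep smooth, soft-tissue-like
#' view profiles.
#'
#' @param image_size Image side length in pixels the phantom is scaled to.
#' @return An [ellipse_phantom()].
#' @examples
#' ph <- default_phantom()
#' nrow(ph)
#' @export
default_phantom <- function(image_size = 256L) {
  s <- image_size / 2
  e <- data.frame(
    cx  = c(0, -0.30, 0.28, 0.05, -0.15, -0.035, 0.035, 0.125, 0.195),
    cy  = c(0, 0.20, 0.15, 0.50, -0.40, 0, 0, -0.605, -0.605),
    a   = c(0.90, 0.18, 0.15, 0.25, 0.10, 0.0275, 0.0275, 0.0275, 0.0275),
    b   = c(0.95, 0.30, 0.28, 0.12, 0.14, 0.0275, 0.0275, 0.0275, 0.0275),
    phi = c(0, 20, -15, 0, -30, 0, 0, 0, 0),
    rho = c(0.25, -0.12, 0.15, 0.10, 0.15, 1, -1, 3, -3))
  ellipse_phantom(e$cx * s, e$cy * s, e$a * s, e$b * s, e$phi, e$rho)
}

#' Analytic parallel-beam projection of an ellipse phantom
#'
#' Computes the exact Radon transform of the phantom at every (view, bin) of
#' the geometry. For an ellipse with semiaxes `a`, `b`, rotation `phi` and
#' density `rho`, a ray at view angle `theta` and signed radial offset `t'`
#' from the ellipse center contributes
#' `2 * rho * a * b * sqrt(s2 - t'^2) / s2` where
#' `s2 = a^2 cos^2(theta - phi) + b^2 sin^2(theta - phi)`, and zero when
#' `t'^2 > s2` (ray misses the ellipse). Contributions are additive over
#' ellipses. No noise is added.
#'
#' @param phantom An [ellipse_phantom()].
#' @param geometry A [ct_geometry()]. The phantom must lie inside the
#'   geometry's field-of-view circle (untruncated projections).
#' @return A [sinogram()] of dimension `length(angles) x n_bins`.
#' @examples
#' g <- ct_geometry(65, seq(0, 350, by = 10), image_size = 64)
#' sino <- project_phantom(ellipse_phantom(0, 0, 20, 20, 0, 1), g)
#' max(sino$data)  # central chord of a disk: 2 * rho * r = 40
#' @export
project_phantom <- function(phantom, geometry) {
  stopifnot(inherits(phantom, "ellipse_phantom"),
            inherits(geometry, "ct_geometry"))
  if (!phantom_in_fov(phantom, geometry$image_size))
    stop("phantom extends beyond the field-of-view circle; ",
         "projections would be truncated")
  t <- detector_coords(geometry)
  th <- geometry$angles * pi / 180
  p <- matrix(0, nrow = length(th), ncol = geometry$n_bins)
  for (k in seq_len(nrow(phantom))) {
    e <- phantom[k, ]
    ang <- th - e$phi * pi / 180
    s2 <- e$a^2 * cos(ang)^2 + e$b^2 * sin(ang)^2          # per view
    tc <- e$cx * cos(th) + e$cy * sin(th)                  # center offset per view
    tp <- outer(-tc, t, `+`)                               # t' = t - tc
    d2 <- sweep(-tp^2, 1, s2, `+`)                         # s2 - t'^2
    d2[d2 < 0] <- 0
    p <- p + 2 * e$rho * e$a * e$b * sweep(sqrt(d2), 1, s2, `/`)
  }
  sinogram(p, geometry)
}

#' Rasterize an ellipse phantom to a ground-truth image
#'
#' Point-samples the phantom at pixel centers: each pixel value is the sum of
#' densities of the ellipses containing its center. No anti-aliasing is
#' applied, so the raster is deterministic for a fixed geometry.
#'
#' @inheritParams project_phantom
#' @return A [recon_image()] of side `geometry$image_size`.
#' @export
rasterize_phantom <- function(phantom, geometry) {
  stopifnot(inherits(phantom, "ellipse_phantom"),
            inherits(geometry, "ct_geometry"))
  n <- geometry$image_size
  # pixel centers: x right, y up; row 1 is the top of the image
  x <- (seq_len(n) - (n + 1) / 2)
  y <- rev(x)
  X <- matrix(x, n, n, byrow = TRUE)
  Y <- matrix(y, n, n)
  img <- matrix(0, n, n)
  for (k in seq_len(nrow(phantom))) {
    e <- phantom[k, ]
    c_ <- cos(e$phi * pi / 180); s_ <- sin(e$phi * pi / 180)
    xr <- (X - e$cx) * c_ + (Y - e$cy) * s_
    yr <- -(X - e$cx) * s_ + (Y - e$cy) * c_
    inside <- (xr / e$a)^2 + (yr / e$b)^2 <= 1
    img <- img + e$rho * inside
  }
  recon_image(img, pixel_spacing = 1)
}

#' Total analytic mass of a phantom
#'
#' Sum over ellipses of `pi * a * b * rho`; equals (up to discretization) the
#' integral of every projection view, which the test-suite uses as a
#' mass-conservation check on [project_phantom()].
#'
#' @param phantom An [ellipse_phantom()].
#' @return A single number.
#' @export
phantom_mass <- function(phantom) {
  stopifnot(inherits(phantom, "ellipse_phantom"))
  sum(pi * phantom$a * phantom$b * phantom$rho)
}

#' Read / write ellipse phantom specifications
#'
#' Plain whitespace-separated text, one ellipse per row with a header line
#' `cx cy a b phi rho`.
#'
#' @param path File path.
#' @param phantom An [ellipse_phantom()].
#' @return `read_phantom` returns an [ellipse_phantom()]; `write_phantom`
#'   returns `path` invisibly.
#' @export
write_phantom <- function(phantom, path) {
  stopifnot(inherits(phantom, "ellipse_phantom"))
  utils::write.table(as.data.frame(phantom), path, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(path) {
  df <- utils::read.table(path, header = TRUE)
  ellipse_phantom(df$cx, df$cy, df$a, df$b, df$phi, df$rho)
}
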