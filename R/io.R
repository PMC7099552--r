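# File formats: 32-bit float single-page TIFF for arrays (sinograms, images,
# error maps), a YAML sidecar ("<file>.geom") for geometry, CSV for tabular
# outputs.  Reading goes through tiff::readTIFF, which returns float samples
# verbatim; writing uses a minimal single-strip float32 writer because the
# installed TIFF writer has no floating-point sample format.

write_float_tiff <- function(m, path) {
  m <- as.matrix(m)
  h <- nrow(m); w <- ncol(m)
  payload <- as.numeric(t(m))            # TIFF is row-major
  nbytes <- 4L * h * w
  con <- file(path, "wb")
  on.exit(close(con))
  wr2 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  wr4 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  # header: little-endian magic, IFD placed after the pixel data
  writeBin(charToRaw("II"), con)
  wr2(42L)
  wr4(8L + nbytes)
  writeBin(payload, con, size = 4L, endian = "little")
  entry <- function(tag, type, count, value) {
    wr2(tag); wr2(type); wr4(count)
    if (type == 3L) { wr2(value); wr2(0L) } else wr4(value)
  }
  wr2(10L)                               # entry count
  entry(256L, 4L, 1L, w)                 # ImageWidth
  entry(257L, 4L, 1L, h)                 # ImageLength
  entry(258L, 3L, 1L, 32L)               # BitsPerSample
  entry(259L, 3L, 1L, 1L)                # Compression: none
  entry(262L, 3L, 1L, 1L)                # Photometric: BlackIsZero
  entry(273L, 4L, 1L, 8L)                # StripOffsets
  entry(277L, 3L, 1L, 1L)                # SamplesPerPixel
  entry(278L, 4L, 1L, h)                 # RowsPerStrip
  entry(279L, 4L, 1L, nbytes)            # StripByteCounts
  entry(339L, 3L, 1L, 3L)                # SampleFormat: IEEE float
  wr4(0L)                                # no further IFD
  invisible(path)
}

read_float_tiff <- function(path) {
  m <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(m)) != 2L)
    stop("expected a single-channel single-page TIFF: ", path)
  m
}

sidecar_path <- function(path) paste0(path, ".geom")

#' Read and write sinograms and images as float TIFF
#'
#' Arrays are stored as 32-bit float single-page TIFF; the acquisition
#' geometry (or pixel spacing) travels in a small YAML sidecar named
#' `<file>.geom`. Values round-trip exactly at float32 precision.
#'
#' @param sino A [sinogram()].
#' @param img A [recon_image()].
#' @param path TIFF file path.
#' @return Readers return the reconstructed object; writers return `path`
#'   invisibly.
#' @export
write_sinogram <- function(sino, path) {
  stopifnot(inherits(sino, "sinogram"))
  write_float_tiff(sino$data, path)
  g <- sino$geometry
  yaml::write_yaml(list(kind = "sinogram", n_bins = g$n_bins,
                        bin_spacing = g$bin_spacing, angles = g$angles,
                        image_size = g$image_size),
                   sidecar_path(path))
  invisible(path)
}

#' @rdname write_sinogram
#' @export
read_sinogram <- function(path) {
  meta <- yaml::read_yaml(sidecar_path(path))
  geom <- ct_geometry(meta$n_bins, meta$angles, meta$bin_spacing,
                      meta$image_size)
  sinogram(read_float_tiff(path), geom, check_support = FALSE)
}

#' @rdname write_sinogram
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "recon_image"))
  write_float_tiff(img$data, path)
  yaml::write_yaml(list(kind = "image", pixel_spacing = img$pixel_spacing),
                   sidecar_path(path))
  invisible(path)
}

#' @rdname write_sinogram
#' @export
read_image <- function(path) {
  meta <- yaml::read_yaml(sidecar_path(path))
  recon_image(read_float_tiff(path), meta$pixel_spacing)
}

#' Export a displacement field as CSV
#'
#' Two columns, `n` (detector bin, 1-based) and `u` (integer displacement),
#' suitable for line plots of the displacement function.
#'
#' @param field A `displacement_field` as returned by
#'   [estimate_displacement()].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_displacement_csv <- function(field, path) {
  stopifnot(inherits(field, "displacement_field"))
  utils::write.csv(data.frame(n = seq_along(field$u), u = field$u),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_displacement_csv
#' @export
read_displacement_csv <- function(path) {
  df <- utils::read.csv(path)
  df$u <- as.integer(df$u)
  df
}
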