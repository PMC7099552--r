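# Shared builders for small synthetic test inputs.

# Uniform full-turn geometry with n_views views.
tiny_geometry <- function(n_bins, n_views,
                          image_size = max(4L, min(n_bins, n_bins %/% 2L)),
                          bin_spacing = 1) {
  ct_geometry(n_bins, (seq_len(n_views) - 1L) * 360 / n_views,
              bin_spacing = bin_spacing, image_size = image_size)
}

# Sinogram whose rows are a Gaussian profile translated by `shift` bins per
# view: ground-truth displacement between consecutive rows is -shift.
bump_sinogram <- function(n_bins = 64L, n_views = 4L, shift = 3L,
                          sigma = 2, center = n_bins / 4) {
  geom <- tiny_geometry(n_bins, n_views)
  rows <- t(vapply(seq_len(n_views) - 1L, function(v)
    exp(-(seq_len(n_bins) - center - v * shift)^2 / (2 * sigma^2)),
    numeric(n_bins)))
  sinogram(rows, geom, check_support = FALSE)
}

# Independent scalar-loop displacement search: the oracle the vectorized
# estimator is checked against.  Mirrors the documented semantics directly:
# joint unit-peak normalization, then per-(n, u) objective_value(), ties to
# the first candidate in (0, -1, +1, -2, +2, ...) order.
naive_displacement <- function(target_row, source_row, config) {
  peak <- max(abs(target_row), abs(source_row))
  if (peak > 0) {
    target_row <- target_row / peak
    source_row <- source_row / peak
  }
  N <- config$search_radius
  cands <- c(0L, as.integer(rbind(-seq_len(N), seq_len(N))))
  vapply(seq_along(target_row), function(n) {
    f <- vapply(cands, function(u)
      objective_value(target_row, source_row, n, u, config), numeric(1))
    cands[which.min(f)]
  }, integer(1))
}

expect_sinogram_equal <- function(a, b, tol = 0) {
  if (tol == 0) expect_identical(a$data, b$data)
  else expect_lt(max(abs(a$data - b$data)), tol)
}
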