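test_that("objective value reproduces hand-computed cases", {
  cfg <- interp_config()
  row <- c(0, 1, 2, 1, 0)
  expect_equal(objective_value(row, row, 3L, 0L, cfg), 0)

  cfg0 <- interp_config(lambda = 0)
  expect_equal(objective_value(c(0, 0, 3), c(0, 0, 1), 3L, 0L, cfg0), 4)

  # data term (2-1)^2 = 1; slope signs +1 vs -1 give 0.01 * 4 = 0.04
  expect_equal(objective_value(c(0, 1, 2), c(0, 2, 1), 3L, 0L,
                               interp_config(lambda = 0.01)), 1.04)

  # squared variant drops the sign term
  expect_equal(objective_value(c(0, 1, 2), c(0, 2, 1), 3L, 0L,
                               interp_config(objective = "squared")), 1)
})

test_that("displacement estimation recovers translations and ties to zero", {
  sino <- bump_sinogram(shift = 3L)
  u <- estimate_displacement(sino, 1L, 2L)
  support <- sino$data[1L, ] > 1e-3
  expect_true(all(u$u[support] == -3L))
  expect_true(all(abs(u$u) <= u$search_radius))

  # identical rows: flat data term at the truth, tie-break picks 0
  g <- tiny_geometry(16L, 2L)
  same <- sinogram(rbind(1:16, 1:16), g, check_support = FALSE)
  expect_true(all(estimate_displacement(same, 1L, 2L)$u == 0L))

  zero <- sinogram(matrix(0, 2L, 16L), g, check_support = FALSE)
  expect_true(all(estimate_displacement(zero, 1L, 2L)$u == 0L))

  expect_error(estimate_displacement(same, 1L, 1L), "distinct")
})

test_that("vectorized search matches the naive double-loop oracle", {
  set.seed(42)
  cfgs <- list(interp_config(search_radius = 4L),
               interp_config(search_radius = 4L, objective = "squared"))
  for (case in 1:60) {
    cfg <- cfgs[[case %% 2L + 1L]]
    tr <- round(rnorm(16L), 2)
    sr <- round(rnorm(16L), 2)
    g <- tiny_geometry(16L, 2L)
    sino <- sinogram(rbind(sr, tr), g, check_support = FALSE)
    expect_identical(estimate_displacement(sino, 1L, 2L, cfg)$u,
                     naive_displacement(tr, sr, cfg))
  }
})

test_that("repeated estimation on identical input is bit-identical", {
  sino <- bump_sinogram(shift = 2L)
  expect_identical(estimate_displacement(sino, 1L, 2L)$u,
                   estimate_displacement(sino, 1L, 2L)$u)
})

test_that("fractional displacement follows the floor/alpha split", {
  src <- as.numeric(1:10)
  u <- rep(0L, 10L)
  expect_identical(apply_fractional_displacement(src, u, 0.7), src)

  u3 <- rep(3L, 10L)
  expect_equal(apply_fractional_displacement(src, u3, 1)[1:7],
               src[4:10])  # integer displacement, alpha = 0
  # n = 5, u = 3, fraction 0.5: reads 6.5 -> 0.5 src[6] + 0.5 src[7]
  expect_equal(apply_fractional_displacement(src, u3, 0.5)[5L],
               0.5 * src[6L] + 0.5 * src[7L])
  # fraction 0 is the identity regardless of u
  expect_identical(apply_fractional_displacement(src, u3, 0), src)
  # out-of-range reads are zero
  expect_equal(apply_fractional_displacement(src, u3, 1)[8:10], c(0, 0, 0))
})

test_that("missing views are reproduced for translating profiles", {
  # profile moves 4 bins per measured gap; midpoint is the 2-bin translate
  sino <- bump_sinogram(n_bins = 64L, n_views = 4L, shift = 4L)
  truth_mid <- exp(-(seq_len(64L) - 16 - 2)^2 / (2 * 2^2))
  for (dir in c("forward", "backward", "bidirectional")) {
    est <- estimate_missing_views(sino, 1L, 2L, 1L,
                                  interp_config(direction = dir))[[1L]]
    expect_lt(max(abs(est - truth_mid)), 1e-6)
  }

  # identical measured views: estimate equals them exactly
  g <- tiny_geometry(32L, 2L)
  row <- exp(-(1:32 - 10)^2 / 8)
  same <- sinogram(rbind(row, row), g, check_support = FALSE)
  est <- estimate_missing_views(same, 1L, 2L, 1L)[[1L]]
  expect_equal(est, row, tolerance = 1e-12)

  expect_error(estimate_missing_views(sino, 1L, 2L, 0L), "at least 1")
})

test_that("odd translations are recovered within the interpolation bound", {
  # shift 3: the midpoint sits between bins, so the error is bounded by the
  # profile's modulus of continuity at half a bin (<= max adjacent jump)
  sino <- bump_sinogram(n_bins = 64L, n_views = 4L, shift = 3L)
  profile <- sino$data[1L, ]
  truth_mid <- exp(-(seq_len(64L) - 16 - 1.5)^2 / (2 * 2^2))
  est <- estimate_missing_views(sino, 1L, 2L, 1L)[[1L]]
  expect_lt(max(abs(est - truth_mid)), max(abs(diff(profile))))
})

test_that("estimated views of a nonnegative sinogram stay nonnegative", {
  set.seed(7)
  g <- tiny_geometry(32L, 6L)
  for (k in 1:20) {
    rows <- matrix(pmax(0, rnorm(6L * 32L, mean = 1)), 6L, 32L)
    sino <- sinogram(rows, g, check_support = FALSE)
    est <- estimate_missing_views(sino, 1L, 2L, 3L)
    expect_true(all(vapply(est, min, numeric(1)) >= 0))
  }
})

test_that("displacement upsampling preserves measured views and wraps", {
  g <- tiny_geometry(16L, 2L)
  row <- exp(-(1:16 - 5)^2 / 4)
  same <- sinogram(rbind(row, row), g, check_support = FALSE)
  up <- upsample_sinogram(same, 2L)
  expect_identical(dim(up$data), c(4L, 16L))
  for (i in 1:4) expect_equal(up$data[i, ], row, tolerance = 1e-12)

  sino <- bump_sinogram(n_bins = 48L, n_views = 6L, shift = 2L)
  up3 <- upsample_sinogram(sino, 3L)
  expect_identical(nrow(up3$data), 18L)
  expect_equal(diff(up3$geometry$angles), rep(20, 17L))
  # measured rows are copied bit-exactly
  expect_identical(up3$data[seq(1L, 18L, by = 3L), ], sino$data)

  expect_error(upsample_sinogram(sino, 1L), "at least 2")
  bad <- ct_geometry(48L, c(0, 10, 50, 100), image_size = 24L)
  nonunif <- sinogram(matrix(0, 4L, 48L), bad, check_support = FALSE)
  expect_error(upsample_sinogram(nonunif, 2L), "uniform")
})
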