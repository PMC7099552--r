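test_that("FBP is linear and recovers a disk's density", {
  g <- ct_geometry(367L, 0:359, image_size = 256L)
  zero <- sinogram(matrix(0, 360L, 367L), g, check_support = FALSE)
  expect_true(all(fbp_reconstruct(zero)$data == 0))

  disk <- project_phantom(ellipse_phantom(0, 0, 40, 40, 0, 1), g)
  rec <- fbp_reconstruct(disk)
  interior <- rec$data[109:148, 109:148]   # well inside the radius-40 disk
  expect_lt(abs(mean(interior) - 1), 0.03)

  # linearity to floating-point accuracy
  s2 <- project_phantom(ellipse_phantom(10, 5, 20, 30, 15, 0.5), g)
  r2 <- fbp_reconstruct(s2)
  mix <- sinogram(disk$data + s2$data, g, check_support = FALSE)
  expect_lt(max(abs(fbp_reconstruct(mix)$data - (rec$data + r2$data))),
            1e-9 * max(abs(rec$data)))

  expect_error(fbp_reconstruct(sinogram(matrix(0, 1L, 367L),
    ct_geometry(367L, 0, image_size = 256L), check_support = FALSE)),
    "at least 2")
})

test_that("Joseph projector and backprojector are exact adjoints", {
  set.seed(21)
  g <- ct_geometry(49L, seq(0, 350, by = 10), bin_spacing = 1,
                   image_size = 32L)
  x <- matrix(rnorm(32L * 32L), 32L)
  y <- matrix(rnorm(36L * 49L), 36L)
  Ax <- forward_project(recon_image(x), g)$data
  Aty <- back_project(sinogram(y, g, check_support = FALSE), 32L)$data
  lhs <- sum(Ax * y); rhs <- sum(x * Aty)
  expect_lt(abs(lhs - rhs) / abs(lhs), 1e-6)
})

test_that("projector geometry is consistent and symmetric", {
  g <- ct_geometry(33L, seq(0, 350, by = 10), bin_spacing = 1,
                   image_size = 17L)
  zero <- forward_project(recon_image(matrix(0, 17L, 17L)), g)
  expect_true(all(zero$data == 0))
  # unit pixel at the exact center projects to a bump at the central bin
  img <- matrix(0, 17L, 17L); img[9L, 9L] <- 1
  p <- forward_project(recon_image(img), g)$data
  expect_true(all(apply(p, 1L, which.max) == 17L))
  # for a smooth image every view carries the same total mass (per-view
  # sums agree once the object is resolved by the bin grid)
  xs <- seq_len(17L) - 9
  blob <- exp(-outer(xs^2, xs^2, `+`) / (2 * 3^2))
  ps <- forward_project(recon_image(blob), g)$data
  sums <- rowSums(ps)
  expect_lt(max(abs(sums - mean(sums))) / mean(sums), 1e-3)

  # backprojection of a constant sinogram is fourfold symmetric for a
  # full uniform turn (rotational symmetry of the operator)
  gc <- ct_geometry(49L, 0:359, bin_spacing = 1, image_size = 32L)
  ones <- sinogram(matrix(1, 360L, 49L), gc, check_support = FALSE)
  b <- back_project(ones, 32L)$data
  expect_true(all(back_project(sinogram(matrix(0, 360L, 49L), gc,
    check_support = FALSE), 32L)$data == 0))
  for (rot in list(t(b), b[rev(seq_len(32L)), rev(seq_len(32L))]))
    expect_lt(max(abs(b - rot)) / max(b), 1e-6)
})

test_that("Landweber iteration descends the residual from any start", {
  g <- ct_geometry(95L, seq(0, 354, by = 6), image_size = 64L)
  sino <- project_phantom(ellipse_phantom(0, 0, 20, 20, 0, 1), g)

  # one iteration from zero equals the relaxed backprojection of the data
  # on the unit-radius FOV scale (c = 2 / image_size)
  one <- landweber_reconstruct(sino, landweber_config(iterations = 1L))
  cs <- 2 / 64
  expect_equal(one$data, 0.01 * cs^2 * back_project(sino, 64L)$data,
               tolerance = 1e-12)

  rec <- landweber_reconstruct(sino, landweber_config(iterations = 200L))
  res <- residual_history(rec)
  expect_identical(nrow(res), 200L)
  expect_true(all(diff(res$residual) <= 0))

  # consistent data at a fixed point leaves the image unchanged
  x0 <- recon_image(matrix(0.5, 64L, 64L))
  p0 <- forward_project(x0, g)
  fixed <- landweber_reconstruct(p0, landweber_config(iterations = 3L),
                                 initial = x0)
  expect_equal(fixed$data, x0$data, tolerance = 1e-10)

  # a step far above the stability bound is flagged, not silently accepted
  expect_warning(
    landweber_reconstruct(sino, landweber_config(alpha = 50,
                                                 iterations = 15L)),
    "residual")
})
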