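test_that("analytic projection matches closed-form ellipse line integrals", {
  # centered disk: every view sees the full chord 2*rho*r at t = 0
  g <- tiny_geometry(65L, 12L, image_size = 60L)
  disk <- ellipse_phantom(0, 0, 20, 20, 0, 1.5)
  p <- project_phantom(disk, g)$data
  expect_equal(p[, 33L], rep(2 * 1.5 * 20, 12L), tolerance = 1e-12)
  # rays beyond the support are exactly zero
  expect_true(all(p[, abs(detector_coords(g)) > 20 + 1] == 0))

  # unrotated ellipse a=2, b=1, rho=1 at theta=0, t=0: 2*1*2*1*sqrt(4)/4 = 2
  ge <- ct_geometry(9L, c(0, 90), bin_spacing = 1, image_size = 8L)
  pe <- project_phantom(ellipse_phantom(0, 0, 2, 1, 0, 1), ge)$data
  expect_equal(pe[1L, 5L], 2, tolerance = 1e-12)
  # at theta=90 the chord is along the short axis: 2*a*b*sqrt(b^2)/b^2 = 4
  expect_equal(pe[2L, 5L], 4, tolerance = 1e-12)
})

test_that("projection agrees with numerical integration of the raster", {
  g <- tiny_geometry(65L, 4L, image_size = 64L)
  ph <- ellipse_phantom(3, -2, 14, 20, 25, 0.8)
  p <- project_phantom(ph, g)$data
  img <- rasterize_phantom(ph, g)$data
  # view at 0 degrees: rays are vertical lines, integral = column sums
  num <- colSums(img)                       # pixel spacing 1
  tcoord <- detector_coords(g)
  xpix <- seq_len(64L) - 65 / 2             # pixel-center x coordinates
  num_at_bins <- approx(xpix, num, xout = tcoord)$y
  inside <- abs(tcoord - 3) < 10            # away from the sqrt edge
  expect_lt(max(abs(p[1L, inside] - num_at_bins[inside])) /
              max(p[1L, ]), 0.01)
})

test_that("projection enforces field-of-view containment", {
  g <- tiny_geometry(65L, 4L, image_size = 40L)
  expect_error(project_phantom(ellipse_phantom(15, 0, 10, 10, 0, 1), g),
               "field-of-view")
})

test_that("rasterization is additive and deterministic", {
  g <- tiny_geometry(33L, 4L, image_size = 16L)
  expect_true(all(rasterize_phantom(ellipse_phantom(
    numeric(0), numeric(0), numeric(0), numeric(0), numeric(0),
    numeric(0)), g)$data == 0))
  big <- ellipse_phantom(0, 0, 8, 8, 0, 1)
  expect_equal(rasterize_phantom(big, g)$data[8L, 8L], 1)
  two <- ellipse_phantom(c(0, 0), c(0, 0), c(8, 4), c(8, 4), c(0, 0),
                         c(1, -0.5))
  r2 <- rasterize_phantom(two, g)$data
  expect_equal(r2[8L, 8L], 0.5)   # overlap region
  expect_equal(r2[8L, 14L], 1)    # outer ellipse only
})

test_that("every view of an analytic sinogram conserves phantom mass", {
  g <- ct_geometry(367L, 0:359, image_size = 256L)
  ph <- default_phantom()
  sino <- project_phantom(ph, g)
  masses <- rowSums(sino$data) * g$bin_spacing
  expect_lt(max(abs(masses - phantom_mass(ph))) / abs(phantom_mass(ph)),
            0.005)
})

test_that("parallel-beam sinogram has the half-turn mirror symmetry", {
  g <- ct_geometry(91L, seq(0, 350, by = 10), image_size = 90L)
  sino <- project_phantom(ellipse_phantom(c(10, -20), c(5, -8), c(12, 6),
                                          c(8, 9), c(30, 0), c(1, -0.4)), g)
  # p(theta + 180, t) == p(theta, -t); the bin grid is symmetric about its
  # center so reversing columns negates t
  for (i in 1:18)
    expect_equal(sino$data[i + 18L, ], rev(sino$data[i, ]), tolerance = 1e-12)
})

test_that("default phantom is valid, reproducible, and dots are resolvable", {
  ph <- default_phantom()
  expect_s3_class(ph, "ellipse_phantom")
  expect_identical(ph, default_phantom())
  expect_true(all(ph$a > 0 & ph$b > 0))
  g <- ct_geometry(367L, 0:359, image_size = 256L)
  expect_identical(dim(rasterize_phantom(ph, g)$data), c(256L, 256L))
  # full-view FBP resolves the central black/white pair: positive peak on
  # the white side, negative on the black side, relative to the body
  rec <- fbp_reconstruct(project_phantom(ph, g))
  white <- max(rec$data[123:134, 119:128]) # around (-4.5, 0)
  black <- min(rec$data[123:134, 130:139]) # around (+4.5, 0)
  expect_gt(white - black, 0)
})

test_that("phantom specs round-trip through their text format", {
  ph <- default_phantom()
  f <- withr::local_tempfile(fileext = ".txt")
  write_phantom(ph, f)
  expect_equal(read_phantom(f), ph, tolerance = 1e-12)
})
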