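test_that("apply_mask modulates every band elementwise", {
  w <- c(500, 510)
  cube <- spectral_cube(random_cube_array(4, 4, 2, seed = 5), w)
  ones <- coded_mask(matrix(1, 4, 4))
  zeros <- coded_mask(matrix(0, 4, 4))
  expect_equal(apply_mask(cube, ones)$data, cube$data)
  expect_true(all(apply_mask(cube, zeros)$data == 0))

  # 2x2x2 checkerboard, product computed voxel by voxel
  cb <- coded_mask(matrix(c(1, 0, 0, 1), 2, 2))
  small <- spectral_cube(array(1:8, c(2, 2, 2)), w)
  out <- apply_mask(small, cb)
  expected <- array(c(1, 0, 0, 4, 5, 0, 0, 8), c(2, 2, 2))
  expect_equal(out$data, expected)
  expect_equal(out$wavelengths, w)
  expect_error(apply_mask(cube, cb), "mask is")
})

test_that("band shifts integrate the reciprocal dispersion and round", {
  dm <- default_dispersion()
  expect_identical(band_shifts(dm, 445), 0L)
  # first interval: 35 nm at 1.67 nm/pixel -> 20.96 -> 21 pixels
  expect_identical(band_shifts(dm, 480), 21L)

  # fine numerical quadrature oracle over the piecewise-constant model
  quad_shift <- function(model, lambda) {
    grid <- seq(model$reference_wavelength, lambda, by = 1e-3)
    bp <- model$breakpoints
    rate <- vapply(grid, function(l) {
      j <- max(which(bp$lambda_lo_nm <= l + 1e-12))
      1 / bp$nm_per_pixel[min(j, nrow(bp))]
    }, 0)
    sum((rate[-1] + rate[-length(rate)]) / 2) * 1e-3
  }
  for (l in c(460, 480, 510, 555, 602))
    expect_identical(band_shifts(dm, l), as.integer(round(quad_shift(dm, l))))

  toy <- uniform_dispersion(2.0, 500, 540, reference_wavelength = 500)
  expect_identical(band_shifts(toy, 510), 5L)
  expect_error(band_shifts(dm, 700), "outside")
  shifts <- band_shifts(dm, default_band_grid(32L))
  expect_true(all(diff(shifts) >= 0L))
})

test_that("forward is shift-and-add with zero fill", {
  w <- c(500, 510)
  # degenerate CASSI: one band, all-ones mask, zero shift
  band <- matrix(runif(12), 3, 4)
  cube1 <- spectral_cube(array(band, c(3, 4, 1)), 500)
  op1 <- sensing_operator(coded_mask(matrix(1, 3, 4)), c(3, 4, 1), shifts = 0L)
  expect_equal(forward_project(cube1, op1)$data, band)

  # 3x3x2, shifts (0, 1): summed image written out by hand
  M <- matrix(c(1, 0, 1, 0, 1, 1, 1, 0, 0), 3, 3)
  cube <- spectral_cube(array(c(1:9, 10:18), c(3, 3, 2)), w)
  op <- sensing_operator(coded_mask(M), c(3, 3, 2), shifts = c(0L, 1L))
  expected <- rbind(c(1, 10, 7, 16),
                    c(0, 5, 14, 0),
                    c(3, 18, 15, 0))
  expect_equal(forward_project(cube, op)$data, expected)
})

test_that("the noiseless forward map is linear", {
  op <- tiny_op(8, 8, 4)
  f1 <- random_cube_array(8, 8, 4, seed = 11)
  f2 <- random_cube_array(8, 8, 4, seed = 12)
  a <- 2.5; b <- -1.25
  lhs <- cassir:::forward_raw(a * f1 + b * f2, op)
  rhs <- a * cassir:::forward_raw(f1, op) + b * cassir:::forward_raw(f2, op)
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("adjoint satisfies the inner-product identity", {
  for (seed in 1:5) {
    op <- tiny_op(8, 8, 4, mask_seed = seed)
    f <- random_cube_array(8, 8, 4, seed = seed)
    y <- withr::with_seed(100 + seed,
                          matrix(stats::rnorm(8 * 11), 8, 11))
    lhs <- sum(cassir:::forward_raw(f, op) * y)
    rhs <- sum(f * cassir:::adjoint_raw(y, op))
    expect_lt(abs(lhs - rhs), 1e-10 * max(abs(lhs), 1))
  }
  op <- tiny_op(5, 5, 3)
  expect_true(all(adjoint_project(matrix(0, 5, 7), op)$data == 0))
  # all-ones mask, single band, zero shift: adjoint is the identity crop
  op1 <- sensing_operator(coded_mask(matrix(1, 4, 4)), c(4, 4, 1), shifts = 0L)
  y1 <- matrix(runif(16), 4, 4)
  expect_equal(adjoint_project(y1, op1)$data[, , 1], y1)
})

test_that("Phi Phi^T is diagonal and matches phi_phit_diag", {
  op <- tiny_op(6, 6, 3, mask_seed = 7, shifts = 0:2)
  Phi <- dense_phi(op)
  PPT <- Phi %*% t(Phi)
  expect_equal(PPT, diag(diag(PPT)))
  expect_equal(diag(PPT), as.vector(phi_phit_diag(op)))

  # all-ones mask: interior measurement pixels see every band
  opo <- sensing_operator(coded_mask(matrix(1, 5, 6)), c(5, 6, 3),
                          shifts = 0:2)
  D <- phi_phit_diag(opo)
  expect_true(all(D[, 3:6] == 3))
  opz <- sensing_operator(coded_mask(matrix(0, 4, 4)), c(4, 4, 2),
                          shifts = 0:1)
  expect_true(all(phi_phit_diag(opz) == 0))
})

test_that("dense_phi reproduces the matrix-free action", {
  # 2x2x1 all-ones, zero shift: a selection (here permutation) matrix
  op1 <- sensing_operator(coded_mask(matrix(1, 2, 2)), c(2, 2, 1), shifts = 0L)
  expect_equal(dense_phi(op1), diag(4))

  op <- tiny_op(5, 5, 3, mask_seed = 4, shifts = 0:2)
  Phi <- dense_phi(op)
  f <- random_cube_array(5, 5, 3, seed = 21)
  expect_equal(as.vector(Phi %*% as.vector(f)),
               as.vector(cassir:::forward_raw(f, op)))
  y <- withr::with_seed(22, matrix(stats::rnorm(5 * 7), 5, 7))
  expect_equal(as.vector(t(Phi) %*% as.vector(y)),
               as.vector(cassir:::adjoint_raw(y, op)))
  # every cube voxel maps to exactly one detector pixel with weight T
  expect_equal(colSums(Phi), rep(as.vector(op$mask$pattern), 3))
  expect_error(dense_phi(tiny_op(30, 30, 12)), "too large")
})

test_that("forward is row-shift equivariant and conserves energy", {
  op <- tiny_op(8, 8, 3, mask_seed = 9, shifts = 0:2)
  f <- random_cube_array(8, 8, 3, seed = 31)
  # translate scene and mask down one row: measurement translates too
  sh <- function(a) a[c(8, 1:7), , drop = FALSE]
  mask2 <- coded_mask(sh(op$mask$pattern))
  op2 <- sensing_operator(mask2, c(8, 8, 3), shifts = 0:2)
  f2 <- f[c(8, 1:7), , , drop = FALSE]
  expect_equal(cassir:::forward_raw(f2, op2),
               sh(cassir:::forward_raw(f, op)))

  ones <- sensing_operator(coded_mask(matrix(1, 8, 8)), c(8, 8, 3),
                           shifts = 0:2)
  expect_equal(sum(cassir:::forward_raw(f, ones)), sum(f))
})

test_that("noise is seeded and reproducible", {
  cube <- spectral_cube(random_cube_array(8, 8, 3, seed = 2),
                        c(500, 510, 520))
  op <- tiny_op(8, 8, 3)
  nm <- noise_model("gaussian", sigma = 0.5, seed = 42L)
  m1 <- forward_project(cube, op, nm)
  m2 <- forward_project(cube, op, nm)
  expect_identical(m1$data, m2$data)
  clean <- forward_project(cube, op)
  expect_false(identical(m1$data, clean$data))
  pg <- noise_model("poisson-gaussian", sigma = 0.1, gain = 0.5, seed = 1L)
  mp <- forward_project(cube, op, pg)
  expect_true(all(is.finite(mp$data)))
})
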