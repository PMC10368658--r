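test_that("initialization matches the dense-matrix solve", {
  op <- tiny_op(5, 5, 3, mask_seed = 2, shifts = 0:2)
  y <- withr::with_seed(8, matrix(stats::runif(5 * 7), 5, 7))
  for (g in list(c(1, 1), c(0.3, 2.5))) {
    f0 <- admm_initialize(y, op, g[1], g[2])$data
    ref <- dense_al_solve(cassir:::adjoint_raw(y, op), op, g[1], g[2])
    expect_lt(max(abs(f0 - ref)), 1e-8 * max(abs(ref)))
  }
  # operator term vanishes at gamma1 = 0
  expect_equal(admm_initialize(y, op, 0, 2)$data,
               cassir:::adjoint_raw(y, op) / 2)
  expect_true(all(admm_initialize(matrix(0, 5, 7), op)$data == 0))
  expect_error(admm_initialize(y, op, 1, 0), "gamma2")
})

test_that("projection step matches the dense solve and fixes consistent points", {
  op <- tiny_op(5, 5, 3, mask_seed = 6, shifts = 0:2)
  v <- random_cube_array(5, 5, 3, seed = 41)
  y <- withr::with_seed(42, matrix(stats::runif(5 * 7), 5, 7))
  l1 <- withr::with_seed(43, matrix(stats::rnorm(5 * 7), 5, 7))
  l2 <- withr::with_seed(44, array(stats::rnorm(75), c(5, 5, 3)))
  g1 <- 0.8; g2 <- 1.7
  got <- projection_step(v, y, l1, l2, g1, g2, op)
  b <- l2 + g2 * v + cassir:::adjoint_raw(g1 * y - l1, op)
  ref <- dense_al_solve(b, op, g1, g2)
  expect_lt(max(abs(got - ref)), 1e-8 * max(abs(ref)))

  # gamma1 = 0 with zero multipliers collapses to v
  expect_equal(projection_step(v, y, 0 * l1, array(0, c(5, 5, 3)), 0, g2, op),
               v)

  # noiseless consistent point is a fixed point
  fstar <- random_cube_array(5, 5, 3, seed = 45)
  ystar <- cassir:::forward_raw(fstar, op)
  got <- projection_step(fstar, ystar, 0 * l1, 0 * l2, g1, g2, op)
  expect_lt(max(abs(got - fstar)), 1e-10 * max(abs(fstar)))
})

test_that("denoise step shifts by the scaled multiplier and honors contracts", {
  f <- random_cube_array(6, 6, 2, seed = 51)
  l2 <- withr::with_seed(52, array(stats::rnorm(72), c(6, 6, 2)))
  idd <- denoiser("identity")
  expect_equal(denoise_step(f, l2, 2, idd, 0.5), f - l2 / 2)
  expect_equal(denoise_step(f, 0 * l2, 1, idd, 0.5), f)
  # strength 0 is the identity for every denoiser
  for (nm in c("tv", "wavelet", "spectral_attention"))
    expect_equal(denoise_step(f, 0 * l2, 1, denoiser(nm), 0), f)
})

test_that("TV denoising reduces the TV functional of a noisy cube", {
  w <- c(500, 510)
  base <- array(0, c(16, 16, 2))
  base[5:12, 5:12, ] <- 1
  noisy <- base + withr::with_seed(6, array(stats::rnorm(512, sd = 0.1),
                                            c(16, 16, 2)))
  den <- denoise(denoiser("tv"), noisy, 0.2)
  expect_lt(cassir:::tv_functional(den), cassir:::tv_functional(noisy))
  # wavelet thresholding also shrinks high-frequency content
  denw <- denoise(denoiser("wavelet"), noisy, 0.1)
  expect_lt(cassir:::tv_functional(denw), cassir:::tv_functional(noisy))
  # zero threshold: Haar analysis/synthesis is a perfect inverse (odd dims)
  odd <- matrix(runif(15 * 13), 15, 13)
  expect_equal(cassir:::haar_soft_threshold(odd, 0), odd, tolerance = 1e-12)
})

test_that("multiplier updates follow the dual-ascent formulas", {
  op <- sensing_operator(coded_mask(matrix(1, 2, 2)), c(2, 2, 1), shifts = 0L)
  f <- array(c(1, 2, 3, 4), c(2, 2, 1))
  v <- array(c(1, 1, 2, 2), c(2, 2, 1))
  y <- matrix(c(2, 2, 2, 2), 2, 2)
  st <- list(f = f, v = v, lambda1 = matrix(1, 2, 2),
             lambda2 = array(0.5, c(2, 2, 1)), gamma1 = 2, gamma2 = 3, i = 1L)
  out <- update_multipliers(st, y, op)
  # lambda1 <- 1 - 2 * (y - f); lambda2 <- 0.5 - 3 * (f - v), by hand
  expect_equal(out$lambda1, matrix(1, 2, 2) - 2 * (y - f[, , 1]))
  expect_equal(out$lambda2, array(0.5, c(2, 2, 1)) - 3 * (f - v))
  expect_equal(out$i, 2L)

  # zero residuals leave multipliers unchanged; zero gammas freeze them
  stc <- st; stc$v <- f; yc <- cassir:::forward_raw(f, op)
  outc <- update_multipliers(stc, yc, op)
  expect_equal(outc$lambda1, st$lambda1)
  expect_equal(outc$lambda2, st$lambda2)
  stz <- st; stz$gamma1 <- 0; stz$gamma2 <- 0
  outz <- update_multipliers(stz, y, op)
  expect_equal(outz$lambda1, st$lambda1)
  expect_equal(outz$lambda2, st$lambda2)
})

test_that("identity operator with identity denoiser recovers the scene exactly", {
  band <- matrix(runif(36), 6, 6)
  cube <- spectral_cube(array(band, c(6, 6, 1)), 500)
  op <- sensing_operator(coded_mask(matrix(1, 6, 6)), c(6, 6, 1), shifts = 0L)
  y <- forward_project(cube, op)
  # the first round closes three quarters of the gap; the multiplier updates
  # make the second round exact
  cfg <- solver_config(n_iterations = 2, denoiser = denoiser("identity"),
                       strength = 0)
  rec <- cassi_reconstruct(y, op, cfg, wavelengths = 500)
  expect_equal(rec$data[, , 1], band, tolerance = 1e-10)
})

test_that("ADMM-TV improves on the initialization and tracks residuals", {
  fx <- phantom_fixture(bands = 8L, rows = 32L, cols = 32L)
  cfg <- solver_config(n_iterations = 30, denoiser = denoiser("tv"),
                       strength = 0.1)
  rec <- cassi_reconstruct(fx$y, fx$op, cfg, wavelengths = fx$w)
  p_init <- psnr(admm_initialize(fx$y, fx$op)$data, fx$scene$cube$data)
  expect_gt(psnr(rec, fx$scene$cube), p_init)
  res <- attr(rec, "residuals")
  expect_length(res, 31L)
  expect_true(all(is.finite(res)))
  expect_true(all(rec$data >= 0))
})

test_that("guidance features expose gamma2, the mask stack and the trace map", {
  op <- tiny_op(6, 6, 3, mask_seed = 1, shifts = 0:2)
  g <- guidance_features(2.5, op)
  expect_equal(dim(g), c(6, 6, 5))
  expect_true(all(g[, , 1] == 2.5))
  for (k in 1:3) expect_equal(g[, , k + 1], op$mask$pattern)
  # trace channel equals the dense diag shifted back per band and averaged
  Phi <- dense_phi(op)
  D <- matrix(diag(Phi %*% t(Phi)), 6, 8)
  ref <- (D[, 1:6] + D[, 2:7] + D[, 3:8]) / 3
  expect_equal(g[, , 5], ref)

  opo <- sensing_operator(coded_mask(matrix(1, 6, 6)), c(6, 6, 3),
                          shifts = 0:2)
  go <- guidance_features(1, opo)
  expect_true(all(go[3:4, 3:4, 5] == 3))
})

test_that("divergent solves raise an error with an iteration trace", {
  op <- tiny_op(6, 6, 2, shifts = 0:1)
  y <- matrix(1e150, 6, 7)
  cfg <- solver_config(n_iterations = 5, gamma1 = 1e160,
                       denoiser = denoiser("identity"), strength = 0)
  expect_error(cassi_reconstruct(y, op, cfg), "diverged")
})
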