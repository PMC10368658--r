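test_that("random masks hit the requested fill and are seed-deterministic", {
  m <- random_binary_mask(1000, 1000, 0.5, seed = 0)
  expect_lt(abs(mean(m$pattern) - 0.5), 0.01)
  expect_identical(random_binary_mask(32, 32, 0.3, seed = 7)$pattern,
                   random_binary_mask(32, 32, 0.3, seed = 7)$pattern)
  expect_true(all(random_binary_mask(16, 16, 0.999999, seed = 1)$pattern == 1))
  # feature upsampling: constant 2x2 blocks
  mf <- random_binary_mask(8, 8, 0.5, feature_px = 2, seed = 3)
  expect_equal(mf$pattern[seq(1, 7, 2), ], mf$pattern[seq(2, 8, 2), ])
  expect_error(random_binary_mask(8, 8, 0), "fill_fraction")
})

test_that("rainbow scene sweeps a Gaussian band linearly across columns", {
  w <- default_band_grid(32L)
  sc <- rainbow_scene(8, 33, w, bandwidth = 10, silhouette = "full")
  centroid <- function(col) {
    v <- sc$data[1, col, ]
    sum(w * v) / sum(v)
  }
  mid <- (w[1] + w[32]) / 2
  expect_equal(centroid(17), mid, tolerance = 1e-6)

  # edge columns: centroid of the Gaussian truncated to the band grid,
  # computed directly from the closed form
  sigma <- 10 / (2 * sqrt(2 * log(2)))
  wts <- exp(-(w - w[1])^2 / (2 * sigma^2))
  expect_equal(centroid(1), sum(w * wts) / sum(wts), tolerance = 1e-9)
  wts <- exp(-(w - w[32])^2 / (2 * sigma^2))
  expect_equal(centroid(33), sum(w * wts) / sum(wts), tolerance = 1e-9)

  # narrow-band limit: a column whose sweep center sits on the band grid
  # lights up a single band
  nb <- rainbow_scene(4, 33, w, bandwidth = 0.5, silhouette = "full")
  v <- nb$data[1, 1, ]
  expect_gt(max(v) / sum(v), 0.999)
})

test_that("bar targets render binary three-bar groups at the stated periods", {
  w <- default_band_grid(4L)
  expect_equal(bar_period_px(50, 10), 2.0)
  sc <- bar_target_scene(64, 64, w, groups = c(20, 40), pixel_pitch_um = 5.8)
  expect_setequal(unique(as.vector(sc$data)), c(0, 1))
  periods <- attr(sc, "periods_px")
  expect_equal(unname(periods), 1000 / c(20, 40) / 5.8)

  # vertical and horizontal renditions of a group are transposes
  p <- ceiling(2.5 * periods[1])
  vbars <- sc$data[1:p, 1:p, 1]
  hbars <- sc$data[1:p, 32 + (1:p), 1]
  expect_equal(hbars, t(vbars))
  # spectrally flat
  expect_equal(sc$data[, , 1], sc$data[, , 4])
  # ground-truth contrast across a bar profile is 1
  expect_equal(bar_contrast(sc$data[1, 1:p, 1]), 1.0)
  expect_error(bar_target_scene(64, 64, w, groups = 200, pixel_pitch_um = 5.8),
               "unrepresentable")
})

test_that("eye phantom carries a 540/575 nm vessel absorber", {
  w <- default_band_grid(32L)
  ph <- eye_phantom_scene(64, 64, w, seed = 0)
  expect_s3_class(ph$cube, "spectral_cube")
  pk <- find_absorption_peaks(ph$truth)
  expect_setequal(pk[1:2], c(540, 575))
  # absorber maxima sit on the stated centers of the band grid
  expect_equal(w[order(ph$absorber, decreasing = TRUE)[1:2]] %in% c(540, 575),
               c(TRUE, TRUE))

  # zero-amplitude absorber: cube equals the background in every band
  ph0 <- eye_phantom_scene(32, 32, w, seed = 1,
                           absorber_args = list(amplitudes = c(0, 0)))
  expect_equal(ph0$cube$data[, , 1], ph0$cube$data[, , 20])
  expect_equal(max(ph0$absorber), 0)

  # vessel coverage stays in the designed 2-10% band across seeds
  fr <- vapply(0:4, function(s)
    mean(eye_phantom_scene(64, 64, default_band_grid(4L), seed = s)$vessels), 0)
  expect_true(all(fr >= 0.02 & fr <= 0.10))
})

test_that("generators are deterministic and produce valid cubes", {
  w <- default_band_grid(8L)
  a <- eye_phantom_scene(32, 32, w, seed = 3)
  b <- eye_phantom_scene(32, 32, w, seed = 3)
  expect_identical(a$cube$data, b$cube$data)
  expect_identical(a$vessels, b$vessels)
  for (cube in list(a$cube, rainbow_scene(16, 16, w),
                    bar_target_scene(64, 64, w))) {
    expect_true(all(is.finite(cube$data)) && all(cube$data >= 0))
    band_sums <- apply(cube$data, 3, sum)
    expect_true(all(band_sums > 0))
  }
})

test_that("a tabulated extinction curve can replace the default absorber", {
  path <- withr::local_tempfile(fileext = ".csv")
  w <- seq(445, 600, by = 5)
  utils::write.csv(data.frame(wavelength_nm = w,
                              extinction = exp(-(w - 560)^2 / 200)),
                   path, row.names = FALSE)
  A <- oxyhemoglobin_absorber(w, extinction_csv = path)
  expect_equal(max(A), 0.6)
  expect_equal(w[which.max(A)], 560)
})
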