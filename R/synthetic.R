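#' Default spectral band grid
#'
#' Band centers covering the imager's 445-602 nm range at 5-nm spacing
#' (32 bands from 445 to 600 nm), the scale at which the synthetic scenes
#' emulate the instrument's 35-channel, ~5-nm regime.
#'
#' @param n_bands number of bands.
#' @param lo first band center (nm).
#' @param step band spacing (nm).
#' @return Numeric vector of band-center wavelengths.
#' @export
default_band_grid <- function(n_bands = 32L, lo = 445, step = 5) {
  lo + step * (seq_len(n_bands) - 1L)
}

#' Random binary coded mask
#'
#' I.i.d. Bernoulli(fill) pattern on the feature grid, upsampled by
#' `feature_px` so each mask feature spans `feature_px x feature_px` sensor
#' pixels. Deterministic given the seed.
#'
#' @param rows,cols mask size in sensor pixels.
#' @param fill_fraction transmitting probability in `(0, 1)`.
#' @param feature_px feature size in pixels (`>= 1`).
#' @param seed integer seed.
#' @return A [coded_mask()].
#' @export
random_binary_mask <- function(rows, cols, fill_fraction = 0.5,
                               feature_px = 1L, seed = 0L) {
  if (fill_fraction <= 0 || fill_fraction >= 1)
    stop("fill_fraction must be in (0, 1)", call. = FALSE)
  feature_px <- as.integer(feature_px)
  fr <- ceiling(rows / feature_px); fc <- ceiling(cols / feature_px)
  coarse <- withr::with_seed(as.integer(seed),
    matrix(stats::rbinom(fr * fc, 1L, fill_fraction), fr, fc))
  fine <- coarse[rep(seq_len(fr), each = feature_px),
                 rep(seq_len(fc), each = feature_px), drop = FALSE]
  coded_mask(fine[seq_len(rows), seq_len(cols), drop = FALSE],
             feature_px = feature_px)
}

# blocky silhouette used by the rainbow scene: a disc and two bars
shape_silhouette <- function(rows, cols) {
  sil <- matrix(0, rows, cols)
  rr <- outer(seq_len(rows), rep(1, cols))
  cc <- outer(rep(1, rows), seq_len(cols))
  r0 <- rows / 2; c0 <- cols * 0.25
  sil[(rr - r0)^2 + (cc - c0)^2 <= (min(rows, cols) / 5)^2] <- 1
  b1 <- round(cols * c(0.45, 0.55)); b2 <- round(cols * c(0.7, 0.8))
  sil[round(rows * 0.2):round(rows * 0.8), b1[1L]:b1[2L]] <- 1
  sil[round(rows * 0.2):round(rows * 0.8), b2[1L]:b2[2L]] <- 1
  sil
}

#' Rainbow-illuminated scene
#'
#' Emulates an object back-lit through a linear variable filter: every column
#' carries a Gaussian spectral band whose center sweeps linearly from the
#' first to the last wavelength across the field. The `bandwidth` is the
#' Gaussian FWHM in nm (the physical filter resolves 7-20 nm; 10 nm is the
#' default).
#'
#' @param rows,cols scene size.
#' @param wavelengths band-center grid (nm).
#' @param bandwidth spectral FWHM of the sweep (nm).
#' @param silhouette `"shapes"` (disc and bars), `"full"`, or a user matrix
#'   in `[0, 1]` of the scene shape.
#' @return A [spectral_cube()].
#' @export
rainbow_scene <- function(rows = 64L, cols = 64L,
                          wavelengths = default_band_grid(),
                          bandwidth = 10, silhouette = "shapes") {
  sil <- if (is.matrix(silhouette)) silhouette
         else if (identical(silhouette, "full")) matrix(1, rows, cols)
         else shape_silhouette(rows, cols)
  stopifnot(all(dim(sil) == c(rows, cols)))
  sigma <- bandwidth / (2 * sqrt(2 * log(2)))
  lo <- wavelengths[1L]; hi <- wavelengths[length(wavelengths)]
  centers <- if (cols == 1L) (lo + hi) / 2
             else lo + (seq_len(cols) - 1L) / (cols - 1L) * (hi - lo)
  L <- length(wavelengths)
  cube <- array(0, c(rows, cols, L))
  for (k in seq_len(L)) {
    wk <- exp(-(wavelengths[k] - centers)^2 / (2 * sigma^2))
    cube[, , k] <- sil * matrix(wk, rows, cols, byrow = TRUE)
  }
  spectral_cube(cube, wavelengths)
}

#' Bar-period in sensor pixels
#'
#' @param frequency lp/mm.
#' @param pixel_pitch_um sensor pixel pitch in micrometres.
#' @return Line-pair period in pixels.
#' @export
bar_period_px <- function(frequency, pixel_pitch_um) {
  1000 / frequency / pixel_pitch_um
}

# three-bar pattern along positions x (0-based pixel centers): bars of width
# period/2 alternating with equal gaps, total extent 2.5 periods
three_bar_profile <- function(n, period) {
  x <- seq_len(n) - 0.5
  as.numeric(x < 2.5 * period & (floor(2 * x / period) %% 2 == 0))
}

#' Resolution bar-target scene
#'
#' Three-bar groups at the stated spatial frequencies, horizontal and
#' vertical, spectrally flat across the band grid. Each group occupies one
#' horizontal strip: vertical bars (varying along columns) on the left half,
#' the transposed horizontal bars on the right half.
#'
#' @param rows,cols scene size.
#' @param wavelengths band grid.
#' @param groups numeric vector of frequencies in lp/mm.
#' @param pixel_pitch_um object-plane pixel pitch in micrometres.
#' @return A [spectral_cube()] with attribute `periods_px` (named per group).
#' @export
bar_target_scene <- function(rows = 64L, cols = 64L,
                             wavelengths = default_band_grid(8L),
                             groups = c(20, 40), pixel_pitch_um = 5.8) {
  n_g <- length(groups)
  strip <- rows %/% n_g
  half <- cols %/% 2L
  periods <- bar_period_px(groups, pixel_pitch_um)
  img <- matrix(0, rows, cols)
  for (i in seq_len(n_g)) {
    p <- periods[i]
    extent <- ceiling(2.5 * p)
    if (p < 2)
      stop(sprintf("frequency %g lp/mm needs a period of %.2f px (< 2 px): unrepresentable",
                   groups[i], p), call. = FALSE)
    if (extent > half || extent > strip)
      stop(sprintf("frequency %g lp/mm does not fit the %d x %d tile",
                   groups[i], strip, half), call. = FALSE)
    r0 <- (i - 1L) * strip
    prof <- three_bar_profile(extent, p)
    # vertical bars: intensity varies along columns
    img[r0 + seq_len(min(extent, strip)), seq_len(extent)] <-
      matrix(prof, min(extent, strip), extent, byrow = TRUE)
    # horizontal bars: the transpose, in the right half
    img[r0 + seq_len(extent), half + seq_len(min(extent, strip))] <-
      matrix(prof, extent, min(extent, strip))
  }
  L <- length(wavelengths)
  cube <- array(rep(img, L), c(rows, cols, L))
  out <- spectral_cube(cube, wavelengths)
  attr(out, "periods_px") <- stats::setNames(periods, groups)
  out
}

#' Oxyhemoglobin-like absorber
#'
#' Two Gaussians centered on the oxyhemoglobin absorption peaks at 540 and
#' 575 nm (FWHM 15 and 12 nm, amplitudes 0.6 and 0.5 by default; the widths
#' are full-width-at-half-maximum so the two bands stay spectrally distinct,
#' as the physiological bands do). A user-supplied extinction table
#' (`wavelength_nm, extinction` CSV) can be used instead; it is
#' max-normalized and scaled to `max(amplitudes)`.
#'
#' @param wavelengths evaluation grid (nm).
#' @param centers,widths,amplitudes Gaussian centers (nm), FWHMs (nm) and
#'   unitless amplitudes.
#' @param extinction_csv optional path to a tabulated extinction curve.
#' @return Numeric absorption fraction per wavelength (in `[0, 1)`).
#' @export
oxyhemoglobin_absorber <- function(wavelengths,
                                   centers = c(540, 575),
                                   widths = c(15, 12),
                                   amplitudes = c(0.6, 0.5),
                                   extinction_csv = NULL) {
  if (!is.null(extinction_csv)) {
    tab <- utils::read.csv(extinction_csv)
    e <- stats::approx(tab$wavelength_nm, tab$extinction, xout = wavelengths,
                       rule = 2)$y
    return(max(amplitudes) * e / max(e))
  }
  sigmas <- widths / (2 * sqrt(2 * log(2)))
  A <- rep(0, length(wavelengths))
  for (j in seq_along(centers))
    A <- A + amplitudes[j] *
      exp(-(wavelengths - centers[j])^2 / (2 * sigmas[j]^2))
  pmin(A, 0.999)
}

# seeded branching random-walk vasculature raster; thickness via a cross
# stamp of the given radius
vessel_raster <- function(rows, cols, seed = 0L, n_seeds = 2L,
                          steps = NULL, radius = 1L, branch_prob = 0.02) {
  if (is.null(steps)) steps <- round(0.7 * max(rows, cols))
  withr::with_seed(as.integer(seed), {
    V <- matrix(0, rows, cols)
    stamp <- function(r, c) {
      rr <- max(1, r - radius):min(rows, r + radius)
      cc <- max(1, c - radius):min(cols, c + radius)
      V[rr, c] <<- 1
      V[r, cc] <<- 1
    }
    walkers <- lapply(seq_len(n_seeds), function(i) {
      side <- sample(4L, 1L)
      pos <- switch(side,
        c(1, stats::runif(1, 1, cols)),
        c(rows, stats::runif(1, 1, cols)),
        c(stats::runif(1, 1, rows), 1),
        c(stats::runif(1, 1, rows), cols))
      ang <- switch(side, pi / 2, -pi / 2, 0, pi) +
        stats::runif(1, -0.5, 0.5)
      list(pos = pos, ang = ang, left = steps)
    })
    while (length(walkers) > 0) {
      w <- walkers[[1L]]; walkers <- walkers[-1L]
      while (w$left > 0) {
        w$pos <- w$pos + c(sin(w$ang), cos(w$ang))
        w$left <- w$left - 1L
        r <- round(w$pos[1L]); c <- round(w$pos[2L])
        if (r < 1 || r > rows || c < 1 || c > cols) break
        stamp(r, c)
        w$ang <- w$ang + stats::rnorm(1, 0, 0.18)
        if (stats::runif(1) < branch_prob && w$left > 8)
          walkers <- c(walkers, list(list(
            pos = w$pos,
            ang = w$ang + sample(c(-1, 1), 1L) * stats::runif(1, 0.5, 1.1),
            left = round(w$left / 2))))
      }
    }
    V
  })
}

#' Eye-phantom scene with a vessel absorber
#'
#' Emulates the painted vasculature of a model eye: a spatially smooth,
#' spectrally flat background reflectance multiplied by
#' `1 - A(lambda) * vessel_map`, where `A` is the two-Gaussian
#' oxyhemoglobin-like absorber of [oxyhemoglobin_absorber()] and the vessel
#' map is a seeded branching random-walk raster covering a few percent of the
#' field. The true vessel absorption spectrum (via the normalized-difference
#' formula against the flat illumination) is returned for recovery tests.
#'
#' @param rows,cols scene size.
#' @param wavelengths band grid (nm).
#' @param seed integer seed driving background and vasculature.
#' @param absorber_args list of overrides passed to
#'   [oxyhemoglobin_absorber()].
#' @return List with elements `cube` ([spectral_cube()]), `vessels` (an
#'   [roi()] of vessel pixels), `truth` (ground-truth vessel absorption
#'   [spectrum()]), and `absorber` (the absorption fractions used).
#' @export
eye_phantom_scene <- function(rows = 64L, cols = 64L,
                              wavelengths = default_band_grid(),
                              seed = 0L, absorber_args = list()) {
  A <- do.call(oxyhemoglobin_absorber,
               c(list(wavelengths = wavelengths), absorber_args))
  vess <- vessel_raster(rows, cols, seed = seed)
  bg <- withr::with_seed(as.integer(seed) + 1L, {
    noise <- matrix(stats::rnorm(rows * cols), rows, cols)
    for (i in 1:6) noise <- binomial3(noise)
    rng <- range(noise)
    0.65 + 0.3 * (noise - rng[1L]) / max(rng[2L] - rng[1L], 1e-12)
  })
  L <- length(wavelengths)
  cube <- array(0, c(rows, cols, L))
  for (k in seq_len(L)) cube[, , k] <- bg * (1 - A[k] * vess)
  # truth: Eq.-form absorption of the mean vessel spectrum against flat
  # illumination; background is spectrally flat so this is 1 - (1-A)/max(1-A)
  sr <- 1 - A
  truth <- spectrum(wavelengths, 1 - sr / max(sr))
  list(cube = spectral_cube(cube, wavelengths),
       vessels = roi(vess),
       truth = truth,
       absorber = A)
}

#' Spectrally and spatially flat scene
#'
#' @param rows,cols scene size.
#' @param wavelengths band grid.
#' @param value constant radiance.
#' @return A [spectral_cube()].
#' @export
flat_scene <- function(rows = 64L, cols = 64L,
                       wavelengths = default_band_grid(), value = 1) {
  spectral_cube(array(value, c(rows, cols, length(wavelengths))), wavelengths)
}
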