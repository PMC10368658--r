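#' Round half away from zero
#'
#' Resolution figures are reported with conventional half-up rounding (R's
#' `round()` rounds half to even).
#' @param x numeric.
#' @param digits decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Spectral resolution of one dispersion band
#'
#' The smallest mask feature spans `feature_px` camera pixels, so the
#' wavelength span dispersed across one feature — the spectral resolution —
#' is the pixel dispersion times the feature size. The instrument's 2-pixel
#' features make the resolution double the pixel dispersion.
#'
#' @param nm_per_pixel camera-plane pixel dispersion (nm/pixel, `> 0`).
#' @param feature_px mask feature size in pixels (`> 0`).
#' @return Resolution in nm, reported half-up to one decimal; the exact
#'   product is attached as `attr(, "exact")`.
#' @export
spectral_resolution <- function(nm_per_pixel, feature_px) {
  if (any(nm_per_pixel <= 0) || any(feature_px <= 0))
    stop("nm_per_pixel and feature_px must be positive", call. = FALSE)
  exact <- nm_per_pixel * feature_px
  structure(round_half_up(exact, 1), exact = exact)
}

#' Average spectral resolution over the covered range
#'
#' Width-weighted mean of the per-interval resolutions of a piecewise
#' dispersion model, reported to the nearest integer nanometre.
#'
#' @param model a [dispersion_model()].
#' @param feature_px mask feature size in pixels.
#' @return Integer-rounded mean resolution (nm) with the unrounded value in
#'   `attr(, "exact")`.
#' @export
average_spectral_resolution <- function(model, feature_px) {
  bp <- model$breakpoints
  widths <- bp$lambda_hi_nm - bp$lambda_lo_nm
  if (sum(widths) <= 0) stop("empty wavelength range", call. = FALSE)
  res <- bp$nm_per_pixel * feature_px
  exact <- sum(widths * res) / sum(widths)
  structure(round_half_up(exact, 0), exact = exact)
}

#' Convert a bar-target spatial frequency to a period
#'
#' A resolution-chart frequency of `f` line pairs per millimetre corresponds
#' to a line-pair period of `1000 / f` micrometres.
#'
#' @param frequency line pairs per mm, `> 0`.
#' @return Period in micrometres, half-up to one decimal, exact value in
#'   `attr(, "exact")`.
#' @export
lpmm_to_micron <- function(frequency) {
  if (any(frequency <= 0)) stop("frequency must be positive", call. = FALSE)
  exact <- 1000 / frequency
  structure(round_half_up(exact, 1), exact = exact)
}

#' Line profile across a bar group
#'
#' @param positions pixel indices (length `>= 3`).
#' @param intensities nonnegative intensities, same length.
#' @return An object of class `line_profile`.
#' @export
line_profile <- function(positions, intensities) {
  stopifnot(length(positions) == length(intensities), length(positions) >= 3)
  if (any(intensities < 0)) stop("intensities must be >= 0", call. = FALSE)
  structure(list(positions = positions, intensities = intensities),
            class = "line_profile")
}

#' Image contrast of a line profile
#'
#' `(I_max - I_min) / (I_max + I_min)` over the profile.
#'
#' @param profile a [line_profile()] or numeric intensity vector.
#' @return Contrast in `[0, 1]`.
#' @export
bar_contrast <- function(profile) {
  I <- if (inherits(profile, "line_profile")) profile$intensities else profile
  mx <- max(I); mn <- min(I)
  if (mx <= 0) stop("contrast undefined for an all-zero profile", call. = FALSE)
  (mx - mn) / (mx + mn)
}

#' Minimally resolvable spatial frequency
#'
#' Scans bar-group contrasts and returns the highest spatial frequency whose
#' contrast still meets the threshold (default 0.4).
#'
#' @param group_contrasts named numeric vector: names are frequencies in
#'   lp/mm, values are contrasts.
#' @param threshold contrast threshold in `(0, 1)`.
#' @return The limiting frequency in lp/mm, or `NA_real_` when no group
#'   reaches the threshold (unresolved).
#' @export
resolvable_limit <- function(group_contrasts, threshold = 0.4) {
  stopifnot(length(group_contrasts) >= 1, threshold > 0, threshold < 1)
  freqs <- as.numeric(names(group_contrasts))
  if (anyNA(freqs)) stop("group_contrasts must be named by frequency (lp/mm)",
                         call. = FALSE)
  ok <- group_contrasts >= threshold
  if (!any(ok)) return(NA_real_)
  max(freqs[ok])
}

# Otsu's global threshold on a numeric image: maximizes between-class
# variance over a 256-bin histogram
otsu_threshold <- function(x, nbins = 256L) {
  rng <- range(x)
  if (diff(rng) == 0)
    stop("cannot threshold a uniform image", call. = FALSE)
  br <- seq(rng[1L], rng[2L], length.out = nbins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  mids <- (br[-1L] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  bcv <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  bcv[!is.finite(bcv)] <- 0
  mids[which.max(bcv)]
}

#' Recover the coded mask from a monochromatic capture
#'
#' Under uniform monochromatic illumination the detector sees the mask
#' pattern itself (no shear ambiguity), so the mask is recovered by global
#' Otsu binarization. The transmitting fill fraction is attached as
#' `attr(, "fill_fraction")`; values far from the design fill are a sign of
#' an inverted or degenerate capture.
#'
#' @param image a [measurement()] or numeric matrix of the capture.
#' @param feature_px annotation for the returned mask.
#' @param expected_fill optional design fill fraction; a deviation beyond
#'   `0.05` raises a warning.
#' @return A [coded_mask()] with attribute `fill_fraction`.
#' @export
mask_from_monochromatic <- function(image, feature_px = 1L,
                                    expected_fill = NULL) {
  X <- if (inherits(image, "cassi_measurement")) image$data else image
  thr <- otsu_threshold(X)
  pat <- (X > thr) * 1
  fill <- mean(pat)
  if (!is.null(expected_fill) && abs(fill - expected_fill) > 0.05)
    warning(sprintf(
      "recovered fill fraction %.3f deviates from expected %.3f; capture may be inverted or degraded",
      fill, expected_fill), call. = FALSE)
  m <- coded_mask(pat, feature_px = feature_px)
  attr(m, "fill_fraction") <- fill
  m
}

#' Resolution report
#'
#' Bundles spectral and spatial resolution calibration into one record.
#'
#' @param model a [dispersion_model()].
#' @param feature_px mask feature size in pixels.
#' @param group_contrasts_h,group_contrasts_v optional named contrast vectors
#'   (names in lp/mm) for horizontal and vertical bars.
#' @param threshold contrast threshold for resolvability.
#' @return An object of class `resolution_report` (a list), serializable with
#'   [write_resolution_report()].
#' @export
resolution_report <- function(model, feature_px = 2L,
                              group_contrasts_h = NULL,
                              group_contrasts_v = NULL,
                              threshold = 0.4) {
  bp <- model$breakpoints
  bands <- data.frame(
    lambda_lo_nm = bp$lambda_lo_nm, lambda_hi_nm = bp$lambda_hi_nm,
    nm_per_pixel = bp$nm_per_pixel,
    resolution_nm = as.numeric(spectral_resolution(bp$nm_per_pixel,
                                                   feature_px)))
  avg <- average_spectral_resolution(model, feature_px)
  rep <- list(bands = bands,
              average_resolution_nm = as.numeric(avg),
              average_resolution_exact_nm = attr(avg, "exact"),
              feature_px = feature_px)
  for (dir in c("h", "v")) {
    gc <- get(paste0("group_contrasts_", dir))
    if (!is.null(gc)) {
      lim <- resolvable_limit(gc, threshold)
      rep[[paste0("limit_lpmm_", dir)]] <- lim
      rep[[paste0("resolution_um_", dir)]] <-
        if (is.na(lim)) NA_real_ else as.numeric(lpmm_to_micron(lim))
      rep[[paste0("contrasts_", dir)]] <- as.list(gc)
    }
  }
  structure(rep, class = "resolution_report")
}

#' @rdname resolution_report
#' @param report a `resolution_report`.
#' @param path JSON output path.
#' @export
write_resolution_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
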