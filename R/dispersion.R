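#' Prism dispersion model
#'
#' The prism's dispersion is piecewise: over each wavelength interval the
#' camera-plane dispersion is a constant number of nanometres per pixel.
#' The lateral shift of a band is the integral of `1 / (nm per pixel)` from
#' the reference wavelength, so shorter intervals with stronger dispersion
#' shear further per nanometre.
#'
#' @param breakpoints data frame with columns `lambda_lo_nm`, `lambda_hi_nm`,
#'   `nm_per_pixel`: contiguous intervals with positive dispersion.
#' @param reference_wavelength wavelength (nm) at which the shift is zero;
#'   defaults to the start of the covered range.
#' @return An object of class `dispersion_model`.
#' @export
dispersion_model <- function(breakpoints, reference_wavelength = NULL) {
  bp <- as.data.frame(breakpoints)
  need <- c("lambda_lo_nm", "lambda_hi_nm", "nm_per_pixel")
  if (!all(need %in% names(bp)))
    stop("breakpoints need columns lambda_lo_nm, lambda_hi_nm, nm_per_pixel",
         call. = FALSE)
  bp <- bp[order(bp$lambda_lo_nm), , drop = FALSE]
  if (any(bp$nm_per_pixel <= 0))
    stop("dispersion values must be positive", call. = FALSE)
  if (any(bp$lambda_hi_nm <= bp$lambda_lo_nm))
    stop("each interval must have lambda_hi_nm > lambda_lo_nm", call. = FALSE)
  if (nrow(bp) > 1 &&
      any(abs(bp$lambda_lo_nm[-1L] - bp$lambda_hi_nm[-nrow(bp)]) > 1e-9))
    stop("intervals must be contiguous", call. = FALSE)
  if (is.null(reference_wavelength)) reference_wavelength <- bp$lambda_lo_nm[1L]
  lo <- bp$lambda_lo_nm[1L]; hi <- bp$lambda_hi_nm[nrow(bp)]
  if (reference_wavelength < lo || reference_wavelength > hi)
    stop("reference_wavelength outside the covered range", call. = FALSE)
  structure(list(breakpoints = bp,
                 reference_wavelength = reference_wavelength),
            class = "dispersion_model")
}

#' @export
print.dispersion_model <- function(x, ...) {
  cat(sprintf("<dispersion_model> %d interval(s), %.0f-%.0f nm, reference %.0f nm\n",
              nrow(x$breakpoints), x$breakpoints$lambda_lo_nm[1L],
              x$breakpoints$lambda_hi_nm[nrow(x$breakpoints)],
              x$reference_wavelength))
  invisible(x)
}

#' Uniform (toy) dispersion model
#'
#' @param nm_per_pixel constant dispersion.
#' @param lo,hi covered wavelength range in nm.
#' @param reference_wavelength zero-shift wavelength (default `lo`).
#' @return A [dispersion_model()].
#' @export
uniform_dispersion <- function(nm_per_pixel, lo, hi, reference_wavelength = lo) {
  dispersion_model(data.frame(lambda_lo_nm = lo, lambda_hi_nm = hi,
                              nm_per_pixel = nm_per_pixel),
                   reference_wavelength = reference_wavelength)
}

#' Packaged camera dispersion table
#'
#' The measured camera-plane pixel dispersion of the imager's wedge prism over
#' 445-602 nm, in four piecewise-constant bands. Shipped as
#' `extdata/dispersion_default.csv`.
#'
#' @param reference_wavelength zero-shift wavelength (default 445 nm).
#' @return A [dispersion_model()].
#' @export
default_dispersion <- function(reference_wavelength = 445) {
  path <- system.file("extdata", "dispersion_default.csv", package = "cassir",
                      mustWork = TRUE)
  read_dispersion_csv(path, reference_wavelength = reference_wavelength)
}

#' Read / write a dispersion table CSV
#'
#' Columns: `lambda_lo_nm, lambda_hi_nm, nm_per_pixel`.
#'
#' @param path CSV path.
#' @param reference_wavelength passed to [dispersion_model()].
#' @return `read_dispersion_csv` returns a [dispersion_model()].
#' @export
read_dispersion_csv <- function(path, reference_wavelength = NULL) {
  if (!file.exists(path))
    stop(sprintf("no such dispersion table: '%s'", path), call. = FALSE)
  bp <- utils::read.csv(path)
  dispersion_model(bp, reference_wavelength = reference_wavelength)
}

#' @rdname read_dispersion_csv
#' @param model a [dispersion_model()].
#' @export
write_dispersion_csv <- function(model, path) {
  utils::write.csv(model$breakpoints, path, row.names = FALSE)
  invisible(path)
}

# Continuous shift in pixels at wavelength lambda: integral of
# d(lambda') / nm_per_pixel(lambda') from the reference wavelength.
dispersion_shift <- function(model, lambda) {
  bp <- model$breakpoints
  lo <- bp$lambda_lo_nm[1L]; hi <- bp$lambda_hi_nm[nrow(bp)]
  if (any(lambda < lo - 1e-9) || any(lambda > hi + 1e-9))
    stop(sprintf("wavelength outside dispersion range [%.6g, %.6g] nm", lo, hi),
         call. = FALSE)
  at <- function(x) {
    # cumulative integral from range start
    s <- 0
    for (j in seq_len(nrow(bp))) {
      a <- bp$lambda_lo_nm[j]; b <- bp$lambda_hi_nm[j]
      s <- s + max(0, min(x, b) - a) / bp$nm_per_pixel[j]
      if (x <= b) break
    }
    s
  }
  vapply(lambda, at, 0) - at(model$reference_wavelength)
}

#' Integer pixel shift per band
#'
#' Converts band-center wavelengths to integer lateral pixel shifts at the
#' detector by integrating the reciprocal dispersion from the model's
#' reference wavelength and rounding to the nearest pixel. Shifts are
#' non-decreasing in wavelength and zero at the reference.
#'
#' @param model a [dispersion_model()].
#' @param wavelengths band-center wavelengths in nm, all inside the model's
#'   covered range.
#' @return Integer vector of pixel shifts, one per wavelength.
#' @export
band_shifts <- function(model, wavelengths) {
  as.integer(round(dispersion_shift(model, wavelengths)))
}
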