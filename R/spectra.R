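#' Spectrum
#'
#' A 1-D intensity-versus-wavelength record in relative units.
#'
#' @param wavelengths strictly increasing wavelengths in nm.
#' @param values numeric values, same length.
#' @return An object of class `cassi_spectrum`.
#' @export
spectrum <- function(wavelengths, values) {
  wavelengths <- as.numeric(wavelengths); values <- as.numeric(values)
  if (length(wavelengths) != length(values))
    stop("wavelengths and values must have equal length", call. = FALSE)
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  structure(list(wavelengths = wavelengths, values = values),
            class = "cassi_spectrum")
}

#' @export
print.cassi_spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d samples, %.1f-%.1f nm\n", length(x$values),
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' Region of interest
#'
#' @param mask logical (or 0/1) matrix over `(rows, cols)`; at least one
#'   pixel must be selected.
#' @return A logical matrix of class `roi`.
#' @export
roi <- function(mask) {
  if (!is.matrix(mask)) stop("roi must be a matrix", call. = FALSE)
  mask <- mask != 0
  if (!any(mask)) stop("roi selects no pixels", call. = FALSE)
  structure(mask, class = c("roi", class(mask)))
}

#' Circular region of interest
#'
#' @param rows,cols image shape.
#' @param center `(row, col)` center.
#' @param radius radius in pixels.
#' @return An [roi()].
#' @export
circular_roi <- function(rows, cols, center, radius) {
  rr <- outer(seq_len(rows) - center[1L], rep(1, cols))
  cc <- outer(rep(1, rows), seq_len(cols) - center[2L])
  roi(rr^2 + cc^2 <= radius^2)
}

#' Field-averaged spectrum over a region
#'
#' Per-band mean of the cube over the selected pixels; the wavelength grid is
#' taken from the cube.
#'
#' @param cube a [spectral_cube()].
#' @param region an [roi()] (or logical matrix) matching the cube's spatial
#'   shape; `NULL` averages the whole field.
#' @return A [spectrum()].
#' @export
field_average_spectrum <- function(cube, region = NULL) {
  d <- dim(cube$data)
  if (is.null(region)) region <- matrix(TRUE, d[1L], d[2L])
  if (!all(dim(region) == d[1:2]))
    stop("roi shape does not match the cube", call. = FALSE)
  sel <- which(region != 0)
  if (length(sel) == 0) stop("roi selects no pixels", call. = FALSE)
  Z <- matrix(cube$data, d[1L] * d[2L], d[3L])
  spectrum(cube$wavelengths, colMeans(Z[sel, , drop = FALSE]))
}

#' Absorption spectrum from reflectance and illumination
#'
#' The absorption spectrum is the difference of the max-normalized
#' illumination and reflectance spectra:
#' `S_a = S_i / max(S_i) - S_r / max(S_r)`. Wavelengths where the tissue
#' absorbs depress the reflectance relative to the lamp, producing peaks in
#' `S_a`. The result is invariant to positive rescaling of either input.
#'
#' @param S_r reflectance [spectrum()].
#' @param S_i illumination [spectrum()], on the same wavelength grid.
#' @return A [spectrum()] of the absorption signature.
#' @export
absorption_spectrum <- function(S_r, S_i) {
  if (length(S_r$wavelengths) != length(S_i$wavelengths) ||
      any(abs(S_r$wavelengths - S_i$wavelengths) > 1e-9))
    stop("reflectance and illumination must share a wavelength grid",
         call. = FALSE)
  mi <- max(S_i$values); mr <- max(S_r$values)
  if (mi <= 0 || mr <= 0)
    stop("spectra must have a positive maximum", call. = FALSE)
  spectrum(S_r$wavelengths, S_i$values / mi - S_r$values / mr)
}

# 3-point moving average, replicate ends
smooth3 <- function(v) {
  n <- length(v)
  (c(v[1L], v[-n]) + v + c(v[-1L], v[n])) / 3
}

# prominence of a local maximum: height above the higher of the two deepest
# valleys separating it from higher ground (or the record edge)
peak_prominence <- function(v, idx) {
  n <- length(v)
  vapply(idx, function(i) {
    left <- v[seq_len(i - 1L)]
    right <- if (i < n) v[(i + 1L):n] else numeric(0)
    lmin <- Inf; rmin <- Inf
    if (length(left)) {
      higher <- which(left > v[i])
      from <- if (length(higher)) max(higher) + 1L else 1L
      lmin <- min(left[from:length(left)])
    }
    if (length(right)) {
      higher <- which(right > v[i])
      to <- if (length(higher)) min(higher) - 1L else length(right)
      rmin <- if (to >= 1L) min(right[1:to]) else Inf
    }
    base <- max(min(lmin, v[i]), min(rmin, v[i]))
    if (!is.finite(base)) base <- min(v)
    v[i] - base
  }, 0)
}

#' Locate absorption peaks
#'
#' Lightly smooths the spectrum (3-point moving average), finds local maxima
#' and ranks them by prominence. Peaks closer than `window_nm` to a more
#' prominent accepted peak are suppressed.
#'
#' @param S_a a [spectrum()] with at least 5 samples.
#' @param window_nm minimum separation between reported peaks (nm).
#' @return Numeric vector of peak wavelengths ordered by decreasing
#'   prominence, with the prominences as `attr(, "prominence")`; empty for a
#'   monotone spectrum.
#' @export
find_absorption_peaks <- function(S_a, window_nm = 15) {
  v <- S_a$values
  if (length(v) < 5) stop("need at least 5 samples", call. = FALSE)
  s <- smooth3(v)
  n <- length(s)
  cand <- which(s[2:(n - 1L)] > s[1:(n - 2L)] &
                s[2:(n - 1L)] >= s[3:n]) + 1L
  if (length(cand) == 0) return(numeric(0))
  # snap each smoothed maximum back to the raw argmax of its neighborhood
  # (smoothing turns an isolated spike into a plateau starting one sample
  # early)
  cand <- vapply(cand, function(i) {
    nb <- max(1L, i - 1L):min(n, i + 1L)
    nb[which.max(v[nb])]
  }, 0L)
  cand <- unique(cand)
  prom <- peak_prominence(s, cand)
  ord <- order(prom, decreasing = TRUE)
  cand <- cand[ord]; prom <- prom[ord]
  keep <- logical(length(cand))
  for (j in seq_along(cand)) {
    w <- S_a$wavelengths[cand[j]]
    if (!any(keep & abs(S_a$wavelengths[cand] - w) < window_nm))
      keep[j] <- TRUE
  }
  structure(S_a$wavelengths[cand[keep]], prominence = prom[keep])
}

#' Read / write spectrum CSV
#'
#' Columns `wavelength_nm, value`.
#'
#' @param path CSV path.
#' @return `read_spectrum_csv` returns a [spectrum()].
#' @export
read_spectrum_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path), call. = FALSE)
  df <- utils::read.csv(path)
  spectrum(df$wavelength_nm, df$value)
}

#' @rdname read_spectrum_csv
#' @param s a [spectrum()].
#' @export
write_spectrum_csv <- function(s, path) {
  utils::write.csv(data.frame(wavelength_nm = s$wavelengths, value = s$values),
                   path, row.names = FALSE)
  invisible(path)
}
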