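#' Coded aperture mask
#'
#' The binary transmission pattern placed at the image plane. It modulates
#' every spectral band identically before the prism shears the bands apart.
#'
#' @param pattern numeric/integer matrix with values in `{0, 1}`.
#' @param feature_px sensor pixels per smallest mask feature (`>= 1`); the
#'   instrument samples each feature with about 2 x 2 pixels.
#' @return An object of class `coded_mask`.
#' @export
coded_mask <- function(pattern, feature_px = 1L) {
  if (!is.matrix(pattern)) stop("mask pattern must be a matrix", call. = FALSE)
  storage.mode(pattern) <- "double"
  if (!all(pattern %in% c(0, 1)))
    stop("mask pattern must be binary {0, 1}", call. = FALSE)
  feature_px <- as.integer(feature_px)
  if (feature_px < 1L) stop("feature_px must be >= 1", call. = FALSE)
  structure(list(pattern = pattern, feature_px = feature_px),
            class = "coded_mask")
}

#' @export
dim.coded_mask <- function(x) dim(x$pattern)

#' @export
print.coded_mask <- function(x, ...) {
  cat(sprintf("<coded_mask> %d x %d, fill %.3f, feature %d px\n",
              nrow(x$pattern), ncol(x$pattern), mean(x$pattern), x$feature_px))
  invisible(x)
}

#' Detector noise model
#'
#' @param kind one of `"none"`, `"gaussian"` (additive, std `sigma` counts) or
#'   `"poisson-gaussian"` (shot noise at `gain` counts/photon plus additive
#'   Gaussian read noise).
#' @param sigma Gaussian standard deviation in counts, `>= 0`.
#' @param gain counts per photon, `> 0`.
#' @param seed integer RNG seed; the same seed reproduces the same frame.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(kind = c("none", "gaussian", "poisson-gaussian"),
                        sigma = 0, gain = 1, seed = 0L) {
  kind <- match.arg(kind)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (gain <= 0) stop("gain must be > 0", call. = FALSE)
  structure(list(kind = kind, sigma = sigma, gain = gain,
                 seed = as.integer(seed)),
            class = "noise_model")
}

apply_noise <- function(y, noise) {
  if (is.null(noise) || noise$kind == "none") return(y)
  withr::with_seed(noise$seed, {
    if (noise$kind == "poisson-gaussian") {
      y <- noise$gain * matrix(stats::rpois(length(y), pmax(y, 0) / noise$gain),
                               nrow(y), ncol(y))
    }
    if (noise$sigma > 0)
      y <- y + matrix(stats::rnorm(length(y), sd = noise$sigma),
                      nrow(y), ncol(y))
    y
  })
}

#' Sensing operator
#'
#' The linear map from a spectral datacube to a snapshot measurement:
#' elementwise mask modulation, an integer column shift per band (the prism
#' shear), and summation over bands onto an extended detector canvas of width
#' `cols + max(shift)`. Keeping the full dispersed footprint makes the
#' adjoint exact.
#'
#' @param mask a [coded_mask()] whose pattern matches the scene rows/cols.
#' @param shifts non-decreasing integer pixel shifts, one per band. Either
#'   given directly or derived from `dispersion` and `wavelengths`.
#' @param scene_dim integer vector `(rows, cols, bands)`.
#' @param dispersion optional [dispersion_model()] used with `wavelengths`
#'   when `shifts` is missing.
#' @param wavelengths band-center wavelengths (nm), required with
#'   `dispersion`.
#' @return An object of class `sensing_operator`.
#' @export
sensing_operator <- function(mask, scene_dim, shifts = NULL,
                             dispersion = NULL, wavelengths = NULL) {
  scene_dim <- as.integer(scene_dim)
  stopifnot(length(scene_dim) == 3L, all(scene_dim >= 1L))
  if (is.null(shifts)) {
    if (is.null(dispersion) || is.null(wavelengths))
      stop("supply either shifts or dispersion + wavelengths", call. = FALSE)
    shifts <- band_shifts(dispersion, wavelengths)
  }
  shifts <- as.integer(shifts)
  if (length(shifts) != scene_dim[3L])
    stop("one shift per band required", call. = FALSE)
  if (any(diff(shifts) < 0L))
    stop("shifts must be non-decreasing with band index", call. = FALSE)
  shifts <- shifts - min(shifts)   # anchor the canvas at the first band
  if (!all(dim(mask$pattern) == scene_dim[1:2]))
    stop(sprintf("mask is %d x %d but scene is %d x %d",
                 nrow(mask$pattern), ncol(mask$pattern),
                 scene_dim[1L], scene_dim[2L]), call. = FALSE)
  structure(list(mask = mask, shifts = shifts, scene_dim = scene_dim),
            class = "sensing_operator")
}

measurement_dim <- function(op) {
  c(op$scene_dim[1L], op$scene_dim[2L] + max(op$shifts))
}

#' @export
print.sensing_operator <- function(x, ...) {
  cat(sprintf("<sensing_operator> scene %d x %d x %d -> measurement %d x %d\n",
              x$scene_dim[1L], x$scene_dim[2L], x$scene_dim[3L],
              measurement_dim(x)[1L], measurement_dim(x)[2L]))
  invisible(x)
}

#' Mask modulation
#'
#' Multiplies every band of the cube elementwise by the coded mask. The
#' wavelength grid is unchanged.
#'
#' @param cube a [spectral_cube()].
#' @param mask a [coded_mask()] with the cube's spatial shape.
#' @return A [spectral_cube()].
#' @export
apply_mask <- function(cube, mask) {
  d <- dim(cube$data)
  if (!all(dim(mask$pattern) == d[1:2]))
    stop(sprintf("mask is %d x %d but cube is %d x %d",
                 nrow(mask$pattern), ncol(mask$pattern), d[1L], d[2L]),
         call. = FALSE)
  spectral_cube(array(as.vector(mask$pattern) * as.vector(cube$data), dim = d),
                cube$wavelengths)
}

check_cube_op <- function(data, op) {
  if (!all(dim(data) == op$scene_dim))
    stop(sprintf("cube is %s but operator scene is %s",
                 paste(dim(data), collapse = "x"),
                 paste(op$scene_dim, collapse = "x")), call. = FALSE)
}

# shift-and-add core on raw arrays (no noise); linear in the input
forward_raw <- function(arr, op) {
  check_cube_op(arr, op)
  d <- op$scene_dim
  M <- op$mask$pattern
  Y <- matrix(0, d[1L], d[2L] + max(op$shifts))
  for (k in seq_len(d[3L])) {
    s <- op$shifts[k]
    idx <- (s + 1L):(s + d[2L])
    Y[, idx] <- Y[, idx] + arr[, , k] * M
  }
  Y
}

adjoint_raw <- function(Y, op) {
  d <- op$scene_dim
  if (!all(dim(Y) == measurement_dim(op)))
    stop(sprintf("measurement is %s but operator expects %s",
                 paste(dim(Y), collapse = "x"),
                 paste(measurement_dim(op), collapse = "x")), call. = FALSE)
  M <- op$mask$pattern
  out <- array(0, d)
  for (k in seq_len(d[3L])) {
    s <- op$shifts[k]
    out[, , k] <- M * Y[, (s + 1L):(s + d[2L])]
  }
  out
}

#' Forward projection: cube to snapshot
#'
#' Applies the sensing operator (mask, per-band shear, band sum) and then the
#' noise model. The noiseless map is linear in the cube.
#'
#' @param cube a [spectral_cube()] matching the operator's scene shape.
#' @param op a [sensing_operator()].
#' @param noise a [noise_model()] or `NULL` for noiseless.
#' @return A [measurement()] of width `cols + max(shift)`.
#' @export
forward_project <- function(cube, op, noise = NULL) {
  Y <- forward_raw(cube$data, op)
  Y <- apply_noise(Y, noise)
  meta <- list(
    noise = if (is.null(noise)) list(kind = "none")
            else noise[c("kind", "sigma", "gain", "seed")],
    shifts = op$shifts)
  measurement(Y, meta = meta)
}

#' Adjoint projection: snapshot to cube
#'
#' The transpose of the sensing map: each band is the measurement window
#' shifted back by that band's shear and re-modulated by the mask. Together
#' with [forward_project()] it satisfies `<Phi f, y> == <f, Phi^T y>`.
#'
#' @param m a [measurement()] (or matrix) of the operator's measurement shape.
#' @param op a [sensing_operator()].
#' @param wavelengths wavelength grid for the returned cube; defaults to the
#'   band index when unknown.
#' @return A [spectral_cube()]. Negative values can occur for noisy input, so
#'   the raw array is returned in the `data` slot without clipping via
#'   an internal constructor.
#' @export
adjoint_project <- function(m, op, wavelengths = NULL) {
  Y <- if (inherits(m, "cassi_measurement")) m$data else m
  arr <- adjoint_raw(Y, op)
  if (is.null(wavelengths)) wavelengths <- seq_len(op$scene_dim[3L])
  cube_unchecked(arr, wavelengths)
}

# internal: skip the nonnegativity check (adjoints/iterates may go negative)
cube_unchecked <- function(data, wavelengths) {
  structure(list(data = data, wavelengths = as.numeric(wavelengths)),
            class = "spectral_cube")
}

#' Diagonal of Phi Phi^T
#'
#' Because each datacube voxel hits exactly one detector pixel, `Phi Phi^T` is
#' diagonal; its diagonal at measurement pixel `(r, c)` is the sum of squared
#' mask transmissions of the bands whose shear places a scene column there.
#' This is what makes the data-fidelity solve of the reconstruction one-shot.
#'
#' @param op a [sensing_operator()].
#' @return Matrix of the measurement shape.
#' @export
phi_phit_diag <- function(op) {
  d <- op$scene_dim
  D <- matrix(0, d[1L], d[2L] + max(op$shifts))
  M2 <- op$mask$pattern^2
  for (k in seq_len(d[3L])) {
    s <- op$shifts[k]
    idx <- (s + 1L):(s + d[2L])
    D[, idx] <- D[, idx] + M2
  }
  D
}

#' Dense sensing matrix (small-instance oracle)
#'
#' Materializes Phi as a dense matrix acting on column-major vectorized cubes,
#' for cross-checking the matrix-free forward/adjoint on small instances.
#'
#' @param op a [sensing_operator()] with at most `max_voxels` scene voxels.
#' @param max_voxels refusal threshold (default `1e4`).
#' @return A dense matrix of dim `(rows * width) x (rows * cols * bands)`.
#' @export
dense_phi <- function(op, max_voxels = 1e4) {
  d <- op$scene_dim
  nvox <- prod(d)
  if (nvox > max_voxels)
    stop(sprintf("instance too large for a dense matrix (%d > %g voxels)",
                 nvox, max_voxels), call. = FALSE)
  md <- measurement_dim(op)
  Phi <- matrix(0, prod(md), nvox)
  M <- op$mask$pattern
  for (k in seq_len(d[3L])) {
    s <- op$shifts[k]
    for (cc in seq_len(d[2L])) {
      for (r in seq_len(d[1L])) {
        vox <- r + (cc - 1L) * d[1L] + (k - 1L) * d[1L] * d[2L]
        pix <- r + (cc + s - 1L) * md[1L]
        Phi[pix, vox] <- M[r, cc]
      }
    }
  }
  Phi
}
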