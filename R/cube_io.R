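#' Spectral datacube
#'
#' A spectral datacube is a nonnegative 3-D array over two spatial axes and a
#' wavelength axis, together with the band-center wavelengths in nanometres.
#' The column axis is the dispersion axis of the imager; the row axis is
#' orthogonal to it. Radiometry is relative: no absolute units are enforced.
#'
#' @param data numeric 3-D array `(rows, cols, bands)`, finite and `>= 0`.
#' @param wavelengths strictly increasing numeric vector of band-center
#'   wavelengths in nm, one per band.
#' @return An object of class `spectral_cube` with elements `data` and
#'   `wavelengths`.
#' @export
spectral_cube <- function(data, wavelengths) {
  data <- as_cube_array(data)
  wavelengths <- as.numeric(wavelengths)
  x <- structure(list(data = data, wavelengths = wavelengths),
                 class = "spectral_cube")
  validate_cube(x)
}

as_cube_array <- function(data) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("cube data must be a 3-D array (rows, cols, bands)", call. = FALSE)
  storage.mode(data) <- "double"
  data
}

validate_cube <- function(x) {
  d <- dim(x$data)
  if (d[3L] != length(x$wavelengths))
    stop(sprintf("band count (%d) must equal length(wavelengths) (%d)",
                 d[3L], length(x$wavelengths)), call. = FALSE)
  if (anyNA(x$wavelengths) || any(diff(x$wavelengths) <= 0))
    stop("wavelengths must be strictly increasing and finite", call. = FALSE)
  if (!all(is.finite(x$data)))
    stop("cube values must be finite", call. = FALSE)
  if (any(x$data < 0))
    stop("cube values must be nonnegative", call. = FALSE)
  x
}

#' @export
dim.spectral_cube <- function(x) dim(x$data)

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<spectral_cube> %d x %d pixels, %d bands (%.1f-%.1f nm)\n",
              d[1L], d[2L], d[3L], min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' Snapshot measurement
#'
#' A single 2-D detector frame: the dispersed, mask-modulated projection of a
#' spectral datacube. The frame is wider than the scene because each band is
#' sheared along the column axis before summation.
#'
#' @param data numeric matrix of detector counts, finite.
#' @param meta optional named list of provenance (mask id, dispersion id,
#'   noise parameters, seed).
#' @return An object of class `cassi_measurement`.
#' @export
measurement <- function(data, meta = list()) {
  if (!is.matrix(data)) stop("measurement data must be a matrix", call. = FALSE)
  storage.mode(data) <- "double"
  if (!all(is.finite(data)))
    stop("measurement values must be finite", call. = FALSE)
  structure(list(data = data, meta = meta), class = "cassi_measurement")
}

#' @export
dim.cassi_measurement <- function(x) dim(x$data)

#' @export
print.cassi_measurement <- function(x, ...) {
  cat(sprintf("<cassi_measurement> %d x %d pixels\n", nrow(x$data), ncol(x$data)))
  invisible(x)
}

#' Sensor geometry
#'
#' @param pixel_pitch pixel pitch in micrometres, `> 0`.
#' @param rows,cols detector pixel counts, `>= 1`.
#' @return An object of class `sensor_geometry`.
#' @export
sensor_geometry <- function(pixel_pitch, rows, cols) {
  stopifnot(pixel_pitch > 0, rows >= 1, cols >= 1)
  structure(list(pixel_pitch = pixel_pitch,
                 rows = as.integer(rows), cols = as.integer(cols)),
            class = "sensor_geometry")
}

sidecar_path <- function(path) paste0(path, ".json")

is_whole <- function(x) all(abs(x - round(x)) < .Machine$double.eps * 4 * pmax(1, abs(x)))

# TIFF pages must live in [0, 1]; the sidecar records the scale used so
# loading restores the original values (exactly for 16-bit integer data).
tiff_pack <- function(data) {
  mx <- max(data)
  if (mx <= 65535 && is_whole(data)) {
    list(scale = 65535, bits = 16L, integer = TRUE)
  } else {
    list(scale = if (mx > 0) mx else 1, bits = 32L, integer = FALSE)
  }
}

#' Save and load spectral datacubes
#'
#' Cubes are written as multi-page grayscale TIFF (one page per band, pages in
#' ascending wavelength order) with a JSON sidecar `<path>.json` that records
#' the wavelength grid and the radiometric scale. The sidecar is authoritative
#' for the wavelength metadata. Integer-valued cubes round-trip bit exactly
#' (16-bit pages); floating-point cubes round-trip to within `1e-6` relative
#' error (32-bit float pages).
#'
#' @param cube a [spectral_cube()].
#' @param path output TIFF path; the sidecar is written next to it.
#' @return `save_cube` returns `path` invisibly; `load_cube` returns a
#'   [spectral_cube()].
#' @export
save_cube <- function(cube, path) {
  validate_cube(cube)
  pk <- tiff_pack(cube$data)
  L <- dim(cube$data)[3L]
  pages <- lapply(seq_len(L), function(k) cube$data[, , k] / pk$scale)
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = pk$bits), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop(sprintf("cannot write cube to '%s'", path), call. = FALSE)
  jsonlite::write_json(
    list(wavelengths_nm = cube$wavelengths, scale = pk$scale,
         integer = pk$integer),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_sidecar <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop(sprintf("wavelengths unavailable: missing sidecar '%s'", sc),
         call. = FALSE)
  jsonlite::read_json(sc, simplifyVector = TRUE)
}

read_tiff_pages <- function(path) {
  pages <- try(tiff::readTIFF(path, all = TRUE), silent = TRUE)
  if (inherits(pages, "try-error"))
    stop(sprintf("cannot parse TIFF '%s': %s", path,
                 attr(pages, "condition")$message), call. = FALSE)
  if (is.matrix(pages)) pages <- list(pages)
  pages
}

unpack_pages <- function(pages, side) {
  scale <- if (is.null(side$scale)) 1 else side$scale
  arr <- vapply(pages, function(p) p * scale,
                matrix(0, nrow(pages[[1L]]), ncol(pages[[1L]])))
  if (isTRUE(side$integer)) arr <- round(arr)
  arr
}

#' @rdname save_cube
#' @export
load_cube <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path), call. = FALSE)
  side <- read_sidecar(path)
  pages <- read_tiff_pages(path)
  w <- side$wavelengths_nm
  if (is.null(w))
    stop("wavelengths unavailable: sidecar lacks 'wavelengths_nm'", call. = FALSE)
  if (length(pages) != length(w))
    stop(sprintf("metadata mismatch: %d TIFF pages but %d wavelengths",
                 length(pages), length(w)), call. = FALSE)
  spectral_cube(unpack_pages(pages, side), w)
}

#' Save and load snapshot measurements
#'
#' Measurements are single-page grayscale TIFF frames with a JSON sidecar
#' holding the radiometric scale and provenance metadata. Integer count frames
#' round-trip exactly.
#'
#' @param m a [measurement()].
#' @param path TIFF path.
#' @return `save_measurement` returns `path` invisibly; `load_measurement`
#'   returns a [measurement()].
#' @export
save_measurement <- function(m, path) {
  if (!inherits(m, "cassi_measurement")) m <- measurement(m)
  if (any(m$data < 0))
    stop("measurement values must be nonnegative for storage", call. = FALSE)
  pk <- tiff_pack(m$data)
  ok <- try(tiff::writeTIFF(m$data / pk$scale, path, bits.per.sample = pk$bits),
            silent = TRUE)
  if (inherits(ok, "try-error"))
    stop(sprintf("cannot write measurement to '%s'", path), call. = FALSE)
  jsonlite::write_json(
    list(scale = pk$scale, integer = pk$integer, meta = m$meta),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_measurement
#' @export
load_measurement <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path), call. = FALSE)
  pages <- read_tiff_pages(path)
  side <- if (file.exists(sidecar_path(path))) read_sidecar(path)
          else list(scale = 1, integer = FALSE, meta = list())
  dat <- unpack_pages(pages[1L], side)[, , 1L]
  if (any(dat < 0)) stop("measurement contains negative values", call. = FALSE)
  measurement(dat, meta = if (is.null(side$meta)) list() else side$meta)
}

#' Save and load coded masks
#'
#' Binary masks are stored as single-channel PNG images (0 = opaque,
#' 255 = transmitting); they round-trip exactly.
#'
#' @param mask a [coded_mask()].
#' @param path PNG path.
#' @return `save_mask` returns `path` invisibly; `load_mask` a [coded_mask()].
#' @export
save_mask <- function(mask, path) {
  stopifnot(inherits(mask, "coded_mask"))
  png::writePNG(mask$pattern, path)
  invisible(path)
}

#' @rdname save_mask
#' @param feature_px sensor pixels per smallest mask feature, used to annotate
#'   the loaded mask.
#' @export
load_mask <- function(path, feature_px = 1L) {
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path), call. = FALSE)
  img <- try(png::readPNG(path), silent = TRUE)
  if (inherits(img, "try-error"))
    stop(sprintf("cannot parse PNG '%s'", path), call. = FALSE)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  vals <- sort(unique(as.vector(img)))
  if (!all(vals %in% c(0, 1)))
    stop("mask image is not binary; threshold it first (see mask_from_monochromatic)",
         call. = FALSE)
  coded_mask(img, feature_px = feature_px)
}
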