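#' Solver configuration
#'
#' Settings for the augmented-Lagrangian/ADMM reconstruction. Penalty
#' schedules are recycled to `n_iterations`; the defaults (constant
#' `gamma1 = gamma2 = 1`) suit the classic priors, while [train_unfolded()]
#' learns per-stage values.
#'
#' @param n_iterations number of outer iterations (`>= 1`). The unfolded
#'   network uses 4; classic priors typically use more (e.g. 50).
#' @param gamma1,gamma2 positive penalty parameters, scalar or one per
#'   iteration.
#' @param denoiser a [denoiser()] (default isotropic TV).
#' @param strength denoiser strength, scalar or one per iteration. By
#'   convention the effective strength of iteration `i` is
#'   `strength[i] / gamma2[i]`: a stiffer quadratic coupling means a milder
#'   denoising move.
#' @param tol optional relative-change stopping tolerance (`0` disables;
#'   fixed-depth unfolding keeps it at `0`).
#' @param seed integer seed recorded for provenance.
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(n_iterations = 50L, gamma1 = 1, gamma2 = 1,
                          denoiser = cassir::denoiser("tv"), strength = 0.1,
                          tol = 0, seed = 0L) {
  n_iterations <- as.integer(n_iterations)
  if (n_iterations < 1L) stop("n_iterations must be >= 1", call. = FALSE)
  if (any(gamma1 < 0) || any(gamma2 <= 0))
    stop("penalties must satisfy gamma1 >= 0, gamma2 > 0", call. = FALSE)
  if (tol < 0) stop("tol must be >= 0", call. = FALSE)
  structure(list(n_iterations = n_iterations,
                 gamma1 = rep_len(gamma1, n_iterations),
                 gamma2 = rep_len(gamma2, n_iterations),
                 denoiser = denoiser,
                 strength = rep_len(strength, n_iterations),
                 tol = tol, seed = as.integer(seed)),
            class = "solver_config")
}

# Solve (gamma2 I + gamma1 Phi^T Phi) x = b in one shot. Phi Phi^T is
# diagonal, so by the Woodbury identity
#   x = b/gamma2 - Phi^T [ Phi b / (1/gamma1 + diag/gamma2) ] / gamma2^2 .
al_solve <- function(b, op, gamma1, gamma2) {
  if (gamma2 <= 0) stop("gamma2 must be > 0", call. = FALSE)
  if (gamma1 < 0) stop("gamma1 must be >= 0", call. = FALSE)
  if (gamma1 == 0) return(b / gamma2)
  d <- phi_phit_diag(op)
  w <- forward_raw(b, op) / (1 / gamma1 + d / gamma2)
  b / gamma2 - adjoint_raw(w, op) / gamma2^2
}

#' Reconstruction initialization
#'
#' Computes `f0 = (gamma2 I + gamma1 Phi^T Phi)^-1 Phi^T y` without a dense
#' inverse, exploiting the diagonal structure of `Phi Phi^T`.
#'
#' @param y a [measurement()] (or matrix).
#' @param op a [sensing_operator()].
#' @param gamma1 nonnegative penalty (`0` reduces to `Phi^T y / gamma2`).
#' @param gamma2 positive penalty.
#' @param wavelengths optional wavelength grid for the returned cube.
#' @return A [spectral_cube()] (values may be negative; no clipping here).
#' @export
admm_initialize <- function(y, op, gamma1 = 1, gamma2 = 1,
                            wavelengths = NULL) {
  Y <- if (inherits(y, "cassi_measurement")) y$data else y
  x <- al_solve(adjoint_raw(Y, op), op, gamma1, gamma2)
  if (is.null(wavelengths)) wavelengths <- seq_len(op$scene_dim[3L])
  cube_unchecked(x, wavelengths)
}

#' Projection step (data-fidelity solve)
#'
#' The closed-form minimizer of the quadratic subproblem coupling the iterate
#' to the measurement and to the denoised auxiliary variable:
#' `(gamma2 I + gamma1 Phi^T Phi)^-1 [lambda2 + gamma2 v +
#' Phi^T (gamma1 y - lambda1)]`, evaluated matrix-free in one shot.
#'
#' @param v auxiliary (denoised) cube: array or [spectral_cube()].
#' @param y measurement (matrix or [measurement()]).
#' @param lambda1 multiplier of the measurement shape.
#' @param lambda2 multiplier of the cube shape.
#' @param gamma1,gamma2 penalties (`gamma1 >= 0`, `gamma2 > 0`).
#' @param op a [sensing_operator()].
#' @return Array of the cube shape.
#' @export
projection_step <- function(v, y, lambda1, lambda2, gamma1, gamma2, op) {
  V <- if (inherits(v, "spectral_cube")) v$data else v
  Y <- if (inherits(y, "cassi_measurement")) y$data else y
  check_cube_op(V, op)
  b <- lambda2 + gamma2 * V + adjoint_raw(gamma1 * Y - lambda1, op)
  al_solve(b, op, gamma1, gamma2)
}

#' Denoising step (prior subproblem)
#'
#' Applies the denoising prior to `f_prev - lambda2 / gamma2`. The effective
#' strength is `strength / gamma2`: the stiffer the quadratic coupling, the
#' smaller the denoising move.
#'
#' @param f_prev current iterate (array or [spectral_cube()]).
#' @param lambda2 cube-shaped multiplier.
#' @param gamma2 positive penalty.
#' @param den a [denoiser()].
#' @param strength base denoiser strength (`>= 0`).
#' @param guidance optional [guidance_features()] array.
#' @return Array of the cube shape.
#' @export
denoise_step <- function(f_prev, lambda2, gamma2, den, strength,
                         guidance = NULL) {
  stopifnot(gamma2 > 0, strength >= 0)
  F <- if (inherits(f_prev, "spectral_cube")) f_prev$data else f_prev
  denoise(den, F - lambda2 / gamma2, strength / gamma2, guidance)
}

#' Multiplier update
#'
#' Dual ascent on both constraints:
#' `lambda1 <- lambda1 - gamma1 (y - Phi f)` and
#' `lambda2 <- lambda2 - gamma2 (f - v)`, then the iteration counter is
#' incremented. At a consistent point (`y == Phi f`, `f == v`) the
#' multipliers are unchanged.
#'
#' @param state list with elements `f`, `v` (cube arrays), `lambda1`,
#'   `lambda2`, `gamma1`, `gamma2`, `i`.
#' @param y measurement matrix (or [measurement()]).
#' @param op a [sensing_operator()].
#' @return The updated state list.
#' @export
update_multipliers <- function(state, y, op) {
  Y <- if (inherits(y, "cassi_measurement")) y$data else y
  state$lambda1 <- state$lambda1 - state$gamma1 * (Y - forward_raw(state$f, op))
  state$lambda2 <- state$lambda2 - state$gamma2 * (state$f - state$v)
  state$i <- state$i + 1L
  state
}

#' Guidance feature maps
#'
#' Per-pixel features summarizing the sensing operator for a guided denoiser:
#' a constant `gamma2` map, the mask replicated per band (the sensing pattern
#' seen from scene coordinates), and the trace map — the diagonal of
#' `Phi Phi^T` shifted back to scene coordinates by each band's shear and
#' averaged over bands. Shape `(rows, cols, bands + 2)`.
#'
#' @param gamma2 positive penalty scalar.
#' @param op a [sensing_operator()].
#' @param y unused placeholder for denoisers that also condition on the
#'   measurement.
#' @return 3-D array `(rows, cols, bands + 2)`.
#' @export
guidance_features <- function(gamma2, op, y = NULL) {
  d <- op$scene_dim
  D <- phi_phit_diag(op)
  tr <- matrix(0, d[1L], d[2L])
  for (k in seq_len(d[3L])) {
    s <- op$shifts[k]
    tr <- tr + D[, (s + 1L):(s + d[2L])]
  }
  tr <- tr / d[3L]
  out <- array(0, c(d[1L], d[2L], d[3L] + 2L))
  out[, , 1L] <- gamma2
  for (k in seq_len(d[3L])) out[, , k + 1L] <- op$mask$pattern
  out[, , d[3L] + 2L] <- tr
  out
}

#' ADMM reconstruction of a spectral datacube
#'
#' Runs the alternating scheme: initialization from the measurement, then
#' `n_iterations` of denoising (prior subproblem), closed-form projection
#' (data subproblem) and dual multiplier updates. Multipliers start at zero.
#' The final iterate is clipped to nonnegative values; per-iteration data
#' residuals `||y - Phi f||_2` are attached as `attr(, "residuals")`.
#'
#' @param y a [measurement()] (or matrix).
#' @param op a [sensing_operator()].
#' @param config a [solver_config()].
#' @param wavelengths optional wavelength grid for the result.
#' @return A [spectral_cube()] with attributes `residuals` (numeric vector,
#'   initialization first) and `iterations`.
#' @export
cassi_reconstruct <- function(y, op, config = solver_config(),
                              wavelengths = NULL) {
  Y <- if (inherits(y, "cassi_measurement")) y$data else y
  if (!all(dim(Y) == measurement_dim(op)))
    stop(sprintf("measurement is %s but operator expects %s",
                 paste(dim(Y), collapse = "x"),
                 paste(measurement_dim(op), collapse = "x")), call. = FALSE)
  d <- op$scene_dim
  f <- admm_initialize(Y, op, config$gamma1[1L], config$gamma2[1L])$data
  lambda1 <- matrix(0, nrow(Y), ncol(Y))
  lambda2 <- array(0, d)
  v <- f
  residuals <- sqrt(sum((Y - forward_raw(f, op))^2))
  needs_guidance <- inherits(config$denoiser, "spectral_attention_denoiser")
  for (i in seq_len(config$n_iterations)) {
    g1 <- config$gamma1[i]; g2 <- config$gamma2[i]
    guid <- if (needs_guidance) guidance_features(g2, op, Y) else NULL
    f_old <- f
    v <- denoise_step(f, lambda2, g2, config$denoiser, config$strength[i],
                      guid)
    f <- projection_step(v, Y, lambda1, lambda2, g1, g2, op)
    st <- update_multipliers(
      list(f = f, v = v, lambda1 = lambda1, lambda2 = lambda2,
           gamma1 = g1, gamma2 = g2, i = i), Y, op)
    lambda1 <- st$lambda1; lambda2 <- st$lambda2
    res <- sqrt(sum((Y - forward_raw(f, op))^2))
    if (!is.finite(res))
      stop(paste0("solver diverged (non-finite residual) at iteration ", i,
                  "; trace: ",
                  paste(signif(c(residuals, res), 6), collapse = ", ")),
           call. = FALSE)
    residuals <- c(residuals, res)
    if (config$tol > 0) {
      rel <- sqrt(sum((f - f_old)^2)) / max(sqrt(sum(f_old^2)), 1e-12)
      if (rel < config$tol) break
    }
  }
  if (is.null(wavelengths)) wavelengths <- seq_len(d[3L])
  out <- spectral_cube(pmax(f, 0), wavelengths)
  attr(out, "residuals") <- residuals
  attr(out, "iterations") <- length(residuals) - 1L
  out
}

#' Peak signal-to-noise ratio
#'
#' `10 log10(peak^2 / MSE)` with `peak = max` of the reference.
#'
#' @param x estimate (array or [spectral_cube()]).
#' @param ref ground truth of the same shape.
#' @return PSNR in dB.
#' @export
psnr <- function(x, ref) {
  X <- if (inherits(x, "spectral_cube")) x$data else x
  R <- if (inherits(ref, "spectral_cube")) ref$data else ref
  stopifnot(all(dim(X) == dim(R)))
  mse <- mean((X - R)^2)
  if (mse == 0) return(Inf)
  10 * log10(max(R)^2 / mse)
}

#' Write a per-iteration residual log
#'
#' @param cube result of [cassi_reconstruct()].
#' @param path CSV path; columns `iteration, residual` (iteration 0 is the
#'   initialization).
#' @export
write_residual_log <- function(cube, path) {
  r <- attr(cube, "residuals")
  if (is.null(r)) stop("cube carries no residual trace", call. = FALSE)
  utils::write.csv(data.frame(iteration = seq_along(r) - 1L, residual = r),
                   path, row.names = FALSE)
  invisible(path)
}
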