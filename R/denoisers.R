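#' Denoising priors
#'
#' The reconstruction alternates a data-fidelity projection with a denoising
#' step; the denoiser plays the role of the prior. Four implementations are
#' provided:
#'
#' * `"identity"` — returns its input (no prior; useful for testing and as
#'   the unfolding ablation baseline).
#' * `"tv"` — isotropic spatial total variation, applied band by band with a
#'   dual-ascent (Chambolle projection) inner loop.
#' * `"wavelet"` — single-level 2-D Haar transform per band with soft
#'   thresholding of the detail subbands.
#' * `"spectral_attention"` — a compact trainable denoiser: per-band spatial
#'   binomial smoothing plus channel-wise self-attention over bands computed
#'   from the iterate's own band Gram matrix, with a handful of scalar
#'   parameters (spatial mixing, attention temperature, band mixing) that
#'   [train_unfolded()] fits end to end.
#'
#' All denoisers return an array of the input's shape and reduce to the
#' identity as `strength -> 0`.
#'
#' @param name one of `"identity"`, `"tv"`, `"wavelet"`,
#'   `"spectral_attention"`.
#' @param ... implementation parameters: `iterations` (TV inner iterations,
#'   default 20); `params` (numeric vector `alpha`, `log_theta`, `beta` for
#'   the spectral-attention denoiser).
#' @return An object of class `cassi_denoiser`.
#' @export
denoiser <- function(name = c("identity", "tv", "wavelet",
                              "spectral_attention"), ...) {
  name <- match.arg(name)
  opts <- list(...)
  obj <- structure(list(name = name, opts = opts),
                   class = c(paste0(name, "_denoiser"), "cassi_denoiser"))
  if (name == "spectral_attention" && is.null(opts$params))
    obj$opts$params <- c(alpha = 0, log_theta = 0, beta = 0)
  obj
}

#' Apply a denoiser
#'
#' @param den a [denoiser()].
#' @param x numeric 3-D array `(rows, cols, bands)`.
#' @param strength nonnegative scalar; `0` returns `x` unchanged.
#' @param guidance optional guidance array from [guidance_features()].
#' @return Array of the same shape as `x`.
#' @export
denoise <- function(den, x, strength, guidance = NULL) {
  stopifnot(inherits(den, "cassi_denoiser"), is.array(x),
            length(dim(x)) == 3L, strength >= 0)
  if (strength == 0) return(x)
  UseMethod("denoise")
}

#' @export
denoise.identity_denoiser <- function(den, x, strength, guidance = NULL) x

#' @export
denoise.tv_denoiser <- function(den, x, strength, guidance = NULL) {
  iters <- den$opts$iterations %||% 20L
  for (k in seq_len(dim(x)[3L]))
    x[, , k] <- tv_denoise_band(x[, , k], strength, iters)
  x
}

#' @export
denoise.wavelet_denoiser <- function(den, x, strength, guidance = NULL) {
  for (k in seq_len(dim(x)[3L]))
    x[, , k] <- haar_soft_threshold(x[, , k], strength)
  x
}

#' @export
denoise.spectral_attention_denoiser <- function(den, x, strength,
                                                guidance = NULL) {
  spectral_attention_denoise(x, strength, den$opts$params, guidance)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# forward differences with Neumann (replicate) boundary
grad_h <- function(u) cbind(u[, -1L, drop = FALSE] - u[, -ncol(u), drop = FALSE], 0)
grad_v <- function(u) rbind(u[-1L, , drop = FALSE] - u[-nrow(u), , drop = FALSE], 0)
div_hv <- function(ph, pv) {
  dh <- ph - cbind(0, ph[, -ncol(ph), drop = FALSE])
  dh[, ncol(dh)] <- -ph[, ncol(ph) - 1L]
  dv <- pv - rbind(0, pv[-nrow(pv), , drop = FALSE])
  dv[nrow(dv), ] <- -pv[nrow(pv) - 1L, ]
  dh + dv
}

# Chambolle dual-ascent projection for min_u ||u - g||^2 / 2 + w * TV(u).
# The dual field p is updated with step tau = 1/4 and projected onto the
# pointwise unit ball (isotropic norm); u = g - w * div(p).
tv_denoise_band <- function(g, w, iters = 20L) {
  if (w <= 0) return(g)
  ph <- pv <- matrix(0, nrow(g), ncol(g))
  tau <- 0.25
  for (it in seq_len(iters)) {
    u <- div_hv(ph, pv) - g / w
    gh <- grad_h(u); gv <- grad_v(u)
    den <- 1 + tau * sqrt(gh^2 + gv^2)
    ph <- (ph + tau * gh) / den
    pv <- (pv + tau * gv) / den
  }
  g - w * div_hv(ph, pv)
}

# total variation functional (isotropic, forward differences); used by tests
# to verify the denoiser decreases it
tv_functional <- function(x) {
  if (length(dim(x)) == 2L) x <- array(x, c(dim(x), 1L))
  s <- 0
  for (k in seq_len(dim(x)[3L])) {
    u <- x[, , k]
    s <- s + sum(sqrt(grad_h(u)^2 + grad_v(u)^2))
  }
  s
}

soft <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

# single-level 2-D Haar analysis/synthesis with replicate padding to even
# dims; detail subbands are soft-thresholded, the approximation is kept
haar_soft_threshold <- function(g, t) {
  nr <- nrow(g); nc <- ncol(g)
  gp <- g
  if (nr %% 2L == 1L) gp <- rbind(gp, gp[nr, ])
  if (nc %% 2L == 1L) gp <- cbind(gp, gp[, nc])
  o1 <- seq(1L, nrow(gp), by = 2L); o2 <- o1 + 1L
  e1 <- seq(1L, ncol(gp), by = 2L); e2 <- e1 + 1L
  a <- gp[o1, e1, drop = FALSE]; b <- gp[o1, e2, drop = FALSE]
  cc <- gp[o2, e1, drop = FALSE]; d <- gp[o2, e2, drop = FALSE]
  LL <- (a + b + cc + d) / 2
  LH <- (a - b + cc - d) / 2
  HL <- (a + b - cc - d) / 2
  HH <- (a - b - cc + d) / 2
  LH <- soft(LH, t); HL <- soft(HL, t); HH <- soft(HH, t)
  out <- matrix(0, nrow(gp), ncol(gp))
  out[o1, e1] <- (LL + LH + HL + HH) / 2
  out[o1, e2] <- (LL - LH + HL - HH) / 2
  out[o2, e1] <- (LL + LH - HL - HH) / 2
  out[o2, e2] <- (LL - LH - HL + HH) / 2
  out[seq_len(nr), seq_len(nc), drop = FALSE]
}

# 3x3 binomial smoothing with replicate boundary
binomial3 <- function(u) {
  pad <- rbind(u[1L, ], u, u[nrow(u), ])
  pad <- cbind(pad[, 1L], pad, pad[, ncol(pad)])
  n <- nrow(u); m <- ncol(u)
  r1 <- 1:n; r2 <- 2:(n + 1L); r3 <- 3:(n + 2L)
  c1 <- 1:m; c2 <- 2:(m + 1L); c3 <- 3:(m + 2L)
  (pad[r1, c1] + 2 * pad[r1, c2] + pad[r1, c3] +
   2 * pad[r2, c1] + 4 * pad[r2, c2] + 2 * pad[r2, c3] +
   pad[r3, c1] + 2 * pad[r3, c2] + pad[r3, c3]) / 16
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Trainable spectral-attention denoiser. Parameters:
#   alpha     - logit of the spatial smoothing mix in [0, 1]
#   log_theta - log attention temperature over the band Gram matrix
#   beta      - logit of the band-attention mix in [0, 1]
# Both mixes are additionally scaled by strength / (1 + strength) so the map
# reduces to the identity as strength -> 0. When guidance features are
# supplied, smoothing is attenuated where the measurement overlap (trace of
# Phi Phi^T, last guidance channel) is high: well-constrained pixels need
# less prior.
spectral_attention_denoise <- function(x, strength, params, guidance = NULL) {
  u <- strength / (1 + strength)
  a <- sigmoid(params[[1L]]) * u
  theta <- exp(params[[2L]])
  b <- sigmoid(params[[3L]]) * u
  d <- dim(x)
  amap <- a
  if (!is.null(guidance)) {
    tr <- guidance[, , dim(guidance)[3L]]
    mx <- max(tr)
    if (mx > 0) amap <- a * (1 - 0.5 * tr / mx)
  }
  xs <- x
  for (k in seq_len(d[3L])) {
    sm <- binomial3(x[, , k])
    xs[, , k] <- (1 - amap) * x[, , k] + amap * sm
  }
  if (d[3L] > 1L && b > 0) {
    Z <- matrix(xs, d[1L] * d[2L], d[3L])
    zn <- sqrt(colSums(Z^2)) + 1e-12
    G <- crossprod(sweep(Z, 2L, zn, "/"))     # band cosine-similarity Gram
    A <- exp(theta * G)
    A <- A / rowSums(A)                        # softmax over source bands
    Za <- Z %*% t(A)
    xs <- array((1 - b) * Z + b * Za, d)
  }
  xs
}
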