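#' Train the unfolded reconstruction end to end
#'
#' Deep unfolding fixes the solver depth (4 stages by default) and fits its
#' free parameters against ground truth: the per-stage penalties
#' `gamma1, gamma2` and denoiser strengths (all kept positive through a
#' log/exponential parameterization) and the scalar weights of the
#' spectral-attention denoiser. The loss is the mean squared error between
#' the unfolded reconstruction and the true cube, averaged over the training
#' pairs. Gradients are taken by central finite differences over the small
#' parameter vector, and each epoch applies one descent step with
#' backtracking (the step is halved until the loss does not increase), so
#' the recorded loss is non-increasing. The base step decays by 0.9 every
#' 15 epochs after the first five.
#'
#' @param trainset list of training pairs; each element is a list with
#'   `cube` (a [spectral_cube()]), `y` (a [measurement()]) and `op` (the
#'   [sensing_operator()] that produced `y`).
#' @param n_stages unfolding depth (default 4).
#' @param epochs number of epochs (one descent step each).
#' @param lr base step size.
#' @param init optional initial parameter vector (as returned in `$params`).
#' @param seed integer seed recorded in the returned config.
#' @return List with `config` (a ready [solver_config()]), `denoiser`,
#'   `gamma1`, `gamma2`, `strength` (positive per-stage vectors),
#'   `loss_history` (epoch 0 = initialization), and `params`.
#' @export
train_unfolded <- function(trainset, n_stages = 4L, epochs = 10L,
                           lr = 0.05, init = NULL, seed = 0L) {
  stopifnot(length(trainset) >= 1, n_stages >= 1, epochs >= 1)
  for (pr in trainset)
    if (is.null(pr$cube) || is.null(pr$y) || is.null(pr$op))
      stop("each training pair needs cube, y and op", call. = FALSE)

  n_stages <- as.integer(n_stages)
  if (is.null(init))
    init <- c(log_gamma1 = rep(0, n_stages), log_gamma2 = rep(0, n_stages),
              log_strength = rep(log(0.05), n_stages),
              alpha = 0, log_theta = 0, beta = 0)
  np <- length(init)

  unpack <- function(p) {
    g1 <- exp(p[seq_len(n_stages)])
    g2 <- exp(p[n_stages + seq_len(n_stages)])
    st <- exp(p[2L * n_stages + seq_len(n_stages)])
    den <- denoiser("spectral_attention",
                    params = unname(p[(3L * n_stages + 1L):np]))
    solver_config(n_iterations = n_stages, gamma1 = g1, gamma2 = g2,
                  denoiser = den, strength = st, seed = seed)
  }

  loss_fn <- function(p) {
    cfg <- unpack(p)
    mean(vapply(trainset, function(pr) {
      rec <- cassi_reconstruct(pr$y, pr$op, cfg,
                               wavelengths = pr$cube$wavelengths)
      mean((rec$data - pr$cube$data)^2)
    }, 0))
  }

  p <- init
  loss <- loss_fn(p)
  history <- loss
  h <- 1e-3
  for (ep in seq_len(epochs)) {
    g <- vapply(seq_len(np), function(j) {
      pp <- p; pp[j] <- pp[j] + h
      pm <- p; pm[j] <- pm[j] - h
      (loss_fn(pp) - loss_fn(pm)) / (2 * h)
    }, 0)
    step <- lr * 0.9^(max(0L, ep - 5L) %/% 15L)
    gn <- sqrt(sum(g^2))
    if (gn > 0) {
      dir <- g / gn
      for (tries in seq_len(10L)) {
        cand <- p - step * dir
        lc <- loss_fn(cand)
        if (lc <= loss) { p <- cand; loss <- lc; break }
        step <- step / 2
      }
    }
    history <- c(history, loss)
  }
  cfg <- unpack(p)
  list(config = cfg, denoiser = cfg$denoiser,
       gamma1 = cfg$gamma1, gamma2 = cfg$gamma2, strength = cfg$strength,
       loss_history = history, params = p)
}

#' Generate unfolding training pairs
#'
#' Simulates `(cube, measurement)` pairs with the forward model: random
#' smooth scenes through a shared mask and dispersion, with optional Gaussian
#' noise. Used for the scaled-down training recipe and its tests.
#'
#' @param n number of pairs.
#' @param rows,cols,bands patch shape (default 32 x 32 x 8).
#' @param op optional shared [sensing_operator()]; one is built from a
#'   seed-0 random mask and a unit shift step when omitted.
#' @param noise_sigma Gaussian noise std relative to the scene peak.
#' @param seed integer seed.
#' @return List of pairs suitable for [train_unfolded()].
#' @export
make_training_pairs <- function(n = 4L, rows = 32L, cols = 32L, bands = 8L,
                                op = NULL, noise_sigma = 0.01, seed = 0L) {
  w <- default_band_grid(bands)
  if (is.null(op)) {
    mask <- random_binary_mask(rows, cols, 0.5, seed = seed)
    op <- sensing_operator(mask, c(rows, cols, bands),
                           shifts = seq_len(bands) - 1L)
  }
  lapply(seq_len(n), function(i) {
    arr <- withr::with_seed(as.integer(seed) + i, {
      a <- array(stats::rnorm(rows * cols * bands), c(rows, cols, bands))
      for (k in seq_len(bands)) for (j in 1:4) a[, , k] <- binomial3(a[, , k])
      a <- a - min(a)
      a / max(a)
    })
    cube <- spectral_cube(arr, w)
    noise <- if (noise_sigma > 0)
      noise_model("gaussian", sigma = noise_sigma * max(arr),
                  seed = as.integer(seed) + 1000L + i)
    else NULL
    list(cube = cube, y = forward_project(cube, op, noise), op = op)
  })
}
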