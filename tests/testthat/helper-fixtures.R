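# Shared fixtures: tiny operators built in code, plus a dense-matrix oracle
# path used to cross-check the matrix-free implementation.

tiny_op <- function(rows = 6L, cols = 6L, bands = 4L, fill = 0.5,
                    mask_seed = 3L, shifts = seq_len(bands) - 1L) {
  mask <- random_binary_mask(rows, cols, fill, seed = mask_seed)
  sensing_operator(mask, c(rows, cols, bands), shifts = shifts)
}

random_cube_array <- function(rows, cols, bands, seed = 1L) {
  withr::with_seed(seed, array(stats::runif(rows * cols * bands),
                               c(rows, cols, bands)))
}

# independent dense solve of (gamma2 I + gamma1 Phi^T Phi) x = b
dense_al_solve <- function(b, op, gamma1, gamma2) {
  Phi <- dense_phi(op)
  A <- gamma2 * diag(ncol(Phi)) + gamma1 * crossprod(Phi)
  array(solve(A, as.vector(b)), dim(b))
}

phantom_fixture <- function(bands = 8L, rows = 64L, cols = 64L, seed = 0L) {
  w <- default_band_grid(bands)
  ph <- eye_phantom_scene(rows, cols, w, seed = seed)
  mask <- random_binary_mask(rows, cols, 0.5, seed = seed)
  op <- sensing_operator(mask, c(rows, cols, bands),
                         shifts = seq_len(bands) - 1L)
  list(scene = ph, op = op, w = w,
       y = forward_project(ph$cube, op))
}
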