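# Small phantom configurations shared across tests.

tiny_config <- function(grid = 16L, seed = 1L, ...) {
  phantom_config(grid_size = grid, b_values = c(50, 1000),
                 n_directions = 2L, n_repetitions = c(2L, 4L),
                 seed = seed, ...)
}

# Pure-noise repetition array with a given per-pixel sigma map.
noise_reps <- function(sigma_map, N, seed = 1L) {
  set.seed(seed)
  H <- nrow(sigma_map); W <- ncol(sigma_map)
  reps <- array(0, c(H, W, N))
  for (j in seq_len(N)) reps[, , j] <- stats::rnorm(H * W) * c(sigma_map)
  reps
}

complex_noise_reps <- function(sigma_map, N, seed = 1L) {
  set.seed(seed)
  H <- nrow(sigma_map); W <- ncol(sigma_map)
  reps <- array(0i, c(H, W, N))
  for (j in seq_len(N))
    reps[, , j] <- (stats::rnorm(H * W) + 1i * stats::rnorm(H * W)) *
      c(sigma_map)
  reps
}
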