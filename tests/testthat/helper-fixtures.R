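# Small in-code fixtures shared across test files.

acq30 <- function() acquisition_params(dt = 0.03, t_pulse = 0.003)

# Build one trajectory from vectors, defaulting to consecutive frames and a
# constant localization uncertainty.
make_traj <- function(x, y, frame = seq_along(x) - 1L, sigma = 0.02,
                      traj_id = "t1", cell_id = "c1") {
  spthmm:::new_trajectory(traj_id, cell_id, frame, x, y,
                          rep(sigma, length.out = length(x)))
}

# A random-walk trajectory with optional single-frame gaps.
random_traj <- function(n, D = 0.1, dt = 0.03, sigma = 0.02,
                        gap_at = integer(0), traj_id = "t1") {
  frame <- seq_len(n) - 1L
  x <- cumsum(c(0, rnorm(n - 1L, 0, sqrt(2 * D * dt))))
  y <- cumsum(c(0, rnorm(n - 1L, 0, sqrt(2 * D * dt))))
  keep <- setdiff(seq_len(n), gap_at)
  spthmm:::new_trajectory(traj_id, "c1", frame[keep], x[keep], y[keep],
                          rep(sigma, length(keep)))
}

random_set <- function(n_traj, n_locs = 12L, D = 0.1, acq = acq30(),
                       sigma = 0.02) {
  trajs <- lapply(seq_len(n_traj), function(i)
    random_traj(n_locs, D = D, dt = acq$dt, sigma = sigma,
                traj_id = paste0("t", i)))
  trajectory_set(trajs, acq)
}

# A valid random model with strictly positive transition probabilities.
random_model <- function(K, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rgamma(K * K, 1) + 0.05, K, K)
  A <- A / rowSums(A)
  diffusion_hmm(D = sort(runif(K, 0.01, 1)), A = A, R = 1 / 60)
}
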