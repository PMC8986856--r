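test_that("blur coefficient matches the shutter-function integral", {
  # numeric evaluation of R = (1/dt) int S(t)(1-S(t)) dt for a square pulse
  numeric_R <- function(dt, tp) {
    S <- function(t) pmin(pmax(t / tp, 0), 1)
    tt <- seq(0, dt, length.out = 2e5 + 1)
    f <- S(tt) * (1 - S(tt))
    sum((f[-1] + f[-length(f)]) / 2 * diff(tt)) / dt
  }
  expect_equal(blur_coefficient(acquisition_params(0.03, 0.003)),
               numeric_R(0.03, 0.003), tolerance = 1e-6)
  expect_equal(blur_coefficient(acquisition_params(0.03, 0.003)), 1 / 60)
  expect_equal(blur_coefficient(acquisition_params(0.05, 0.05)), 1 / 6)
  expect_lt(blur_coefficient(acquisition_params(0.03, 1e-9)), 1e-6)
  expect_error(acquisition_params(0.03, 0.04))
})

test_that("step variance combines diffusion, blur, and localization error", {
  acq <- acq30()  # R = 1/60
  expect_equal(step_variance(0, 1, acq, 0, 0), 0)
  acq0 <- acquisition_params(0.03, 1e-12)  # R ~ 0
  expect_equal(step_variance(0.1, 1, acq0), 0.006, tolerance = 1e-6)
  expect_equal(step_variance(0.1, 1, acq, 0.02, 0.03),
               2 * 0.1 * 0.03 * (1 - 2 / 60) + 0.02^2 + 0.03^2)
  # gap-spanning step: doubled time, halved blur reduction
  expect_equal(step_variance(0.1, 2, acq),
               2 * 0.1 * 0.06 * (1 - 1 / 60))
  expect_error(step_variance(0.1, 3, acq), "n_frames")
})

test_that("K=1 forward log-likelihood equals the Gaussian closed form", {
  set.seed(11)
  acq <- acq30()
  traj <- random_traj(12, D = 0.2, sigma = 0.03, gap_at = 6L)
  model <- diffusion_hmm(D = 0.2, A = matrix(1, 1, 1), R = 1 / 60)
  dx <- diff(traj$x); dy <- diff(traj$y); nf <- diff(traj$frame)
  s2 <- traj$sigma[-length(traj$sigma)]^2 + traj$sigma[-1]^2
  v <- step_variance(0.2, nf, acq, 0, 0) + s2
  closed <- sum(dnorm(dx, 0, sqrt(v), log = TRUE) +
                dnorm(dy, 0, sqrt(v), log = TRUE))
  expect_equal(trajectory_loglik(model, traj, acq), closed,
               tolerance = 1e-12)
  expect_equal(bruteforce_loglik(model, traj, acq), closed,
               tolerance = 1e-12)
})

test_that("forward algorithm equals brute-force path enumeration", {
  set.seed(21)
  acq <- acq30()
  for (rep in 1:60) {
    K <- sample(1:3, 1)
    n <- sample(3:9, 1)  # up to 8 steps
    gap_at <- if (runif(1) < 0.4) sample(2:(n - 1), 1) else integer(0)
    traj <- random_traj(n, D = runif(1, 0.01, 0.5),
                        sigma = runif(1, 0, 0.05), gap_at = gap_at)
    model <- random_model(K)
    ll_f <- trajectory_loglik(model, traj, acq)
    ll_b <- bruteforce_loglik(model, traj, acq)
    expect_equal(ll_f, ll_b, tolerance = 1e-9)
  }
})

test_that("one-step brute force is a K-component Gaussian mixture", {
  acq <- acq30()
  model <- random_model(3, seed = 5)
  traj <- make_traj(x = c(0, 0.15), y = c(0, -0.05), sigma = 0.02)
  v <- step_variance(model$D, 1, acq, 0.02, 0.02)
  mix <- sum(model$pi * dnorm(0.15, 0, sqrt(v)) * dnorm(-0.05, 0, sqrt(v)))
  expect_equal(bruteforce_loglik(model, traj, acq), log(mix),
               tolerance = 1e-12)
})

test_that("consistent state relabeling leaves the log-likelihood unchanged", {
  set.seed(31)
  acq <- acq30()
  traj <- random_traj(10, D = 0.1)
  K <- 3
  A <- matrix(rgamma(9, 1) + 0.1, K, K); A <- A / rowSums(A)
  D <- c(0.03, 0.2, 0.8)
  base <- list(K = K, D = D, A = A,
               pi = stationary_distribution(A), R = 1 / 60)
  class(base) <- "diffusion_hmm"
  ll0 <- trajectory_loglik(base, traj, acq)
  for (perm in list(c(2, 1, 3), c(3, 1, 2), c(2, 3, 1))) {
    pm <- base
    pm$D <- D[perm]; pm$A <- A[perm, perm]; pm$pi <- base$pi[perm]
    expect_equal(trajectory_loglik(pm, traj, acq), ll0, tolerance = 1e-12)
  }
})

test_that("stationary distribution solves pi A = pi", {
  expect_equal(stationary_distribution(matrix(c(.9, .1, .1, .9), 2, 2)),
               c(0.5, 0.5))
  A <- matrix(c(0.8, 0.2, 0.8, 0.2), 2, 2, byrow = TRUE)
  expect_equal(stationary_distribution(A), c(0.8, 0.2))
  # power-iteration oracle on random chains
  set.seed(41)
  for (rep in 1:20) {
    K <- sample(2:6, 1)
    A <- matrix(rgamma(K * K, 1) + 1e-3, K, K); A <- A / rowSums(A)
    p <- rep(1 / K, K)
    for (i in 1:20000) p <- as.vector(p %*% A)
    expect_equal(stationary_distribution(A), p, tolerance = 1e-12)
  }
  # reducible chain is rejected with the offending block named
  A <- diag(2)
  expect_error(stationary_distribution(A), "reducible")
})

test_that("K=1 fit recovers the method-of-moments diffusion coefficient", {
  set.seed(51)
  acq <- acq30()
  sigma <- 0.03
  set <- random_set(30, n_locs = 20L, D = 0.15, sigma = sigma)
  fit <- fit_hmm(set, fit_options(K = 1, n_restarts = 1))
  dt <- acq$dt; R <- blur_coefficient(acq)
  comp2 <- unlist(lapply(set$trajectories, function(t)
    c(diff(t$x)^2, diff(t$y)^2)))
  D_mom <- max((mean(comp2) - 2 * sigma^2) / (2 * dt * (1 - 2 * R)), 1e-6)
  expect_equal(fit$D, D_mom, tolerance = 1e-8)
})

test_that("fitted models satisfy their structural invariants", {
  set.seed(61)
  sim <- simulate_dataset(simulation_config(
    states = data.frame(D = c(0.05, 0.4), mean_dwell = c(3, 1)),
    n_trajectories = 150, seed = 9))
  fit <- fit_hmm(sim$set, fit_options(K = 2, n_restarts = 2))
  expect_equal(rowSums(fit$A), rep(1, 2), tolerance = 1e-12)
  expect_equal(sum(fit$pi), 1, tolerance = 1e-12)
  expect_equal(as.vector(fit$pi %*% fit$A), fit$pi, tolerance = 1e-10)
  expect_false(is.unsorted(fit$D))
  expect_equal(fit$aic, 2 * fit$n_params - 2 * fit$loglik)
  expect_equal(fit$n_params, 2 + 2 * 1)
  # serialization round trip
  js <- model_to_json(fit)
  back <- model_from_json(js)
  expect_equal(back$D, fit$D, tolerance = 1e-12)
  expect_equal(back$A, fit$A, tolerance = 1e-12)
  expect_equal(back$aic, fit$aic, tolerance = 1e-10)
})

test_that("EM log-likelihood is monotone and restarts are deterministic", {
  set.seed(71)
  sim <- simulate_dataset(simulation_config(
    states = data.frame(D = c(0.04, 0.5), mean_dwell = c(1.5, 0.6)),
    n_trajectories = 80, gap_prob = 0.08, seed = 3))
  fit1 <- fit_hmm(sim$set, fit_options(K = 2, n_restarts = 2, seed = 5))
  fit2 <- fit_hmm(sim$set, fit_options(K = 2, n_restarts = 2, seed = 5))
  expect_identical(fit1$D, fit2$D)
  tr <- fit1$metadata$ll_trace
  expect_true(all(diff(tr) >= -1e-10 * (abs(tr[-length(tr)]) + 1)))
})

test_that("model-size sweep runs and AIC prefers two states on two-state data", {
  set.seed(81)
  sim <- simulate_dataset(simulation_config(
    states = data.frame(D = c(0.03, 0.6), mean_dwell = c(2, 2)),
    n_trajectories = 120, seed = 13))
  models <- fit_hmm_sizes(sim$set, K_range = 1:3, n_restarts = 1,
                          max_iter = 300, tol = 1e-7)
  expect_named(models, c("K1", "K2", "K3"))
  expect_lt(models$K2$aic, models$K1$aic)
  # nesting: a larger model never fits notably worse
  expect_gte(models$K3$loglik, models$K2$loglik - 1e-4 * abs(models$K2$loglik))
  expect_gte(models$K2$loglik, models$K1$loglik - 1e-6)
})

test_that("deleting one localization (gap) barely changes a K=1 fit", {
  set.seed(91)
  acq <- acq30()
  set <- random_set(100, n_locs = 101L, D = 0.12, sigma = 0.02)  # 1e4 steps
  fit_full <- fit_hmm(set, fit_options(K = 1, n_restarts = 1))
  gapped <- lapply(set$trajectories, function(t) {
    i <- 50L
    spthmm:::new_trajectory(t$traj_id, t$cell_id, t$frame[-i], t$x[-i],
                            t$y[-i], t$sigma[-i])
  })
  fit_gap <- fit_hmm(trajectory_set(gapped, acq),
                     fit_options(K = 1, n_restarts = 1))
  expect_lt(abs(fit_gap$D - fit_full$D) / fit_full$D, 0.02)
})
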