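two_state_model <- function(D = c(0.05, 0.4), p_leave = c(0.01, 0.1)) {
  A <- matrix(c(1 - p_leave[1], p_leave[1], p_leave[2], 1 - p_leave[2]),
              2, 2, byrow = TRUE)
  diffusion_hmm(D = D, A = A, R = 1 / 60)
}

test_that("states are classified bound iff D is strictly below the threshold", {
  m <- two_state_model(D = c(0.05, 0.4))
  expect_equal(classify_states(m, 0.25), c("bound", "free"))
  expect_equal(classify_states(m, 1e-9), c("free", "free"))
  m2 <- two_state_model(D = c(0.25, 0.4))
  expect_equal(classify_states(m2, 0.25), c("free", "free"))  # boundary
})

test_that("aggregate occupancy sums stationary mass and conserves total", {
  m <- two_state_model(p_leave = c(0.03, 0.07))
  labels <- classify_states(m)
  occ <- aggregate_occupancy(m, labels)
  expect_equal(unname(occ), c(0.7, 0.3), tolerance = 1e-12)
  expect_equal(sum(occ), 1, tolerance = 1e-15)
  expect_message(occ_all <- aggregate_occupancy(m, c("bound", "bound")),
                 "empty")
  expect_equal(unname(occ_all), c(1, 0))
})

test_that("dwell times follow dt/(1-p_stay) with stationary weights", {
  m <- two_state_model(p_leave = c(0.01, 0.5))
  tau <- aggregate_dwell_time(m, classify_states(m), dt = 0.03)
  expect_equal(tau[["bound"]], 3.0, tolerance = 1e-12)
  expect_equal(tau[["free"]], 0.06, tolerance = 1e-12)
  # multi-state aggregate: weighted stay probability
  A <- matrix(c(0.90, 0.08, 0.02,
                0.05, 0.90, 0.05,
                0.01, 0.04, 0.95), 3, 3, byrow = TRUE)
  m3 <- diffusion_hmm(D = c(0.03, 0.08, 0.5), A = A)
  labels <- classify_states(m3, 0.25)
  tau3 <- aggregate_dwell_time(m3, labels, dt = 0.03)
  S <- 1:2
  w <- m3$pi[S] / sum(m3$pi[S])
  p_stay <- sum(w * rowSums(m3$A[S, S]))
  expect_equal(tau3[["bound"]], 0.03 / (1 - p_stay), tolerance = 1e-12)
  expect_error(aggregate_dwell_time(m3, c("free", "free", "free"), 0.03),
               "empty")
})

test_that("aggregate dwell time matches simulated sojourns of the chain", {
  set.seed(7)
  A <- matrix(c(0.97, 0.02, 0.01,
                0.03, 0.93, 0.04,
                0.02, 0.08, 0.90), 3, 3, byrow = TRUE)
  m <- diffusion_hmm(D = c(0.02, 0.1, 0.6), A = A)
  labels <- classify_states(m, 0.25)
  tau <- aggregate_dwell_time(m, labels, dt = 0.03)
  # simulate the chain and measure completed bound sojourns
  n <- 4e5
  s <- integer(n); s[1] <- 1L
  for (i in 2:n) s[i] <- sample.int(3, 1, prob = A[s[i - 1], ])
  bound <- labels[s] == "bound"
  r <- rle(bound)
  soj <- r$lengths[r$values]
  soj <- soj[-c(1, length(soj))]  # drop censored first/last sojourns
  se <- sd(soj) / sqrt(length(soj))
  expect_lt(abs(mean(soj) * 0.03 - tau[["bound"]]), 3 * se * 0.03)
  # empirical time fraction below threshold matches occupancy
  occ <- aggregate_occupancy(m, labels)
  se_occ <- sd(bound) / sqrt(n / 20)  # conservative: autocorrelated chain
  expect_lt(abs(mean(bound) - occ[["bound"]]), 3 * se_occ)
})

test_that("weighted model averaging reduces to the obvious cases", {
  df <- data.frame(K = 7:8, occupancy_bound = c(0.9, 0.9),
                   occupancy_free = c(0.1, 0.1),
                   tau_bound = c(20, 24), tau_free = c(1.5, 1.5))
  agg <- weighted_model_average(df)
  expect_equal(agg$scheme, "equal")
  expect_equal(unname(agg$mean["tau_bound"]), 22)
  expect_equal(unname(agg$wsd["tau_bound"]), 2)
  expect_equal(unname(agg$wsd["occupancy_bound"]), 0)
  one <- weighted_model_average(df[1, ])
  expect_equal(unname(one$mean["tau_bound"]), 20)
  expect_equal(unname(one$wsd["tau_bound"]), 0)
  expect_error(weighted_model_average(df, weights = c(0, 0)), "zero")
})

test_that("inverse-variance weighting beats equal weighting on replicates", {
  # two estimators of the same quantity with very different noise
  set.seed(17)
  n_rep <- 200
  truth <- 20
  est <- function() {
    x <- c(truth + rnorm(1, 0, 0.5), truth + rnorm(1, 0, 4))
    df <- data.frame(K = 7:8, occupancy_bound = 0.9, occupancy_free = 0.1,
                     tau_bound = x, tau_free = 1.5,
                     se_occupancy_bound = 0.01, se_occupancy_free = 0.01,
                     se_tau_bound = c(0.5, 4), se_tau_free = 0.1)
    c(iv = weighted_model_average(df)$mean[["tau_bound"]],
      eq = weighted_model_average(df, weights = c(1, 1))$mean[["tau_bound"]])
  }
  reps <- t(replicate(n_rep, est()))
  expect_lt(var(reps[, "iv"]), var(reps[, "eq"]))
})

test_that("threshold sensitivity re-grains without refitting", {
  m <- diffusion_hmm(D = c(0.05, 0.1, 0.5),
                     A = matrix(c(.9, .05, .05, .1, .8, .1, .02, .08, .9),
                                3, 3, byrow = TRUE))
  ref <- coarse_grain(m, dt = 0.03, threshold = 0.25)
  tab <- threshold_sensitivity(list(m), c(0.25), dt = 0.03)
  expect_equal(tab$tau_bound, ref$tau_bound)
  expect_equal(tab$rel_change_tau_bound, 0)
  # thresholds that do not cross a fitted D leave everything unchanged
  tab2 <- threshold_sensitivity(list(m), c(0.15, 0.2, 0.3, 0.4), dt = 0.03)
  expect_true(all(abs(tab2$rel_change_occupancy_bound) < 1e-12))
  # raising the threshold past a state raises occupancy_bound; extreme
  # thresholds empty an aggregate, whose dwell time is then undefined
  tab3 <- threshold_sensitivity(list(m), c(0.01, 0.25, 0.75), dt = 0.03)
  expect_true(all(diff(tab3$occupancy_bound) >= 0))
  expect_equal(tab3$occupancy_bound, c(0, sum(m$pi[1:2]), 1),
               tolerance = 1e-12)
  expect_true(is.na(tab3$tau_bound[1]) && is.na(tab3$tau_free[3]))
})

test_that("bootstrap errors are seeded, and zero for degenerate resampling", {
  set.seed(23)
  # one trajectory visiting both a slow and a fast phase, so a 2-state fit
  # straddles the coarse-graining threshold
  sd_slow <- sqrt(2 * 0.05 * 0.03); sd_fast <- sqrt(2 * 0.4 * 0.03)
  tr <- make_traj(x = cumsum(c(0, rnorm(10, 0, sd_slow),
                               rnorm(10, 0, sd_fast))),
                  y = cumsum(c(0, rnorm(10, 0, sd_slow),
                               rnorm(10, 0, sd_fast))))
  copies <- lapply(1:25, function(i) {
    t2 <- tr; t2$traj_id <- paste0("c", i); t2
  })
  set <- trajectory_set(copies, acq30())
  fit <- fit_hmm(set, fit_options(K = 2, n_restarts = 1, max_iter = 200,
                                  tol = 1e-7))
  cfg <- coarse_grain_config(n_bootstrap = 4, seed = 11)
  se1 <- bootstrap_errors(set, 2, cfg, fit = fit)
  point <- coarse_grain(fit, dt = 0.03)
  expect_lt(se1[["se_tau_bound"]], 1e-6 * point$tau_bound + 1e-9)
  # determinism: same seed twice
  sim <- simulate_dataset(simulation_config(
    states = data.frame(D = c(0.05, 0.4), mean_dwell = c(1.2, 0.6)),
    n_trajectories = 60, seed = 2))
  fit2 <- fit_hmm(sim$set, fit_options(K = 2, n_restarts = 1,
                                       max_iter = 200, tol = 1e-7))
  se_a <- bootstrap_errors(sim$set, 2, cfg, fit = fit2)
  se_b <- bootstrap_errors(sim$set, 2, cfg, fit = fit2)
  expect_identical(se_a, se_b)
  expect_true(all(se_a > 0))
})
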