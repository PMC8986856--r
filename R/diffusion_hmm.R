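#' Motion-blur coefficient for a square illumination pulse
#'
#' For a camera frame of length `dt` illuminated by a single square laser
#' pulse of duration `t_pulse`, the dimensionless blur coefficient is
#' \deqn{R = \frac{1}{dt}\int_0^{dt} S(t)\,(1 - S(t))\,dt = \frac{t_{pulse}}{6\,dt},}
#' where S is the cumulative shutter (illumination) function. R quantifies
#' how intra-frame motion averaging reduces the observed displacement
#' variance: R = 1/6 for continuous illumination, R -> 0 in the
#' stroboscopic limit. A 3 ms pulse in a 30 ms frame gives R = 1/60.
#'
#' @param acquisition An [acquisition_params()] object.
#' @return The blur coefficient, a number in (0, 1/6].
#' @export
blur_coefficient <- function(acquisition) {
  stopifnot(inherits(acquisition, "acquisition_params"))
  acquisition$t_pulse / (6 * acquisition$dt)
}

#' Per-dimension variance of an observed displacement
#'
#' Emission variance of the diffusion HMM for one displacement observed
#' between two localizations `n_frames` frames apart (2 means the
#' displacement spans a single-frame gap):
#' \deqn{Var = 2 D (n\,\Delta t)\,(1 - 2R/n) + \sigma_a^2 + \sigma_b^2.}
#' The first factor is free 2-D Brownian motion over the elapsed time,
#' reduced by motion blur at the two exposures; the sigma terms add the
#' localization-error variance of the two endpoint spots. The blur-induced
#' correlation between consecutive displacements is neglected (see the
#' methods vignette); for stroboscopic acquisitions (R of order 1/60) the
#' neglected covariance is a few percent of the step variance at most.
#'
#' @param D Diffusion coefficient (µm²/s), >= 0.
#' @param n_frames 1 for an ordinary step, 2 for a gap-spanning step.
#' @param acquisition An [acquisition_params()] object.
#' @param sigma_a,sigma_b Localization uncertainty (µm) of the two endpoint
#'   spots.
#' @return Variance per dimension (µm²).
#' @export
step_variance <- function(D, n_frames, acquisition, sigma_a = 0, sigma_b = 0) {
  stopifnot(all(D >= 0), all(sigma_a >= 0), all(sigma_b >= 0))
  if (!all(n_frames %in% c(1L, 2L)))
    stop("n_frames must be 1 or 2", call. = FALSE)
  R <- blur_coefficient(acquisition)
  dt <- acquisition$dt
  2 * D * (n_frames * dt) * (1 - 2 * R / n_frames) + sigma_a^2 + sigma_b^2
}

#' Stationary distribution of a transition matrix
#'
#' Solves pi A = pi, sum(pi) = 1 for a row-stochastic matrix. The chain must
#' be irreducible: if A decomposes into communicating classes, the stationary
#' vector is not unique and an error names a closed block.
#'
#' @param A Row-stochastic square matrix.
#' @return Probability vector `pi` with `pi %*% A = pi`.
#' @examples
#' stationary_distribution(matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2))
#' @export
stationary_distribution <- function(A) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A), all(is.finite(A)), all(A >= 0))
  K <- nrow(A)
  if (any(abs(rowSums(A) - 1) > 1e-9))
    stop("A is not row-stochastic", call. = FALSE)
  if (K > 1L) {
    # reachability closure; a closed communicating class that excludes some
    # state makes the chain reducible
    step <- (A > 0) | diag(K)
    reach <- step
    for (i in seq_len(K)) reach <- (reach %*% step) > 0
    comm <- reach & t(reach)
    if (!all(comm)) {
      cls <- unique(apply(comm, 1L, function(r) paste(which(r), collapse = ",")))
      closed <- cls[vapply(cls, function(cl) {
        idx <- as.integer(strsplit(cl, ",")[[1]])
        !any(reach[idx, -idx, drop = FALSE])
      }, logical(1))]
      stop("A is reducible; closed block: {", closed[1L], "}", call. = FALSE)
    }
  }
  M <- t(diag(K) - A)
  M[K, ] <- 1
  pi <- solve(M, c(rep(0, K - 1L), 1))
  pi <- pmax(pi, 0)
  pi / sum(pi)
}

#' Fitting options for the diffusion HMM
#'
#' @param K Number of hidden diffusion states.
#' @param n_restarts Number of EM restarts; the first uses the deterministic
#'   log-spaced initialization, subsequent restarts jitter the initial D
#'   multiplicatively (lognormal, 20%).
#' @param max_iter Maximum EM iterations per restart.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param D_min Floor on fitted diffusion coefficients (µm²/s), guarding the
#'   zero-variance degeneracy when localization-error terms exceed the
#'   observed variance.
#' @param seed Integer seed controlling restart jitter.
#' @return An object of class `fit_options`.
#' @export
fit_options <- function(K, n_restarts = 3L, max_iter = 2000L, tol = 1e-8,
                        D_min = 1e-6, seed = 1L) {
  stopifnot(K >= 1L, n_restarts >= 1L, max_iter >= 1L, tol > 0, D_min > 0)
  structure(list(K = as.integer(K), n_restarts = as.integer(n_restarts),
                 max_iter = as.integer(max_iter), tol = tol, D_min = D_min,
                 seed = as.integer(seed)),
            class = "fit_options")
}

#' Construct a diffusion HMM object
#'
#' Assembles a K-state diffusion model from its parameters, deriving the
#' stationary occupancy, parameter count and (when a log-likelihood is
#' supplied) the AIC. States are sorted by ascending diffusion coefficient.
#'
#' @param D Vector of diffusion coefficients (µm²/s).
#' @param A K x K per-frame transition probability matrix.
#' @param R Motion-blur coefficient.
#' @param loglik Total log-likelihood of the data under the model (optional).
#' @param metadata Optional list of fit metadata.
#' @return An object of class `diffusion_hmm` with fields `K`, `D`, `A`,
#'   `pi`, `R`, `loglik`, `n_params`, `aic`, `metadata`.
#' @export
diffusion_hmm <- function(D, A, R = 0, loglik = NA_real_, metadata = list()) {
  K <- length(D)
  stopifnot(K >= 1L, is.matrix(A), nrow(A) == K, ncol(A) == K, all(D >= 0))
  if (any(abs(rowSums(A) - 1) > 1e-9))
    stop("A is not row-stochastic", call. = FALSE)
  ord <- order(D)
  D <- D[ord]
  A <- A[ord, ord, drop = FALSE]
  # renormalize rows exactly so invariants hold to 1e-12
  A <- A / rowSums(A)
  pi <- stationary_distribution(A)
  n_params <- K + K * (K - 1L)
  structure(list(K = K, D = as.numeric(D), A = A, pi = pi, R = R,
                 loglik = loglik, n_params = n_params,
                 aic = 2 * n_params - 2 * loglik, metadata = metadata),
            class = "diffusion_hmm")
}

#' @export
print.diffusion_hmm <- function(x, digits = 4, ...) {
  cat(sprintf("%d-state diffusion HMM (R = %.4g)\n", x$K, x$R))
  tab <- data.frame(D_um2_s = signif(x$D, digits),
                    occupancy = signif(x$pi, digits),
                    stay_prob = signif(diag(x$A), digits))
  print(tab, row.names = TRUE)
  if (is.finite(x$loglik))
    cat(sprintf("logLik = %.4f, n_params = %d, AIC = %.4f\n",
                x$loglik, x$n_params, x$aic))
  invisible(x)
}

#' @export
AIC.diffusion_hmm <- function(object, ..., k = 2) {
  k * object$n_params - 2 * object$loglik
}

#' @export
logLik.diffusion_hmm <- function(object, ...) {
  structure(object$loglik, df = object$n_params, class = "logLik")
}

# ---------------------------------------------------------------------------
# Internal packed representation: all steps of all trajectories, flattened in
# step-major order with trajectories sorted by decreasing step count, so that
# the set of trajectories active at step s is always the prefix 1..n_active[s]
# and each step-slice is a contiguous index range.
# ---------------------------------------------------------------------------
pack_trajectories <- function(set) {
  trajs <- Filter(function(t) n_steps(t) >= 1L, set$trajectories)
  if (length(trajs) == 0L)
    stop("no trajectory with at least one step", call. = FALSE)
  Tlen <- vapply(trajs, n_steps, integer(1))
  ord <- order(Tlen, decreasing = TRUE)
  trajs <- trajs[ord]
  Tlen <- Tlen[ord]
  ntraj <- length(trajs)
  maxT <- Tlen[1L]
  n_active <- vapply(seq_len(maxT), function(s) sum(Tlen >= s), integer(1))
  off <- c(0L, cumsum(n_active))
  total <- off[maxT + 1L]
  dx <- dy <- s2 <- numeric(total)
  nf <- integer(total)
  for (j in seq_len(ntraj)) {
    t <- trajs[[j]]
    Tj <- Tlen[j]
    idx <- off[seq_len(Tj)] + j
    dx[idx] <- diff(t$x)
    dy[idx] <- diff(t$y)
    nf[idx] <- diff(t$frame)
    s2[idx] <- t$sigma[-length(t$sigma)]^2 + t$sigma[-1L]^2
  }
  list(ntraj = ntraj, Tlen = Tlen, maxT = maxT, n_active = n_active,
       off = off, total = total, dx = dx, dy = dy, r2 = dx^2 + dy^2,
       s2 = s2, nf = nf, order = ord)
}

# Precompute the grouping of steps by identical (blur coefficient, sigma^2)
# pairs used by the M-step D update; with a constant sigma law there are
# only a couple of groups and the update collapses to tiny sums.
pack_groups <- function(pack, dt, R) {
  a <- 2 * dt * (pack$nf - 2 * R)
  key <- paste(a, pack$s2)
  u <- !duplicated(key)
  gid <- match(key, key[u])
  list(a = a, gid = gid, ngroup = sum(u), ag = a[u], s2g = pack$s2[u])
}

rowmax <- function(E) {
  m <- E[, 1L]
  for (k in seq_len(ncol(E))[-1L]) m <- pmax(m, E[, k])
  m
}

# Log emission densities (2-D, per step) for all states: total x K matrix.
# v = a * D + s2 with a = 2*dt*(nf - 2R).
emission_loglik <- function(pack, D, dt, R) {
  a <- 2 * dt * (pack$nf - 2 * R)
  K <- length(D)
  E <- matrix(0, pack$total, K)
  for (k in seq_len(K)) {
    v <- a * D[k] + pack$s2
    E[, k] <- -log(2 * pi * v) - pack$r2 / (2 * v)
  }
  E
}

# Scaled forward-backward over the packed set. Returns the total
# log-likelihood, flattened posteriors G (total x K), expected per-frame
# transition counts C (gap links distributed over the latent mid-frame
# state), and the summed step-1 posterior (for the p0 update).
forward_backward <- function(pack, D, A, p0, dt, R, want_posteriors = TRUE) {
  K <- length(D)
  E <- emission_loglik(pack, D, dt, R)
  if (K == 1L) {
    ll <- sum(E)
    if (!want_posteriors) return(list(loglik = ll))
    return(list(loglik = ll, G = matrix(1, pack$total, 1L),
                C = matrix(sum(pack$n_active[-1L]) +
                             2 * sum(pack$nf == 2L), 1L, 1L),
                gamma1 = pack$n_active[1L]))
  }
  A2 <- A %*% A
  maxT <- pack$maxT
  off <- pack$off
  na <- pack$n_active
  alpha <- vector("list", maxT)
  cs <- vector("list", maxT)
  W <- vector("list", maxT)   # scaled emissions exp(E - rowmax)
  ll <- 0
  # forward
  sl <- off[1L] + seq_len(na[1L])
  Es <- E[sl, , drop = FALSE]
  m <- rowmax(Es)
  w <- exp(Es - m)
  a_raw <- w * rep(p0, each = na[1L])
  cc <- rowSums(a_raw)
  ll <- ll + sum(log(cc) + m)
  alpha[[1L]] <- a_raw / cc
  cs[[1L]] <- cc
  W[[1L]] <- w
  if (maxT > 1L) for (s in seq_len(maxT - 1L)) {
    n2 <- na[s + 1L]
    a_prev <- alpha[[s]][seq_len(n2), , drop = FALSE]
    nf_s <- pack$nf[off[s] + seq_len(n2)]
    pred <- a_prev %*% A
    gap <- nf_s == 2L
    if (any(gap)) pred[gap, ] <- a_prev[gap, , drop = FALSE] %*% A2
    sl <- off[s + 1L] + seq_len(n2)
    Es <- E[sl, , drop = FALSE]
    m <- rowmax(Es)
    w <- exp(Es - m)
    a_raw <- pred * w
    cc <- rowSums(a_raw)
    ll <- ll + sum(log(cc) + m)
    alpha[[s + 1L]] <- a_raw / cc
    cs[[s + 1L]] <- cc
    W[[s + 1L]] <- w
  }
  if (!want_posteriors)
    return(list(loglik = ll))
  # backward, accumulating posteriors and transition counts
  G <- matrix(0, pack$total, K)
  C1 <- matrix(0, K, K)      # expected counts over single-frame links
  X2 <- matrix(0, K, K)      # expected endpoint counts over gap (A^2) links
  beta <- matrix(1, na[maxT], K)
  g <- alpha[[maxT]] * beta
  G[off[maxT] + seq_len(na[maxT]), ] <- g / rowSums(g)
  if (maxT > 1L) for (s in rev(seq_len(maxT - 1L))) {
    n2 <- na[s + 1L]
    nf_s <- pack$nf[off[s] + seq_len(n2)]
    wb <- (W[[s + 1L]] * beta) / cs[[s + 1L]]   # n2 x K
    a_prev <- alpha[[s]][seq_len(n2), , drop = FALSE]
    gap <- nf_s == 2L
    if (any(!gap)) {
      i1 <- which(!gap)
      C1 <- C1 + A * crossprod(a_prev[i1, , drop = FALSE],
                               wb[i1, , drop = FALSE])
    }
    if (any(gap)) {
      i2 <- which(gap)
      X2 <- X2 + A2 * crossprod(a_prev[i2, , drop = FALSE],
                                wb[i2, , drop = FALSE])
    }
    beta_new <- matrix(1, na[s], K)    # trajectories ending at step s
    bn <- wb %*% t(A)
    if (any(gap)) bn[gap, ] <- wb[gap, , drop = FALSE] %*% t(A2)
    beta_new[seq_len(n2), ] <- bn
    beta <- beta_new
    g <- alpha[[s]] * beta
    G[off[s] + seq_len(na[s]), ] <- g / rowSums(g)
  }
  # distribute A^2 endpoint counts over the latent mid-frame state:
  # count(i,k) += A_ik (W A')_ik ; count(k,j) += A_kj (A' W)_kj, W = X2/A2
  if (any(X2 > 0)) {
    Wm <- ifelse(A2 > 0, X2 / A2, 0)
    C1 <- C1 + A * (Wm %*% t(A)) + A * (t(A) %*% Wm)
  }
  g1 <- colSums(G[off[1L] + seq_len(na[1L]), , drop = FALSE])
  list(loglik = ll, G = G, C = C1, gamma1 = g1)
}

# M-step update of the diffusion coefficients: for each state maximize the
# gamma-weighted Gaussian log-likelihood over D by grouped closed form /
# bounded Brent search (per-spot sigma heterogeneity breaks the closed form).
update_D <- function(pack, G, D_old, dt, R, D_min, groups = NULL) {
  if (is.null(groups)) groups <- pack_groups(pack, dt, R)
  gid <- groups$gid; ngroup <- groups$ngroup
  ag <- groups$ag; s2g <- groups$s2g
  K <- ncol(G)
  D_new <- numeric(K)
  D_hi <- max(1, max(pack$r2) / (2 * min(groups$a)))
  for (k in seq_len(K)) {
    Sg <- rowsum(G[, k], gid, reorder = FALSE)[, 1L]
    Sgr <- rowsum(G[, k] * pack$r2, gid, reorder = FALSE)[, 1L]
    if (ngroup == 1L) {
      v_hat <- Sgr / (2 * Sg)
      D_new[k] <- max((v_hat - s2g) / ag, D_min)
    } else {
      f <- function(D) {
        v <- ag * D + s2g
        -sum(Sg * log(v) + Sgr / (2 * v))
      }
      opt <- stats::optimize(f, c(D_min, D_hi), maximum = TRUE,
                             tol = 1e-12)
      # keep whichever of {old, new} scores better: guards EM monotonicity
      D_new[k] <- if (f(opt$maximum) >= f(max(D_old[k], D_min)))
        opt$maximum else max(D_old[k], D_min)
    }
  }
  D_new
}

run_em <- function(pack, D0, A0, p00, dt, R, max_iter, tol, D_min) {
  groups <- pack_groups(pack, dt, R)
  D <- D0; A <- A0; p0 <- p00
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    fb <- forward_backward(pack, D, A, p0, dt, R)
    ll_trace <- c(ll_trace, fb$loglik)
    if (is.finite(ll_old) &&
        abs(fb$loglik - ll_old) < tol * (abs(ll_old) + 1e-3)) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    ll_old <- fb$loglik
    # M-step
    rs <- rowSums(fb$C)
    A_new <- fb$C / rs
    A_new[rs == 0, ] <- A[rs == 0, ]          # untouched state: keep row
    A <- A_new
    p0 <- fb$gamma1 / sum(fb$gamma1)
    D <- update_D(pack, fb$G, D, dt, R, D_min, groups)
  }
  list(D = D, A = A, p0 = p0, loglik = ll_trace[length(ll_trace)],
       ll_trace = ll_trace, converged = converged, iterations = iter,
       posterior_occupancy = colSums(
         forward_backward(pack, D, A, p0, dt, R)$G) / pack$total)
}

#' Fit a K-state diffusion HMM to a trajectory set
#'
#' Maximum-likelihood fitting by expectation-maximization over all
#' trajectories jointly. The E-step runs a scaled forward-backward pass per
#' trajectory (vectorized across trajectories); displacements spanning a
#' single-frame gap use the two-frame transition matrix A² and the
#' corresponding two-frame emission variance. The M-step updates the
#' transition matrix from expected transition counts (with gap-link counts
#' distributed over the latent mid-frame state, so EM remains exact and the
#' objective is non-decreasing), and each diffusion coefficient by a bounded
#' one-dimensional search, since per-spot localization uncertainties break
#' the closed-form update.
#'
#' Initialization spaces D log-uniformly on 0.005-5 µm²/s and sets the
#' transition matrix to 0.9 on the diagonal; restarts jitter D
#' multiplicatively (lognormal, 20%), seeded. The best restart is returned
#' with states sorted by ascending D and `pi` set to the stationary
#' distribution of the fitted per-frame transition matrix. During fitting
#' the initial-state distribution is a free (shared) parameter so EM is
#' exactly monotone; the reported log-likelihood re-scores the data with the
#' stationary initial distribution, matching [trajectory_loglik()].
#'
#' @param set A [trajectory_set()] (already filtered as desired).
#' @param options A [fit_options()] object.
#' @return A [diffusion_hmm()] with fit metadata (`converged`, `iterations`,
#'   `seed`, `ll_trace` of the best restart, `posterior_occupancy`).
#' @export
fit_hmm <- function(set, options) {
  stopifnot(inherits(set, "trajectory_set"), inherits(options, "fit_options"))
  pack <- pack_trajectories(set)
  dt <- set$acquisition$dt
  R <- blur_coefficient(set$acquisition)
  K <- options$K
  D_init <- if (K == 1L) 0.15 else exp(seq(log(0.005), log(5), length.out = K))
  A_init <- matrix(if (K > 1L) 0.1 / (K - 1) else 0, K, K)
  diag(A_init) <- if (K > 1L) 0.9 else 1
  best <- NULL
  for (r in seq_len(options$n_restarts)) {
    D0 <- if (r == 1L) D_init else {
      set.seed(options$seed + r - 1L)
      D_init * exp(stats::rnorm(K, 0, 0.2))
    }
    em <- run_em(pack, pmax(D0, options$D_min), A_init, rep(1 / K, K),
                 dt, R, options$max_iter, options$tol, options$D_min)
    if (is.null(best) || em$loglik > best$loglik) best <- em
  }
  # reported log-likelihood: stationary initial distribution (the model's pi)
  ord <- order(best$D)
  D <- best$D[ord]
  A <- best$A[ord, ord, drop = FALSE]
  A <- A / rowSums(A)
  pi <- stationary_distribution(A)
  ll <- forward_backward(pack, D, A, pi, dt, R, want_posteriors = FALSE)$loglik
  diffusion_hmm(D, A, R = R, loglik = ll,
                metadata = list(converged = best$converged,
                                iterations = best$iterations,
                                seed = options$seed,
                                n_restarts = options$n_restarts,
                                em_loglik = best$loglik,
                                ll_trace = best$ll_trace,
                                p0 = best$p0[ord],
                                posterior_occupancy =
                                  best$posterior_occupancy[ord],
                                dt = dt))
}

#' Fit a range of model sizes
#'
#' Convenience wrapper fitting one [fit_hmm()] model per requested number of
#' states (conventionally 2-11, with sizes 7-11 averaged downstream).
#'
#' @param set A [trajectory_set()].
#' @param K_range Integer vector of model sizes.
#' @param n_restarts,max_iter,tol,D_min,seed Passed to [fit_options()].
#' @return Named list of [diffusion_hmm()] objects (names `"K2"`, `"K3"`, ...).
#' @export
fit_hmm_sizes <- function(set, K_range = 2:11, n_restarts = 3L,
                          max_iter = 2000L, tol = 1e-8, D_min = 1e-6,
                          seed = 1L) {
  models <- lapply(K_range, function(K) {
    fit_hmm(set, fit_options(K = K, n_restarts = n_restarts,
                             max_iter = max_iter, tol = tol, D_min = D_min,
                             seed = seed + K))
  })
  names(models) <- paste0("K", K_range)
  models
}

check_model <- function(model) {
  stopifnot(inherits(model, "diffusion_hmm"))
  if (any(abs(rowSums(model$A) - 1) > 1e-8))
    stop("invalid model: transition matrix rows not normalized",
         call. = FALSE)
  invisible(model)
}

traj_step_data <- function(traj) {
  list(dx = diff(traj$x), dy = diff(traj$y), nf = diff(traj$frame),
       s2 = traj$sigma[-length(traj$sigma)]^2 + traj$sigma[-1L]^2)
}

#' Forward-algorithm log-likelihood of one trajectory
#'
#' Computes the exact marginal log-likelihood of a trajectory's displacement
#' series under a diffusion HMM by the scaled forward algorithm, initialized
#' at the model's stationary distribution. Displacements are independent
#' zero-mean Gaussians per dimension given the hidden state, with variance
#' [step_variance()]; a gap-spanning step uses `n_frames = 2` and the
#' two-frame transition matrix A².
#'
#' @param model A [diffusion_hmm()].
#' @param traj An `sp_trajectory` with at least one step.
#' @param acquisition An [acquisition_params()] object.
#' @return The log-likelihood (a scalar).
#' @seealso [bruteforce_loglik()] for the enumeration cross-check.
#' @export
trajectory_loglik <- function(model, traj, acquisition) {
  check_model(model)
  sd_ <- traj_step_data(traj)
  T_ <- length(sd_$dx)
  stopifnot(T_ >= 1L)
  dt <- acquisition$dt
  R <- blur_coefficient(acquisition)
  K <- model$K
  A2 <- model$A %*% model$A
  ll <- 0
  p <- model$pi
  for (s in seq_len(T_)) {
    v <- 2 * model$D * (sd_$nf[s] * dt) * (1 - 2 * R / sd_$nf[s]) + sd_$s2[s]
    le <- -log(2 * pi * v) - (sd_$dx[s]^2 + sd_$dy[s]^2) / (2 * v)
    m <- max(le)
    a <- p * exp(le - m)
    cc <- sum(a)
    ll <- ll + log(cc) + m
    if (s < T_) {
      Tr <- if (sd_$nf[s] == 2L) A2 else model$A
      p <- as.vector((a / cc) %*% Tr)
    }
  }
  ll
}

#' Brute-force log-likelihood by path enumeration
#'
#' Independent oracle for [trajectory_loglik()]: sums the joint probability
#' of the observations over every hidden-state sequence explicitly. Only
#' feasible for small instances; `K^steps` is capped at 1e6.
#'
#' @inheritParams trajectory_loglik
#' @return The log-likelihood (a scalar).
#' @export
bruteforce_loglik <- function(model, traj, acquisition) {
  check_model(model)
  sd_ <- traj_step_data(traj)
  T_ <- length(sd_$dx)
  stopifnot(T_ >= 1L)
  K <- model$K
  if (K^T_ > 1e6) stop("instance too large for enumeration", call. = FALSE)
  dt <- acquisition$dt
  R <- blur_coefficient(acquisition)
  A2 <- model$A %*% model$A
  # per-step emission log-densities, K x T
  E <- vapply(seq_len(T_), function(s) {
    v <- 2 * model$D * (sd_$nf[s] * dt) * (1 - 2 * R / sd_$nf[s]) + sd_$s2[s]
    -log(2 * pi * v) - (sd_$dx[s]^2 + sd_$dy[s]^2) / (2 * v)
  }, numeric(K))
  E <- matrix(E, nrow = K)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  logp <- log(model$pi)[paths[, 1L]] + E[cbind(paths[, 1L], 1L)]
  if (T_ > 1L) for (s in 2:T_) {
    Tr <- if (sd_$nf[s - 1L] == 2L) A2 else model$A
    logp <- logp + log(Tr)[cbind(paths[, s - 1L], paths[, s])] +
      E[cbind(paths[, s], s)]
  }
  m <- max(logp)
  m + log(sum(exp(logp - m)))
}

#' Serialize a diffusion HMM to JSON
#'
#' @param model A [diffusion_hmm()].
#' @param path Optional output path; if `NULL`, the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
model_to_json <- function(model, path = NULL) {
  check_model(model)
  obj <- list(K = model$K, D = model$D, A = as.vector(t(model$A)),
              pi = model$pi, R = model$R, loglik = model$loglik,
              n_params = model$n_params, aic = model$aic,
              metadata = model$metadata[c("converged", "iterations", "seed",
                                          "n_restarts", "dt")])
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Deserialize a diffusion HMM from JSON
#'
#' @param path Path to a JSON file written by [model_to_json()], or a JSON
#'   string.
#' @return A [diffusion_hmm()].
#' @export
model_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  A <- matrix(obj$A, obj$K, obj$K, byrow = TRUE)
  diffusion_hmm(obj$D, A, R = obj$R, loglik = obj$loglik,
                metadata = as.list(obj$metadata))
}
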