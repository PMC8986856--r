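#' Coarse-graining configuration
#'
#' Settings for collapsing multi-state diffusion HMMs into mRNA-bound and
#' free aggregates. The default threshold of 0.25 µm²/s separates
#' translating (mRNA-bound) from freely diffusing ribosomal subunits;
#' model sizes 7-11 are averaged because occupancies and dwell times
#' converge with increasing model size in that range.
#'
#' @param threshold Diffusion-coefficient cutoff (µm²/s); states strictly
#'   below it are labeled bound.
#' @param model_sizes Integer vector of model sizes entering the weighted
#'   cross-model average.
#' @param n_bootstrap Number of bootstrap replicates for standard errors
#'   (0 disables the bootstrap).
#' @param seed Integer seed for bootstrap resampling.
#' @return An object of class `coarse_grain_config`.
#' @export
coarse_grain_config <- function(threshold = 0.25, model_sizes = 7:11,
                                n_bootstrap = 100L, seed = 1L) {
  stopifnot(threshold > 0, length(model_sizes) >= 1L, n_bootstrap >= 0)
  structure(list(threshold = threshold, model_sizes = as.integer(model_sizes),
                 n_bootstrap = as.integer(n_bootstrap),
                 seed = as.integer(seed)),
            class = "coarse_grain_config")
}

#' Classify HMM states as mRNA-bound or free
#'
#' A state is bound iff its diffusion coefficient is strictly below the
#' threshold (a state at exactly the threshold is free). With the default
#' 0.25 µm²/s this reproduces the separation between translating and freely
#' diffusing ribosomal subunits established by initiation-inhibition
#' controls.
#'
#' @param model A [diffusion_hmm()].
#' @param threshold Cutoff in µm²/s.
#' @return Character vector (`"bound"`/`"free"`), one label per state.
#' @export
classify_states <- function(model, threshold = 0.25) {
  check_model(model)
  ifelse(model$D < threshold, "bound", "free")
}

#' Aggregate occupancy of the bound and free states
#'
#' Sums the stationary occupancy over the states of each aggregate. An empty
#' aggregate has occupancy 0 (with a message).
#'
#' @param model A [diffusion_hmm()].
#' @param labels Labels from [classify_states()].
#' @return Named numeric vector `c(bound = ..., free = ...)`, summing to 1.
#' @export
aggregate_occupancy <- function(model, labels) {
  check_model(model)
  stopifnot(length(labels) == model$K)
  occ <- c(bound = sum(model$pi[labels == "bound"]),
           free = sum(model$pi[labels == "free"]))
  if (any(occ == 0))
    message("empty aggregate: ", names(occ)[occ == 0])
  occ
}

#' Mean dwell time in the bound and free aggregates
#'
#' For an aggregate S of states, the per-frame probability of staying within
#' the aggregate is the occupancy-weighted average of the within-aggregate
#' transition mass,
#' \deqn{p_{stay} = \sum_{i \in S} w_i \sum_{j \in S} A_{ij}, \quad
#'       w_i = \pi_i / \sum_{k \in S} \pi_k,}
#' and the mean dwell time is \eqn{\tau_S = \Delta t / (1 - p_{stay})}. For a
#' single-state aggregate this reduces to the diagonal element of the
#' transition matrix. Because the estimate comes from per-frame stay
#' probabilities, dwell times far longer than any single trajectory can be
#' estimated. An absorbing aggregate (p_stay = 1) yields `Inf` with a
#' warning.
#'
#' @param model A [diffusion_hmm()].
#' @param labels Labels from [classify_states()]; both aggregates must be
#'   nonempty.
#' @param dt Frame time in seconds.
#' @return Named numeric vector `c(bound = tau_bound, free = tau_free)` in
#'   seconds.
#' @export
aggregate_dwell_time <- function(model, labels, dt) {
  check_model(model)
  stopifnot(length(labels) == model$K, dt > 0)
  vapply(c(bound = "bound", free = "free"), function(lab) {
    S <- which(labels == lab)
    if (length(S) == 0L)
      stop("empty aggregate: ", lab, call. = FALSE)
    w <- model$pi[S] / sum(model$pi[S])
    p_stay <- sum(w * rowSums(model$A[S, S, drop = FALSE]))
    if (p_stay >= 1) {
      warning("absorbing aggregate '", lab, "': infinite dwell time",
              call. = FALSE)
      return(Inf)
    }
    max(dt / (1 - p_stay), dt)
  }, numeric(1))
}

#' Coarse-grain one fitted model into two functional states
#'
#' @param model A [diffusion_hmm()].
#' @param dt Frame time (s); defaults to the dt recorded in the model's fit
#'   metadata.
#' @param threshold Diffusion cutoff (µm²/s).
#' @return A one-row data frame with columns `K`, `occupancy_bound`,
#'   `occupancy_free`, `tau_bound`, `tau_free`.
#' @export
coarse_grain <- function(model, dt = model$metadata$dt, threshold = 0.25) {
  labels <- classify_states(model, threshold)
  occ <- aggregate_occupancy(model, labels)
  tau <- aggregate_dwell_time(model, labels, dt)
  data.frame(K = model$K, occupancy_bound = occ[["bound"]],
             occupancy_free = occ[["free"]], tau_bound = tau[["bound"]],
             tau_free = tau[["free"]])
}

#' Weighted average of coarse summaries across model sizes
#'
#' Combines per-model-size occupancies and dwell times into weighted means
#' with weighted standard deviations, as used to report one estimate per
#' condition from model sizes 7-11. Default weights are the inverse
#' bootstrap variances when bootstrap standard errors are available (columns
#' `se_*`), otherwise equal weights.
#'
#' @param summaries Data frame with one row per model size (from
#'   [coarse_grain()], optionally with `se_` columns from
#'   [bootstrap_errors()]).
#' @param weights Optional matrix/data frame of positive weights per quantity
#'   (columns `occupancy_bound`, `occupancy_free`, `tau_bound`, `tau_free`)
#'   or a single vector recycled across quantities.
#' @return A list with `mean`, `wsd` (weighted standard deviation) named
#'   vectors over the four quantities, the `weights` used, and the input
#'   `summaries`.
#' @export
weighted_model_average <- function(summaries, weights = NULL) {
  qty <- c("occupancy_bound", "occupancy_free", "tau_bound", "tau_free")
  stopifnot(all(qty %in% names(summaries)), nrow(summaries) >= 1L)
  n <- nrow(summaries)
  if (is.null(weights)) {
    se_cols <- paste0("se_", qty)
    if (all(se_cols %in% names(summaries)) &&
        all(is.finite(as.matrix(summaries[se_cols])))) {
      W <- 1 / pmax(as.matrix(summaries[se_cols]), 1e-12)^2
      colnames(W) <- qty
      scheme <- "inverse_bootstrap_variance"
    } else {
      W <- matrix(1, n, length(qty), dimnames = list(NULL, qty))
      scheme <- "equal"
    }
  } else {
    W <- if (is.null(dim(weights)))
      matrix(weights, n, length(qty), dimnames = list(NULL, qty))
    else as.matrix(weights)[, qty, drop = FALSE]
    scheme <- "user"
  }
  if (any(colSums(W) <= 0)) stop("all-zero weights", call. = FALSE)
  m <- vapply(qty, function(q) sum(W[, q] * summaries[[q]]) / sum(W[, q]),
              numeric(1))
  wsd <- vapply(qty, function(q) {
    sqrt(sum(W[, q] * (summaries[[q]] - m[[q]])^2) / sum(W[, q]))
  }, numeric(1))
  list(mean = m, wsd = wsd, weights = W, scheme = scheme,
       summaries = summaries)
}

#' Bootstrap standard errors for coarse-grained quantities
#'
#' Resamples trajectories with replacement (the trajectory being the
#' exchangeable unit of the pooled fit), refits the K-state model
#' warm-started from the full-data fit, coarse-grains each replicate, and
#' returns the standard deviation across replicates. Replicates that fail to
#' converge are dropped and counted; more than 20% dropped is an error.
#'
#' @param set A [trajectory_set()] (filtered).
#' @param K Model size.
#' @param config A [coarse_grain_config()] with `n_bootstrap >= 2`.
#' @param fit Optional full-data [fit_hmm()] fit to warm-start from; fitted
#'   here if missing.
#' @param max_iter Maximum EM iterations per replicate refit.
#' @return Named vector `c(se_occupancy_bound, se_occupancy_free,
#'   se_tau_bound, se_tau_free)` with attributes `n_dropped` and
#'   `replicates` (the per-replicate coarse summaries).
#' @export
bootstrap_errors <- function(set, K, config = coarse_grain_config(),
                             fit = NULL, max_iter = 200L) {
  stopifnot(inherits(set, "trajectory_set"), config$n_bootstrap >= 2L)
  if (is.null(fit))
    fit <- fit_hmm(set, fit_options(K = K, seed = config$seed))
  dt <- set$acquisition$dt
  R <- blur_coefficient(set$acquisition)
  ntraj <- length(set$trajectories)
  set.seed(config$seed)
  reps <- vector("list", config$n_bootstrap)
  dropped <- 0L
  for (b in seq_len(config$n_bootstrap)) {
    idx <- sample.int(ntraj, ntraj, replace = TRUE)
    trajs <- set$trajectories[idx]
    for (i in seq_along(trajs)) trajs[[i]]$traj_id <- paste0("b", b, "_", i)
    bset <- trajectory_set(trajs, set$acquisition)
    pack <- pack_trajectories(bset)
    em <- run_em(pack, fit$D, fit$A, fit$pi, dt, R,
                 max_iter = max_iter, tol = 1e-7, D_min = 1e-6)
    rep_cg <- if (em$converged) tryCatch({
      model <- diffusion_hmm(em$D, em$A, R = R, loglik = em$loglik)
      coarse_grain(model, dt = dt, threshold = config$threshold)
    }, error = function(e) NULL) else NULL
    if (is.null(rep_cg)) dropped <- dropped + 1L
    reps[[b]] <- rep_cg
  }
  if (dropped > 0.2 * config$n_bootstrap)
    stop(dropped, " of ", config$n_bootstrap,
         " bootstrap replicates failed to converge", call. = FALSE)
  repdf <- do.call(rbind, reps[!vapply(reps, is.null, logical(1))])
  qty <- c("occupancy_bound", "occupancy_free", "tau_bound", "tau_free")
  se <- vapply(qty, function(q) stats::sd(repdf[[q]]), numeric(1))
  names(se) <- paste0("se_", qty)
  attr(se, "n_dropped") <- dropped
  attr(se, "replicates") <- repdf
  se
}

#' Sensitivity of coarse-grained estimates to the threshold
#'
#' Re-coarse-grains already-fitted models at each candidate threshold (no
#' refitting) and reports the relative change of each quantity against the
#' reference threshold.
#'
#' @param models List of [diffusion_hmm()] objects (one per model size).
#' @param thresholds Numeric vector of thresholds (µm²/s).
#' @param dt Frame time (s); defaults to the dt of the first model's fit
#'   metadata.
#' @param reference Reference threshold (default 0.25).
#' @return Data frame with one row per (model size, threshold), columns for
#'   the four quantities and their relative change vs the reference.
#' @export
threshold_sensitivity <- function(models, thresholds, dt = NULL,
                                  reference = 0.25) {
  if (inherits(models, "diffusion_hmm")) models <- list(models)
  if (is.null(dt)) dt <- models[[1L]]$metadata$dt
  # empty aggregates (threshold beyond all fitted D) keep their occupancy
  # of 0 but have no dwell time
  soft_cg <- function(m, th) {
    labels <- classify_states(m, th)
    occ <- suppressMessages(aggregate_occupancy(m, labels))
    tau <- tryCatch(suppressWarnings(
      aggregate_dwell_time(m, labels, dt)),
      error = function(e) c(bound = NA_real_, free = NA_real_))
    data.frame(K = m$K, occupancy_bound = occ[["bound"]],
               occupancy_free = occ[["free"]], tau_bound = tau[["bound"]],
               tau_free = tau[["free"]])
  }
  rows <- lapply(models, function(m) {
    ref <- soft_cg(m, reference)
    do.call(rbind, lapply(thresholds, function(th) {
      cg <- soft_cg(m, th)
      cg$threshold <- th
      for (q in c("occupancy_bound", "occupancy_free", "tau_bound",
                  "tau_free"))
        cg[[paste0("rel_change_", q)]] <- cg[[q]] / ref[[q]] - 1
      cg
    }))
  })
  do.call(rbind, rows)
}
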