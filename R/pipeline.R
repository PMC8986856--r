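#' Steady-state occupancy implied by two dwell times
#'
#' For a two-state Markov chain with mean dwell times `tau_bound` and
#' `tau_free`, the stationary occupancies follow from the per-frame chain
#' built by [transition_matrix_from_dwells()] and are independent of the
#' frame time: the bound fraction is tau_bound / (tau_bound + tau_free).
#' Used as a consistency check between reported dwell times and reported
#' occupancies.
#'
#' @param tau_bound,tau_free Mean dwell times (s).
#' @return Named vector `c(bound = ..., free = ...)`.
#' @export
implied_occupancy <- function(tau_bound, tau_free) {
  dt <- min(tau_bound, tau_free) / 10
  A <- transition_matrix_from_dwells(c(tau_bound, tau_free), dt)
  pi <- stationary_distribution(A)
  c(bound = pi[1L], free = pi[2L])
}

#' Validate and normalize a pipeline configuration
#'
#' Fills defaults (threshold 0.25 µm²/s, minimum 10 steps, model sizes
#' 2-11 fitted and 7-11 averaged), checks units and ranges, and returns a
#' normalized `pipeline_config`. Exactly one of `input` (trajectory CSV
#' path) or `scenario` (simulation preset name) must be set. Violations are
#' collected and reported together, each naming the offending key.
#'
#' @param config A named list (e.g. parsed from a YAML file): keys `input`,
#'   `scenario`, `n_trajectories`, `acquisition` (`dt_s`, `t_pulse_s`,
#'   `pixel_size_um`), `min_steps`, `fit` (`K_range`, `n_restarts`,
#'   `max_iter`, `tol`, `D_min`), `coarse` (`threshold`, `model_sizes`,
#'   `n_bootstrap`, `thresholds`), `msd` (`segment_length`, `n_fit_points`),
#'   `out_dir`, `seed`.
#' @return A `pipeline_config` object, or an error listing every violation.
#' @export
validate_config <- function(config = list()) {
  errs <- character(0)
  get <- function(path, default) {
    x <- config
    for (k in strsplit(path, ".", fixed = TRUE)[[1L]]) {
      if (is.null(x[[k]])) return(default)
      x <- x[[k]]
    }
    x
  }
  cf <- list(
    input = get("input", NULL),
    scenario = get("scenario", NULL),
    n_trajectories = get("n_trajectories", 3000L),
    acquisition = list(dt_s = get("acquisition.dt_s", 0.03),
                       t_pulse_s = get("acquisition.t_pulse_s", 0.003),
                       pixel_size_um = get("acquisition.pixel_size_um",
                                           NA_real_)),
    min_steps = get("min_steps", 10L),
    fit = list(K_range = get("fit.K_range", 2:11),
               n_restarts = get("fit.n_restarts", 3L),
               max_iter = get("fit.max_iter", 2000L),
               tol = get("fit.tol", 1e-8),
               D_min = get("fit.D_min", 1e-6)),
    coarse = list(threshold = get("coarse.threshold", 0.25),
                  model_sizes = get("coarse.model_sizes", 7:11),
                  n_bootstrap = get("coarse.n_bootstrap", 0L),
                  thresholds = get("coarse.thresholds",
                                   seq(0.15, 0.40, by = 0.05))),
    msd = list(segment_length = get("msd.segment_length", 7L),
               n_fit_points = get("msd.n_fit_points", 3L)),
    out_dir = get("out_dir", NULL),
    seed = get("seed", 1L))
  if (is.null(cf$input) == is.null(cf$scenario))
    errs <- c(errs, "input/scenario: exactly one of the two must be set")
  if (!is.null(cf$scenario) &&
      !cf$scenario %in% scenario_table()$name)
    errs <- c(errs, paste0("scenario: unknown preset '", cf$scenario, "'"))
  if (cf$acquisition$dt_s <= 0)
    errs <- c(errs, "acquisition.dt_s: must be > 0")
  if (cf$acquisition$t_pulse_s <= 0 ||
      cf$acquisition$t_pulse_s > cf$acquisition$dt_s)
    errs <- c(errs, "acquisition.t_pulse_s: must be in (0, dt_s]")
  if (cf$coarse$threshold <= 0)
    errs <- c(errs, "coarse.threshold: must be > 0")
  if (cf$min_steps < 0)
    errs <- c(errs, "min_steps: must be >= 0")
  if (any(cf$fit$K_range < 1) || any(cf$fit$K_range > 20))
    errs <- c(errs, "fit.K_range: sizes must lie in [1, 20]")
  if (cf$fit$tol <= 0)
    errs <- c(errs, "fit.tol: must be > 0")
  if (length(cf$coarse$model_sizes) == 0L)
    errs <- c(errs, "coarse.model_sizes: must be nonempty")
  if (length(errs) > 0L)
    stop("invalid pipeline config:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  cf$R <- blur_coefficient(acquisition_params(cf$acquisition$dt_s,
                                              cf$acquisition$t_pulse_s))
  structure(cf, class = "pipeline_config")
}

write_csv9 <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) df[[j]] <- sprintf("%.9g", df[[j]])
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
}

#' Run the full tracking analysis pipeline
#'
#' Orchestrates an end-to-end run: simulate (or load) trajectories, filter
#' short tracks, fit diffusion HMMs across the configured model sizes,
#' coarse-grain each into bound/free aggregates, average across model
#' sizes (bootstrap errors optional), compute the MSD apparent-D
#' distribution and the threshold-sensitivity table, and assemble a
#' machine-readable report. All stage seeds are derived deterministically
#' from the global seed (simulation: seed; fitting: seed + 100 + K;
#' bootstrap: seed + 200 + K), so identical configs give identical reports;
#' changing only the bootstrap settings does not change the fitted models.
#' If a stage fails, completed outputs are retained and the report marks the
#' failed stage.
#'
#' @param config A `pipeline_config` from [validate_config()] (a plain list
#'   is validated first).
#' @param quiet Suppress progress messages.
#' @return The report, a list with elements `config`, `data`, `models`
#'   (per-size parameters), `aic`, `coarse` (per-size and aggregate),
#'   `msd`, `threshold_sensitivity`, `failed_stage` (`NULL` on success).
#'   When `out_dir` is set, models (JSON), tables (CSV) and the report
#'   (JSON) are also written there.
#' @export
run_full_analysis <- function(config, quiet = FALSE) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  say <- function(...) if (!quiet) message(...)
  report <- list(schema_version = "1.0",
                 package_version = as.character(
                   utils::packageVersion("spthmm")),
                 config = unclass(config), failed_stage = NULL)
  out <- config$out_dir
  if (!is.null(out) && !dir.exists(out))
    dir.create(out, recursive = TRUE)
  acq <- acquisition_params(config$acquisition$dt_s,
                            config$acquisition$t_pulse_s,
                            config$acquisition$pixel_size_um)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      report$failed_stage <<- list(stage = name,
                                   message = conditionMessage(e))
      say("stage '", name, "' failed: ", conditionMessage(e))
      NULL
    })
  }
  # --- data ---------------------------------------------------------------
  truth <- NULL
  set <- stage("data", {
    if (!is.null(config$scenario)) {
      say("simulating scenario ", config$scenario)
      sim <- simulate_dataset(scenario_config(
        config$scenario, n_trajectories = config$n_trajectories,
        seed = config$seed))
      truth <- sim$truth
      sim$set
    } else {
      say("reading ", config$input)
      read_trajectories(config$input, acq)
    }
  })
  if (is.null(set)) return(report)
  fset <- filter_trajectories(set, config$min_steps)
  report$data <- list(
    n_trajectories = length(set), n_after_filter = length(fset),
    n_steps = sum(vapply(fset$trajectories, n_steps, integer(1))),
    truth = if (!is.null(truth))
      as.list(truth_coarse_summary(truth, config$coarse$threshold)))
  say(report$data$n_after_filter, " trajectories with >= ",
      config$min_steps, " steps (", report$data$n_steps, " steps)")
  # --- fitting ------------------------------------------------------------
  models <- stage("fit", {
    fit_hmm_sizes(fset, K_range = config$fit$K_range,
                  n_restarts = config$fit$n_restarts,
                  max_iter = config$fit$max_iter, tol = config$fit$tol,
                  D_min = config$fit$D_min, seed = config$seed + 100L)
  })
  if (is.null(models)) return(report)
  for (nm in names(models))
    say(nm, ": logLik = ", sprintf("%.2f", models[[nm]]$loglik),
        ", iterations = ", models[[nm]]$metadata$iterations)
  report$models <- lapply(models, function(m)
    list(K = m$K, D = m$D, A = as.vector(t(m$A)), pi = m$pi, R = m$R,
         loglik = m$loglik, n_params = m$n_params, aic = m$aic,
         converged = m$metadata$converged,
         iterations = m$metadata$iterations))
  report$aic <- data.frame(
    K = vapply(models, `[[`, integer(1), "K"),
    loglik = vapply(models, `[[`, numeric(1), "loglik"),
    aic = vapply(models, `[[`, numeric(1), "aic"))
  # --- coarse-graining ----------------------------------------------------
  coarse <- stage("coarse_grain", {
    per_size <- do.call(rbind, lapply(models, function(m)
      coarse_grain(m, dt = acq$dt, threshold = config$coarse$threshold)))
    if (config$coarse$n_bootstrap >= 2L) {
      ses <- lapply(names(models), function(nm) {
        K <- models[[nm]]$K
        if (!K %in% config$coarse$model_sizes) return(NULL)
        say("bootstrap for K = ", K)
        bootstrap_errors(fset, K,
                         coarse_grain_config(
                           threshold = config$coarse$threshold,
                           model_sizes = config$coarse$model_sizes,
                           n_bootstrap = config$coarse$n_bootstrap,
                           seed = config$seed + 200L + K),
                         fit = models[[nm]])
      })
      for (i in seq_along(ses)) if (!is.null(ses[[i]]))
        per_size[i, names(ses[[i]])] <- as.list(ses[[i]])
    }
    avg_rows <- per_size$K %in% config$coarse$model_sizes
    agg <- if (any(avg_rows))
      weighted_model_average(per_size[avg_rows, , drop = FALSE]) else NULL
    list(per_size = per_size, aggregate = agg)
  })
  if (!is.null(coarse)) {
    report$coarse <- list(
      per_size = coarse$per_size,
      aggregate = if (!is.null(coarse$aggregate))
        list(mean = as.list(coarse$aggregate$mean),
             wsd = as.list(coarse$aggregate$wsd),
             scheme = coarse$aggregate$scheme))
    if (!is.null(coarse$aggregate))
      say(sprintf(
        "aggregate (sizes %s): tau_bound = %.3g s, tau_free = %.3g s, occ_free = %.3g",
        paste(range(config$coarse$model_sizes), collapse = "-"),
        coarse$aggregate$mean[["tau_bound"]],
        coarse$aggregate$mean[["tau_free"]],
        coarse$aggregate$mean[["occupancy_free"]]))
  }
  # --- MSD ----------------------------------------------------------------
  msd <- stage("msd", {
    D_distribution(fset, acq, msd_config(config$msd$segment_length,
                                         config$msd$n_fit_points))
  })
  if (!is.null(msd)) {
    report$msd <- list(n_segments = nrow(msd$segments), mean = msd$mean,
                       median = msd$median)
    say(sprintf("MSD: %d segments, mean apparent D = %.4g um2/s",
                nrow(msd$segments), msd$mean))
  }
  # --- threshold sensitivity ---------------------------------------------
  tsens <- stage("threshold_sensitivity", {
    threshold_sensitivity(models, config$coarse$thresholds, dt = acq$dt,
                          reference = config$coarse$threshold)
  })
  if (!is.null(tsens)) report$threshold_sensitivity <- tsens
  # --- outputs ------------------------------------------------------------
  if (!is.null(out)) {
    stage("write_outputs", {
      for (nm in names(models))
        model_to_json(models[[nm]], file.path(out, paste0("model_", nm,
                                                          ".json")))
      if (!is.null(coarse)) {
        write_csv9(coarse$per_size, file.path(out, "coarse_summary.csv"))
        if (!is.null(coarse$aggregate)) {
          agg_df <- data.frame(quantity = names(coarse$aggregate$mean),
                               mean = unname(coarse$aggregate$mean),
                               weighted_sd = unname(coarse$aggregate$wsd))
          write_csv9(agg_df, file.path(out, "coarse_aggregate.csv"))
        }
      }
      write_csv9(report$aic, file.path(out, "aic.csv"))
      if (!is.null(msd)) {
        write_csv9(msd$segments, file.path(out, "msd_segments.csv"))
        write_csv9(msd$histogram, file.path(out, "msd_histogram.csv"))
      }
      if (!is.null(tsens))
        write_csv9(tsens, file.path(out, "threshold_sensitivity.csv"))
      if (!is.null(config$scenario))
        write_trajectories(set, file.path(out, "trajectories.csv"))
      jsonlite::write_json(report, file.path(out, "report.json"),
                           auto_unbox = TRUE, digits = NA, null = "null",
                           dataframe = "columns")
      NULL
    })
  }
  report
}
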