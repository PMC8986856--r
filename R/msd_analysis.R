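#' MSD analysis configuration
#'
#' @param segment_length Localizations per segment (default 7).
#' @param n_fit_points Number of MSD lags used in the origin-constrained
#'   linear fit (default 3).
#' @param dimension Spatial dimension of the trajectories (fixed at 2).
#' @return An object of class `msd_config`.
#' @export
msd_config <- function(segment_length = 7L, n_fit_points = 3L,
                       dimension = 2L) {
  stopifnot(n_fit_points < segment_length, dimension == 2L,
            n_fit_points >= 1L)
  structure(list(segment_length = as.integer(segment_length),
                 n_fit_points = as.integer(n_fit_points),
                 dimension = as.integer(dimension)),
            class = "msd_config")
}

#' Cut trajectories into gap-free segments
#'
#' Partitions each trajectory into non-overlapping consecutive windows of
#' exactly `segment_length` gap-free localizations (frame difference 1
#' throughout); the remainder is discarded and segments never span a
#' tracking gap.
#'
#' @param set A [trajectory_set()].
#' @param config An [msd_config()].
#' @return List of segments; each is a list with `traj_id`, `segment_id`,
#'   `x`, `y`.
#' @export
segment_trajectories <- function(set, config = msd_config()) {
  stopifnot(inherits(set, "trajectory_set"))
  L <- config$segment_length
  segs <- list()
  for (traj in set$trajectories) {
    runs <- split(seq_along(traj$frame),
                  cumsum(c(1L, diff(traj$frame) != 1L)))
    si <- 0L
    for (run in runs) {
      nseg <- length(run) %/% L
      for (i in seq_len(nseg)) {
        si <- si + 1L
        idx <- run[((i - 1L) * L + 1L):(i * L)]
        segs[[length(segs) + 1L]] <-
          list(traj_id = traj$traj_id,
               segment_id = paste0(traj$traj_id, ".", si),
               x = traj$x[idx], y = traj$y[idx])
      }
    }
  }
  segs
}

#' Apparent diffusion coefficient of one segment
#'
#' Computes the empirical MSD at lags 1..`n_fit_points`, each averaged over
#' all in-segment position pairs at that lag (time average), and fits a line
#' through the origin by ordinary least squares to
#' \deqn{MSD(t) = 2 n D \Delta t \cdot t, \qquad t = 1, 2, 3,}
#' with n = 2 the spatial dimension. No localization-error or blur
#' correction is applied: the estimate is deliberately the *apparent*
#' diffusion coefficient.
#'
#' @param segment One segment from [segment_trajectories()] (or any list
#'   with equal-length `x`, `y`).
#' @param acquisition An [acquisition_params()] object.
#' @param config An [msd_config()].
#' @return Apparent D in µm²/s (non-negative).
#' @export
apparent_D <- function(segment, acquisition, config = msd_config()) {
  x <- segment$x; y <- segment$y
  L <- length(x)
  stopifnot(length(y) == L)
  kmax <- config$n_fit_points
  if (L - 1L < kmax)
    stop("segment too short for ", kmax, " MSD lags", call. = FALSE)
  msd <- vapply(seq_len(kmax), function(k) {
    i <- seq_len(L - k)
    mean((x[i + k] - x[i])^2 + (y[i + k] - y[i])^2)
  }, numeric(1))
  k <- seq_len(kmax)
  slope <- sum(k * msd) / sum(k^2)        # OLS through the origin
  slope / (2 * config$dimension * acquisition$dt)
}

#' Distribution of apparent diffusion coefficients
#'
#' Applies [apparent_D()] to every segment of a trajectory set, returning
#' the per-segment values, summary statistics and a log-spaced histogram.
#' The overall mean is the apparent average diffusion coefficient reported
#' per experimental condition.
#'
#' @param set A [trajectory_set()].
#' @param acquisition Acquisition parameters; defaults to the set's.
#' @param config An [msd_config()].
#' @param n_bins Number of log-spaced histogram bins.
#' @return An object of class `msd_result`: data frame `segments`
#'   (`segment_id`, `traj_id`, `D_app_um2_s`), `mean`, `median`, and
#'   `histogram` (data frame of bin edges and counts).
#' @export
D_distribution <- function(set, acquisition = set$acquisition,
                           config = msd_config(), n_bins = 40L) {
  segs <- segment_trajectories(set, config)
  if (length(segs) == 0L)
    stop("no segments of length ", config$segment_length, call. = FALSE)
  D <- vapply(segs, apparent_D, numeric(1), acquisition = acquisition,
              config = config)
  df <- data.frame(
    segment_id = vapply(segs, `[[`, character(1), "segment_id"),
    traj_id = vapply(segs, `[[`, character(1), "traj_id"),
    D_app_um2_s = D, stringsAsFactors = FALSE)
  pos <- D[D > 0]
  histogram <- if (length(pos) >= 2L) {
    breaks <- exp(seq(log(min(pos)), log(max(pos)), length.out = n_bins + 1L))
    breaks[1L] <- breaks[1L] * (1 - 1e-9)
    h <- graphics::hist(pos, breaks = breaks, plot = FALSE)
    data.frame(lower = h$breaks[-length(h$breaks)], upper = h$breaks[-1L],
               count = h$counts)
  } else data.frame(lower = numeric(), upper = numeric(), count = integer())
  structure(list(segments = df, mean = mean(D), median = stats::median(D),
                 n_zero = sum(D == 0), histogram = histogram),
            class = "msd_result")
}

#' @export
print.msd_result <- function(x, ...) {
  cat(sprintf("MSD result: %d segments, mean apparent D = %.4g um2/s, ",
              nrow(x$segments), x$mean))
  cat(sprintf("median = %.4g um2/s\n", x$median))
  invisible(x)
}
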