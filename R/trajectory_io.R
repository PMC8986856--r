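#' Acquisition parameters
#'
#' Frame time and illumination pulse duration for a stroboscopic
#' single-particle tracking acquisition. The pulse duration sets the
#' motion-blur coefficient used by the emission model (see
#' [blur_coefficient()]); typical live-cell ribosome tracking uses 3 ms laser
#' pulses within 30 or 60 ms camera exposures.
#'
#' @param dt Frame time in seconds (> 0).
#' @param t_pulse Illumination pulse duration in seconds; must satisfy
#'   `0 < t_pulse <= dt`.
#' @param pixel_size Camera pixel size in micrometers (metadata only, may be
#'   `NA`).
#' @return An object of class `acquisition_params`.
#' @examples
#' acquisition_params(dt = 0.03, t_pulse = 0.003)
#' @export
acquisition_params <- function(dt, t_pulse = dt, pixel_size = NA_real_) {
  stopifnot(is.numeric(dt), length(dt) == 1L, is.finite(dt), dt > 0,
            is.numeric(t_pulse), length(t_pulse) == 1L, is.finite(t_pulse))
  if (t_pulse <= 0 || t_pulse > dt)
    stop("t_pulse must satisfy 0 < t_pulse <= dt", call. = FALSE)
  structure(list(dt = as.numeric(dt), t_pulse = as.numeric(t_pulse),
                 pixel_size = as.numeric(pixel_size)),
            class = "acquisition_params")
}

#' @export
print.acquisition_params <- function(x, ...) {
  cat(sprintf("Acquisition: dt = %g s, t_pulse = %g s (R = %.5g)\n",
              x$dt, x$t_pulse, blur_coefficient(x)))
  invisible(x)
}

# Internal constructor for one trajectory. Vectors must be equally long,
# frames strictly increasing with consecutive differences in {1, 2}.
new_trajectory <- function(traj_id, cell_id, frame, x, y, sigma,
                           validate = TRUE) {
  traj <- structure(
    list(traj_id = as.character(traj_id), cell_id = as.character(cell_id),
         frame = as.integer(frame), x = as.numeric(x), y = as.numeric(y),
         sigma = as.numeric(sigma)),
    class = "sp_trajectory")
  if (validate) validate_trajectory(traj)
  traj
}

validate_trajectory <- function(traj) {
  n <- length(traj$frame)
  if (n < 2L)
    stop("trajectory '", traj$traj_id, "' has fewer than 2 localizations",
         call. = FALSE)
  if (length(traj$x) != n || length(traj$y) != n || length(traj$sigma) != n)
    stop("trajectory '", traj$traj_id, "' has ragged fields", call. = FALSE)
  if (any(!is.finite(traj$x)) || any(!is.finite(traj$y)))
    stop("trajectory '", traj$traj_id, "' has non-finite coordinates",
         call. = FALSE)
  if (any(traj$sigma < 0) || any(!is.finite(traj$sigma)))
    stop("trajectory '", traj$traj_id, "' has invalid sigma", call. = FALSE)
  if (any(traj$frame < 0L))
    stop("trajectory '", traj$traj_id, "' has negative frame index",
         call. = FALSE)
  d <- diff(traj$frame)
  if (any(d < 1L))
    stop("trajectory '", traj$traj_id,
         "' frames are not strictly increasing", call. = FALSE)
  if (any(d > 2L))
    stop("trajectory '", traj$traj_id, "' contains a gap of more than one ",
         "missing frame; split it first", call. = FALSE)
  invisible(traj)
}

#' Number of steps in a trajectory
#'
#' A step is one displacement between consecutive retained localizations; a
#' displacement spanning a single-frame gap counts as one step.
#'
#' @param traj An `sp_trajectory`.
#' @return Integer step count (number of localizations minus one).
#' @export
n_steps <- function(traj) length(traj$frame) - 1L

#' Construct a trajectory set
#'
#' Bundles trajectories with the shared acquisition parameters under which
#' they were recorded. Trajectory ids must be unique.
#'
#' @param trajectories List of `sp_trajectory` objects.
#' @param acquisition An [acquisition_params()] object.
#' @return An object of class `trajectory_set`.
#' @export
trajectory_set <- function(trajectories, acquisition) {
  stopifnot(inherits(acquisition, "acquisition_params"), is.list(trajectories))
  ids <- vapply(trajectories, function(t) t$traj_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate traj_id: ", paste(unique(ids[duplicated(ids)]),
                                      collapse = ", "), call. = FALSE)
  structure(list(trajectories = trajectories, acquisition = acquisition),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  ns <- vapply(x$trajectories, n_steps, integer(1))
  cat(sprintf("Trajectory set: %d trajectories, %d steps total (dt = %g s)\n",
              length(x$trajectories), sum(ns), x$acquisition$dt))
  invisible(x)
}

#' @export
length.trajectory_set <- function(x) length(x$trajectories)

#' @export
as.data.frame.trajectory_set <- function(x, ...) {
  if (length(x$trajectories) == 0L)
    return(data.frame(traj_id = character(), cell_id = character(),
                      frame = integer(), x_um = numeric(), y_um = numeric(),
                      sigma_um = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, lapply(x$trajectories, function(t) {
    data.frame(traj_id = t$traj_id, cell_id = t$cell_id, frame = t$frame,
               x_um = t$x, y_um = t$y, sigma_um = t$sigma,
               stringsAsFactors = FALSE)
  }))
}

# Split a block of rows (one raw traj_id, frame-sorted) wherever the frame
# difference exceeds 2 (more than one missing point); suffix the pieces.
# Pieces left with < 2 localizations are dropped (counted by the caller).
split_on_gaps <- function(traj_id, cell_id, frame, x, y, sigma) {
  brk <- c(0L, which(diff(frame) > 2L), length(frame))
  pieces <- list()
  n_pieces <- length(brk) - 1L
  for (i in seq_len(n_pieces)) {
    idx <- (brk[i] + 1L):brk[i + 1L]
    if (length(idx) < 2L) next
    id <- if (n_pieces == 1L) traj_id else paste0(traj_id, "_", i)
    pieces[[length(pieces) + 1L]] <-
      new_trajectory(id, cell_id[idx[1L]], frame[idx], x[idx], y[idx],
                     sigma[idx])
  }
  pieces
}

#' Read single-particle trajectories from CSV
#'
#' Reads a trajectory table in the package's fixed dialect: comma-separated
#' with header `traj_id,cell_id,frame,x_um,y_um,sigma_um`; positions in
#' micrometers, frames as 0-based integers, `sigma_um` the per-localization
#' uncertainty standard deviation per coordinate. Rows are grouped by
#' `traj_id` and sorted by frame. Within one id, a frame jump of more than 2
#' (i.e. more than one missing point) splits the track into separate
#' trajectories with suffixed ids, mirroring linkers that allow gaps of one
#' missing point only. Rows with non-finite coordinates are dropped with a
#' warning; resulting fragments of fewer than 2 localizations are dropped.
#'
#' @param path Path to a CSV file.
#' @param acquisition An [acquisition_params()] object.
#' @param default_sigma Optional global localization uncertainty (µm) used
#'   when the `sigma_um` column is absent (a message is emitted).
#' @return A [trajectory_set()].
#' @seealso [write_trajectories()], [filter_trajectories()]
#' @export
read_trajectories <- function(path, acquisition, default_sigma = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("traj_id", "cell_id", "frame", "x_um", "y_um")
  if (!all(need %in% names(df)))
    stop("missing required column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  if (!"sigma_um" %in% names(df)) {
    if (is.null(default_sigma))
      stop("missing required column(s): sigma_um ",
           "(supply default_sigma to use a global value)", call. = FALSE)
    message("sigma_um column absent; using global sigma = ", default_sigma,
            " um")
    df$sigma_um <- as.numeric(default_sigma)
  }
  if (nrow(df) == 0L) {
    warning("empty trajectory file: ", path, call. = FALSE)
    return(trajectory_set(list(), acquisition))
  }
  bad <- !is.finite(df$x_um) | !is.finite(df$y_um) | !is.finite(df$sigma_um) |
    !is.finite(df$frame)
  if (any(bad)) {
    warning(sum(bad), " row(s) with non-finite values rejected",
            call. = FALSE)
    df <- df[!bad, , drop = FALSE]
  }
  df <- df[order(df$traj_id, df$frame), , drop = FALSE]
  trajs <- list()
  dropped <- 0L
  for (id in unique(df$traj_id)) {
    b <- df[df$traj_id == id, , drop = FALSE]
    if (anyDuplicated(b$frame))
      stop("duplicate frame index within traj_id '", id, "'", call. = FALSE)
    pieces <- split_on_gaps(id, b$cell_id, as.integer(b$frame), b$x_um,
                            b$y_um, b$sigma_um)
    dropped <- dropped + (nrow(b) >= 2L && length(pieces) == 0L)
    trajs <- c(trajs, pieces)
  }
  if (nrow(df) > 0L && length(trajs) == 0L)
    warning("no trajectory with >= 2 localizations after validation",
            call. = FALSE)
  trajectory_set(trajs, acquisition)
}

#' Write a trajectory set to CSV
#'
#' Writes the package's fixed CSV dialect with deterministic row order
#' (by `traj_id`, then `frame`) and 9 significant digits, enough for a
#' lossless read/write round trip. Gap frames are not imputed: only observed
#' localizations are written.
#'
#' @param set A [trajectory_set()].
#' @param path Output file path.
#' @return Invisibly, the path written.
#' @export
write_trajectories <- function(set, path) {
  stopifnot(inherits(set, "trajectory_set"))
  df <- as.data.frame(set)
  df <- df[order(df$traj_id, df$frame), , drop = FALSE]
  out <- data.frame(traj_id = df$traj_id, cell_id = df$cell_id,
                    frame = df$frame,
                    x_um = sprintf("%.9g", df$x_um),
                    y_um = sprintf("%.9g", df$y_um),
                    sigma_um = sprintf("%.9g", df$sigma_um),
                    stringsAsFactors = FALSE)
  ok <- tryCatch({
    utils::write.table(out, path, sep = ",", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write ", path, ": ", conditionMessage(ok),
                        call. = FALSE)
  invisible(path)
}

#' Filter trajectories by minimum step count
#'
#' Retains trajectories with at least `min_steps` displacements. A
#' displacement spanning a single-frame gap counts as one step, so a
#' trajectory of m localizations has m - 1 steps regardless of gaps; the
#' default of 10 steps reproduces the usual short-track exclusion in
#' diffusion-HMM analyses.
#'
#' @param set A [trajectory_set()].
#' @param min_steps Minimum number of steps (default 10).
#' @return A filtered [trajectory_set()].
#' @export
filter_trajectories <- function(set, min_steps = 10L) {
  stopifnot(inherits(set, "trajectory_set"), min_steps >= 0)
  keep <- vapply(set$trajectories, function(t) n_steps(t) >= min_steps,
                 logical(1))
  trajectory_set(set$trajectories[keep], set$acquisition)
}
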