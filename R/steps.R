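#' Running steps from a behavior window length
#'
#' A running window of `W` samples converts to steps as
#' `R = round(W * K / L)`: the window is divided by the baseline step
#' length `L` (29 samples per normal walking step at 32 Hz) and scaled by
#' `K` (2.1, calibrated against manual counts), because a running sheep
#' takes more than one step per baseline period while peak counting misses
#' the extra ones. Rounding is half-away-from-zero by default
#' (`cfg$round_mode = "floor"` truncates instead).
#'
#' @param W window size(s) in samples, >= 0.
#' @param cfg a [threshold_config()] supplying `K` and `L`.
#' @return Integer step count(s); 0 when `W = 0`.
#' @examples
#' running_steps(29)   # 2.1 rounds to 2
#' running_steps(290)  # exactly 21
#' @export
running_steps <- function(W, cfg = threshold_config()) {
  if (any(W < 0)) stop("window size W must be >= 0")
  r <- W * cfg$K / cfg$L
  if (identical(cfg$round_mode, "floor")) floor(r) else round_half_away(r)
}

#' Aggregate extrema and behavior windows into a step report
#'
#' Implements the per-behavior accounting:
#' `total steps = peak count - running-window peak count + running steps -
#' leg-shaking steps`. The raw peak count includes the unreliable peaks
#' produced inside running windows (where steps are under-detected) and
#' leg-shake windows (which are not steps at all); both are subtracted, and
#' the window-length estimate [running_steps()] is added back for running.
#' Leg-shaking "steps" are the detected above-threshold peaks inside
#' leg-shake windows. Fast-walk windows keep their peaks as ordinary
#' walking steps.
#'
#' @param extrema an `extrema_set` from [detect_extrema()].
#' @param windows a data.frame of labeled behavior windows with columns
#'   `label` (`"running"`, `"leg_shake"` or `"fast_walk"`), `W`, and list
#'   column `peak_ids` (positions into the extrema set). Windows must be
#'   disjoint.
#' @param cfg a [threshold_config()].
#' @return An object of class `step_report`; see [count_steps()].
#' @export
aggregate_steps <- function(extrema, windows, cfg = threshold_config()) {
  stopifnot(inherits(extrema, "extrema_set"))
  np <- length(extrema$peak_indices)
  if (is.null(windows) || !nrow(windows)) {
    windows <- data.frame(label = character(0), W = integer(0))
    windows$peak_ids <- list()
  }
  all_ids <- unlist(windows$peak_ids)
  if (length(all_ids) && (any(all_ids < 1L) || any(all_ids > np))) {
    stop("window peak_ids inconsistent with the extrema set")
  }
  if (anyDuplicated(all_ids)) stop("behavior windows must be disjoint")

  step_peaks_in <- function(rows) {
    ids <- unlist(windows$peak_ids[rows])
    if (!length(ids)) 0L else sum(extrema$above_thr[ids])
  }
  run_rows <- which(windows$label == "running")
  shake_rows <- which(windows$label == "leg_shake")
  fast_rows <- which(windows$label == "fast_walk")

  total_peaks <- sum(extrema$above_thr)
  running_window_peaks <- step_peaks_in(run_rows)
  run_steps <- if (length(run_rows)) {
    sum(running_steps(windows$W[run_rows], cfg))
  } else 0
  leg_shake_peaks <- step_peaks_in(shake_rows)
  total <- total_peaks - running_window_peaks + run_steps - leg_shake_peaks
  walking <- total_peaks - running_window_peaks - leg_shake_peaks

  rep <- structure(list(
    total_peaks = total_peaks,
    running_windows = length(run_rows),
    running_window_peaks = running_window_peaks,
    running_steps = run_steps,
    leg_shake_windows = length(shake_rows),
    leg_shake_peaks = leg_shake_peaks,
    fast_walk_windows = length(fast_rows),
    fast_walk_peaks = step_peaks_in(fast_rows),
    walking_steps = walking,
    total_steps = total,
    windows = windows,
    config = cfg,
    schema_version = 1L
  ), class = "step_report")
  stopifnot(rep$total_steps ==
              rep$total_peaks - rep$running_window_peaks +
              rep$running_steps - rep$leg_shake_peaks)
  rep
}

#' @export
print.step_report <- function(x, ...) {
  cat("<step_report>\n")
  cat(sprintf("  total steps:        %d\n", as.integer(x$total_steps)))
  cat(sprintf("  walking peaks:      %d (of %d peaks above thr)\n",
              as.integer(x$walking_steps), as.integer(x$total_peaks)))
  cat(sprintf("  running:            %d window(s), %d peaks replaced by %d steps\n",
              x$running_windows, as.integer(x$running_window_peaks),
              as.integer(x$running_steps)))
  cat(sprintf("  leg shake:          %d window(s), %d peaks removed\n",
              x$leg_shake_windows, as.integer(x$leg_shake_peaks)))
  cat(sprintf("  fast walk:          %d window(s), peaks kept as steps\n",
              x$fast_walk_windows))
  invisible(x)
}

#' Full step-counting pipeline
#'
#' Runs the complete chain on a six-axis trace: combined acceleration,
#' zero-phase low-pass filtering, window peak/valley detection and pairing,
#' running-window detection, leg-shake candidate detection with
#' gyro-variance classification, and per-behavior aggregation. Traces with
#' recording gaps (timestamp jumps > 2/fs) are split and the segment
#' reports summed.
#'
#' @param series an [imu_series()].
#' @param cfg a [threshold_config()].
#' @return A `step_report`: per-behavior and total step counts, the labeled
#'   behavior windows (audit trail), and the configuration used.
#' @export
count_steps <- function(series, cfg = threshold_config()) {
  stopifnot(inherits(series, "imu_series"))
  segs <- split_on_gaps(series)
  reports <- lapply(segs, count_steps_segment, cfg = cfg)
  if (length(reports) == 1L) return(reports[[1L]])
  merge_step_reports(reports, cfg)
}

count_steps_segment <- function(series, cfg) {
  mag <- prepare_magnitude(series, cfg)
  ex <- detect_extrema(mag, cfg)
  run <- detect_running(ex, cfg, signal = mag)
  cand <- detect_leg_shake_candidates(ex, mag, cfg, running_windows = run)
  run_ok <- run[run$is_running, , drop = FALSE]

  labels <- character(0)
  if (nrow(cand)) {
    labels <- vapply(seq_len(nrow(cand)), function(i) {
      classify_candidate(cand[i, ], series$gyro_x, cfg)
    }, character(1))
  }
  windows <- rbind(
    if (nrow(run_ok)) data.frame(label = "running",
                                 start = run_ok$start, end = run_ok$end,
                                 W = run_ok$W, truncated = run_ok$truncated),
    if (nrow(cand)) data.frame(label = labels,
                               start = cand$start, end = cand$end,
                               W = cand$W, truncated = cand$truncated)
  )
  if (is.null(windows)) {
    windows <- data.frame(label = character(0), start = integer(0),
                          end = integer(0), W = integer(0),
                          truncated = logical(0))
    windows$peak_ids <- list()
  } else {
    windows$peak_ids <- c(if (nrow(run_ok)) run_ok$peak_ids,
                          if (nrow(cand)) cand$peak_ids)
  }
  aggregate_steps(ex, windows, cfg)
}

merge_step_reports <- function(reports, cfg) {
  sum_field <- function(f) sum(vapply(reports, function(r) as.numeric(r[[f]]), numeric(1)))
  windows <- do.call(rbind, lapply(seq_along(reports), function(i) {
    w <- reports[[i]]$windows
    if (nrow(w)) w$segment <- i
    w
  }))
  structure(list(
    total_peaks = sum_field("total_peaks"),
    running_windows = sum_field("running_windows"),
    running_window_peaks = sum_field("running_window_peaks"),
    running_steps = sum_field("running_steps"),
    leg_shake_windows = sum_field("leg_shake_windows"),
    leg_shake_peaks = sum_field("leg_shake_peaks"),
    fast_walk_windows = sum_field("fast_walk_windows"),
    fast_walk_peaks = sum_field("fast_walk_peaks"),
    walking_steps = sum_field("walking_steps"),
    total_steps = sum_field("total_steps"),
    windows = windows,
    config = cfg,
    schema_version = 1L
  ), class = "step_report")
}

#' Export a step report as JSON
#'
#' The JSON carries every threshold used (provenance block) and a
#' `schema_version` field.
#'
#' @param report a `step_report` from [count_steps()].
#' @param path output path; `NULL` returns the JSON string.
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "step_report"))
  obj <- unclass(report)
  obj$windows$peak_ids <- NULL
  obj$config <- unclass(obj$config)
  if (is.null(path)) {
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, dataframe = "rows"))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Sweep the running-step scale factor K
#'
#' For each candidate `K`, predicts running steps `round(W * K / L)` for
#' every window, takes the signed error against the true counts, and
#' summarises with [mse_rmse_mae()] (divisor n-1). The `K` minimising MSE
#' is the calibrated scale factor.
#'
#' @param true_steps true running step counts, one per window.
#' @param windows_W running window sizes in samples, same length.
#' @param K_grid candidate scale factors.
#' @param cfg a [threshold_config()] supplying `L` and the rounding mode.
#' @return A list with `table` (data.frame of K, MSE, RMSE, MAE), `errors`
#'   (list of signed error vectors per K), and `best_K` (argmin-MSE).
#' @export
sweep_K <- function(true_steps, windows_W, K_grid, cfg = threshold_config()) {
  if (!length(K_grid)) stop("empty K grid")
  if (length(true_steps) != length(windows_W)) {
    stop("true_steps and windows_W must have equal length")
  }
  errors <- lapply(K_grid, function(K) {
    cfgK <- cfg
    cfgK$K <- K
    running_steps(windows_W, cfgK) - true_steps
  })
  summ <- lapply(errors, mse_rmse_mae)
  tab <- data.frame(
    K = K_grid,
    MSE = vapply(summ, `[[`, numeric(1), "mse"),
    RMSE = vapply(summ, `[[`, numeric(1), "rmse"),
    MAE = vapply(summ, `[[`, numeric(1), "mae")
  )
  list(table = tab, errors = errors, best_K = K_grid[which.min(tab$MSE)])
}
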