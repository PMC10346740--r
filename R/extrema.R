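#' Window peak detection
#'
#' A sample is a peak when it is the top of a strict rise over its `n` left
#' neighbors and a strict fall over its `n` right neighbors, and exceeds the
#' amplitude threshold `thr`. The two-sided monotonicity requirement
#' suppresses pseudo-peaks (noise wiggles riding on a step pulse) that a
#' simple local-maximum test would keep. Indices are 1-based R indices;
#' samples within `n` of either boundary can never qualify because the
#' window requires `n` real neighbors on each side. All inequalities are
#' strict: plateaus produce no peak.
#'
#' @param signal a [magnitude_series()] or numeric vector.
#' @param n window half-width (default 4, the calibrated value for peaks).
#' @param thr amplitude threshold in m/s2; use `-Inf` to detect every
#'   structural peak regardless of height.
#' @return A list with `indices` (integer) and `values` (numeric).
#' @examples
#' x <- c(9, 9, 9, 10, 11, 12, 13, 14, 13, 12, 11, 10, 9, 9, 9)
#' detect_peaks(x, n = 4, thr = 12)  # one peak at index 8, value 14
#' @export
detect_peaks <- function(signal, n = 4, thr = 12) {
  x <- signal_values(signal)
  n <- as.integer(n)
  if (n < 1L) stop("window half-width n must be >= 1")
  len <- length(x)
  if (len <= 2L * n) {
    warning("signal shorter than 2n+1 samples; no peaks detectable")
    return(list(indices = integer(0), values = numeric(0)))
  }
  d <- diff(x)
  cpos <- c(0, cumsum(d > 0))
  cneg <- c(0, cumsum(d < 0))
  i <- (n + 1L):(len - n)
  # strict rise over d[i-n .. i-1], strict fall over d[i .. i+n-1]
  left_ok <- (cpos[i] - cpos[i - n]) == n
  right_ok <- (cneg[i + n] - cneg[i]) == n
  keep <- left_ok & right_ok & (x[i] > thr)
  list(indices = i[keep], values = x[i[keep]])
}

#' Window valley detection
#'
#' Mirror image of [detect_peaks()]: a strict fall over the `n` left
#' neighbors and a strict rise over the `n` right neighbors. No amplitude
#' threshold is applied — valleys are used for peak-valley difference rules,
#' not step counting. The calibrated half-width for valleys is `n = 2`
#' (valley troughs are narrower than peak crests in sheep gait).
#'
#' @inheritParams detect_peaks
#' @param n window half-width (default 2).
#' @return A list with `indices` and `values`.
#' @export
detect_valleys <- function(signal, n = 2) {
  x <- signal_values(signal)
  n <- as.integer(n)
  if (n < 1L) stop("window half-width n must be >= 1")
  len <- length(x)
  if (len <= 2L * n) {
    warning("signal shorter than 2n+1 samples; no valleys detectable")
    return(list(indices = integer(0), values = numeric(0)))
  }
  d <- diff(x)
  cpos <- c(0, cumsum(d > 0))
  cneg <- c(0, cumsum(d < 0))
  i <- (n + 1L):(len - n)
  left_ok <- (cneg[i] - cneg[i - n]) == n
  right_ok <- (cpos[i + n] - cpos[i]) == n
  keep <- left_ok & right_ok
  list(indices = i[keep], values = x[i[keep]])
}

signal_values <- function(signal) {
  if (inherits(signal, "magnitude_series")) signal$values
  else as.numeric(signal)
}

#' Pair each peak with its following valley
#'
#' Peak and valley data appear in pairs in gait waveforms; the difference
#' rules for running and leg-shake detection compare `peak[k]` with
#' `valley[k]`. Each peak is paired with the nearest detected valley that
#' follows it and precedes the next peak. When no detected valley lies in
#' that span, the minimum sample between the two peaks (or between the last
#' peak and the end of the signal) serves as the fallback valley.
#'
#' @param peaks,valleys results of [detect_peaks()] / [detect_valleys()].
#' @param signal the signal the extrema came from (for the fallback rule).
#' @return A list with `peak_indices`, `peak_values`, `valley_indices`,
#'   `valley_values`, all of equal length, ascending in peak index.
#' @export
pair_extrema <- function(peaks, valleys, signal) {
  x <- signal_values(signal)
  np <- length(peaks$indices)
  v_idx <- integer(np)
  v_val <- numeric(np)
  bounds <- c(peaks$indices, length(x) + 1L)
  for (k in seq_len(np)) {
    lo <- bounds[k]
    hi <- bounds[k + 1L]
    cand <- valleys$indices[valleys$indices > lo & valleys$indices < hi]
    if (length(cand)) {
      v_idx[k] <- cand[1L]
      v_val[k] <- x[cand[1L]]
    } else {
      span <- if (hi - lo > 1L) (lo + 1L):(hi - 1L) else lo
      v_idx[k] <- span[which.min(x[span])]
      v_val[k] <- x[v_idx[k]]
    }
  }
  list(peak_indices = peaks$indices, peak_values = peaks$values,
       valley_indices = v_idx, valley_values = v_val)
}

#' Detect and pair all extrema of a filtered magnitude signal
#'
#' Runs [detect_peaks()] (without an amplitude threshold — behavior windows
#' need the low peaks that close them), [detect_valleys()], and
#' [pair_extrema()], and records which peaks clear the walking-step
#' threshold `cfg$thr`.
#'
#' @param signal a filtered [magnitude_series()].
#' @param cfg a [threshold_config()].
#' @return An object of class `extrema_set`: paired peak/valley indices and
#'   values, the detection parameters, and `above_thr`, a logical marking
#'   peaks that count as walking steps.
#' @export
detect_extrema <- function(signal, cfg = threshold_config()) {
  peaks <- detect_peaks(signal, n = cfg$n_peak, thr = -Inf)
  valleys <- detect_valleys(signal, n = cfg$n_valley)
  paired <- pair_extrema(peaks, valleys, signal)
  structure(
    c(paired,
      list(above_thr = paired$peak_values > cfg$thr,
           n_peak = cfg$n_peak, n_valley = cfg$n_valley, thr = cfg$thr)),
    class = "extrema_set"
  )
}

#' @export
print.extrema_set <- function(x, ...) {
  cat(sprintf("<extrema_set> %d peaks (%d above thr=%g), n=%d/%d\n",
              length(x$peak_indices), sum(x$above_thr), x$thr,
              x$n_peak, x$n_valley))
  invisible(x)
}

#' Export an extrema set as JSON
#'
#' @param extrema an `extrema_set` from [detect_extrema()].
#' @param path output path; `NULL` returns the JSON string.
#' @export
extrema_to_json <- function(extrema, path = NULL) {
  stopifnot(inherits(extrema, "extrema_set"))
  obj <- unclass(extrema)
  if (is.null(path)) {
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
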