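#' Threshold configuration for detection and step counting
#'
#' Bundles every tunable constant of the pipeline so that no threshold is
#' hard-coded at a call site. Defaults are the values calibrated on leg-worn
#' 32 Hz recordings of grazing sheep:
#'
#' * `thr` (12 m/s2): minimum combined-acceleration peak height for a peak to
#'   count as a walking step.
#' * `thr1` (30), `thr2` (20), `thr3` (12): open / close thresholds of the
#'   running behavior window — a window opens at a peak above `thr1` and
#'   closes when the signal drops back towards strolling or standing levels.
#' * `thr4` (20): minimum paired-valley height inside a running window
#'   (the peak-valley difference rule `acc_p - acc_v < acc_p - thr4`
#'   reduces algebraically to `acc_v > thr4`).
#' * `thr5` (12), `thr7` (12): leg-shake window opening threshold and
#'   paired-valley floor (same structure as the running rule, gentler motion).
#' * `thr8` (39): regional peak restriction — every peak inside a leg-shake
#'   candidate must stay below this, separating leg shaking from running.
#' * `var_cut` (10): x-axis gyroscope variance above which a candidate window
#'   is leg shaking rather than brisk walking.
#' * `n_peak` (4), `n_valley` (2): half-widths of the two-sided monotonicity
#'   window for peak and valley detection.
#' * `K` (2.1): scale factor converting running-window length to steps.
#' * `L` (29): average samples per normal walking step at 32 Hz.
#' * `fs` (32 Hz): sampling frequency.
#' * `cutoff_hz` (5), `filter_order` (2): low-pass filter parameters.
#'
#' Behavioral switches: `pair_rule` ("all" requires every interior
#' peak-valley pair to satisfy the difference rule, "any" at least one);
#' `close_on` ("sample", the default, closes behavior windows at the first
#' filtered sample below `thr3` or the first low peak, whichever comes
#' first; "peak" closes only at a low peak); `var_type`
#' ("population" or "sample") selects the variance
#' convention for the gyro cut; `round_mode` ("half_away" or "floor") selects
#' how fractional running steps are rounded.
#'
#' @param ... named overrides of any field listed above.
#' @return An object of class `threshold_config` (a named list).
#' @examples
#' cfg <- threshold_config()
#' cfg$thr1
#' threshold_config(K = 2.0, var_cut = 8)$K
#' @export
threshold_config <- function(...) {
  cfg <- list(
    thr = 12, thr1 = 30, thr2 = 20, thr3 = 12, thr4 = 20,
    thr5 = 12, thr7 = 12, thr8 = 39,
    var_cut = 10, n_peak = 4L, n_valley = 2L,
    K = 2.1, L = 29, fs = 32,
    cutoff_hz = 5, filter_order = 2L,
    pair_rule = "all", close_on = "sample",
    var_type = "population", round_mode = "half_away"
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown threshold_config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  class(cfg) <- "threshold_config"
  validate_threshold_config(cfg)
  cfg
}

validate_threshold_config <- function(cfg) {
  num <- c("thr", "thr1", "thr2", "thr3", "thr4", "thr5", "thr7", "thr8",
           "var_cut", "n_peak", "n_valley", "K", "L", "fs",
           "cutoff_hz", "filter_order")
  for (f in num) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("threshold_config field '", f, "' must be a single positive number")
    }
  }
  if (!(cfg$thr1 > cfg$thr2 && cfg$thr2 > cfg$thr3)) {
    stop("threshold_config requires thr1 > thr2 > thr3")
  }
  if (cfg$cutoff_hz >= cfg$fs / 2) {
    stop("cutoff_hz must be below the Nyquist frequency fs/2")
  }
  match.arg(cfg$pair_rule, c("all", "any"))
  match.arg(cfg$close_on, c("peak", "sample"))
  match.arg(cfg$var_type, c("population", "sample"))
  match.arg(cfg$round_mode, c("half_away", "floor"))
  invisible(cfg)
}

#' @export
print.threshold_config <- function(x, ...) {
  cat("<threshold_config>\n")
  cat(sprintf("  step threshold thr=%g m/s2; peak/valley window n=%d/%d\n",
              x$thr, x$n_peak, x$n_valley))
  cat(sprintf("  running: thr1=%g thr2=%g thr3=%g thr4=%g; K=%g L=%g\n",
              x$thr1, x$thr2, x$thr3, x$thr4, x$K, x$L))
  cat(sprintf("  leg shake: thr5=%g thr7=%g thr8=%g; gyro var cut=%g (%s)\n",
              x$thr5, x$thr7, x$thr8, x$var_cut, x$var_type))
  cat(sprintf("  fs=%g Hz; low-pass %g Hz order %d\n",
              x$fs, x$cutoff_hz, x$filter_order))
  invisible(x)
}

#' Read or write a threshold configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_config()` returns a [threshold_config()]; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(threshold_config, vals)
}

#' @rdname read_config
#' @param cfg a [threshold_config()].
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "threshold_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
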