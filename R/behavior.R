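#' Detect running behavior windows
#'
#' Running shows as sustained high peaks with elevated valleys: at 32 Hz a
#' running sheep takes several steps per second, the waveform never falls
#' back to baseline, and plain peak counting misses steps. A window opens at
#' the first peak above `thr1` (30 m/s2) and closes at the first subsequent
#' peak below `thr2` (20) — the sheep has dropped back to strolling or
#' standing. The window is labeled running when the peak-valley difference
#' rule holds for the pairs between its interior peaks:
#' `acc_p - acc_v < acc_p - thr4`, i.e. every interior valley stays above
#' `thr4` (20). The drop to the closing peak itself is the termination of
#' the behavior and is not part of the pair check.
#'
#' By default (`cfg$close_on = "sample"`) the window also closes at the
#' first filtered sample below `thr3`, whichever comes first — the signal
#' dropping to baseline ends the behavior even before a low peak forms.
#' `cfg$close_on = "peak"` closes only on low peaks. With
#' `cfg$pair_rule = "any"` a single qualifying pair suffices for the
#' running label.
#'
#' @param extrema an `extrema_set` from [detect_extrema()].
#' @param cfg a [threshold_config()].
#' @param signal the filtered [magnitude_series()]; required for
#'   `close_on = "sample"` and to close a still-open window at the end of
#'   the series (truncation).
#' @return A data.frame of detected high-amplitude windows with columns
#'   `start`, `end` (sample indices, half-open `[start, end)`), `W` (window
#'   size `end - start` in samples), `is_running` (did the pair rule hold),
#'   `truncated`, and a list column `peak_ids` of positions (into the
#'   extrema set) of the peaks inside the window.
#' @export
detect_running <- function(extrema, cfg = threshold_config(), signal = NULL) {
  scan_behavior_windows(
    extrema, signal,
    open_thr = cfg$thr1, close_thr = cfg$thr2,
    sample_thr = cfg$thr3, close_on = cfg$close_on,
    valley_floor = cfg$thr4, peak_ceiling = Inf,
    min_interior = 1L, pair_rule = cfg$pair_rule,
    label_col = "is_running"
  )
}

#' Detect leg-shake candidate windows
#'
#' Leg shaking (scratching while standing or lying) produces step-like peaks
#' of moderate height with a small peak-valley difference: the waveform
#' falls back only briefly before being pulled up again. A candidate window
#' opens at a peak above `thr5` (12 m/s2) and closes at the first peak below
#' `thr3` (12). It is a candidate when it holds at least two interior peaks,
#' every interior peak stays below the regional peak restriction `thr8`
#' (39 — anything higher is running territory), and the interior pair rule
#' `acc_v > thr7` (12) holds. Candidates overlapping a detected running
#' window are discarded. The at-least-two-peaks requirement exists because
#' the pair rule quantifies over adjacent peak-valley pairs: an isolated
#' walking step (one peak, then baseline) has no such pair and is not an
#' oscillatory behavior.
#'
#' Whether a candidate is leg shaking or merely brisk walking is decided
#' afterwards by [classify_candidate()] on the gyroscope.
#'
#' @inheritParams detect_running
#' @param signal the filtered [magnitude_series()].
#' @param running_windows optional result of [detect_running()]; candidates
#'   overlapping a row with `is_running = TRUE` are dropped.
#' @return A data.frame in the format of [detect_running()] with an
#'   `is_candidate` column instead of `is_running`.
#' @export
detect_leg_shake_candidates <- function(extrema, signal,
                                        cfg = threshold_config(),
                                        running_windows = NULL) {
  w <- scan_behavior_windows(
    extrema, signal,
    open_thr = cfg$thr5, close_thr = cfg$thr3,
    sample_thr = cfg$thr3, close_on = cfg$close_on,
    valley_floor = cfg$thr7, peak_ceiling = cfg$thr8,
    min_interior = 2L, pair_rule = cfg$pair_rule,
    label_col = "is_candidate"
  )
  if (!is.null(running_windows) && nrow(running_windows) && nrow(w)) {
    run <- running_windows[running_windows$is_running, , drop = FALSE]
    if (nrow(run)) {
      overlaps <- vapply(seq_len(nrow(w)), function(i) {
        any(w$start[i] < run$end & run$start < w$end[i])
      }, logical(1))
      w <- w[!overlaps, , drop = FALSE]
    }
  }
  w[w$is_candidate, , drop = FALSE]
}

# Shared scanner for threshold-delimited behavior windows on the peak stream.
# Opens at a peak above open_thr, closes at the first peak below close_thr
# (or, with close_on = "sample", at the first raw sample below sample_thr if
# that comes earlier). The label condition checks interior peaks against
# peak_ceiling and the valleys between consecutive interior peaks against
# valley_floor.
scan_behavior_windows <- function(extrema, signal, open_thr, close_thr,
                                  sample_thr, close_on, valley_floor,
                                  peak_ceiling, min_interior, pair_rule,
                                  label_col) {
  pv <- extrema$peak_values
  pidx <- extrema$peak_indices
  vv <- extrema$valley_values
  np <- length(pv)
  x <- if (!is.null(signal)) signal_values(signal) else NULL

  rows <- list()
  i <- 1L
  while (i <= np) {
    if (!(pv[i] > open_thr)) {
      i <- i + 1L
      next
    }
    close <- NA_integer_
    j <- i + 1L
    while (j <= np) {
      # disjunction as in the reference pseudo-code (close_thr dominates)
      if (pv[j] < close_thr || pv[j] < sample_thr) {
        close <- j
        break
      }
      j <- j + 1L
    }
    truncated <- is.na(close)
    end_idx <- if (truncated) {
      if (!is.null(x)) length(x) + 1L else pidx[np] + 1L
    } else {
      pidx[close]
    }
    if (identical(close_on, "sample") && !is.null(x)) {
      after <- (pidx[i] + 1L):length(x)
      low <- after[x[after] < sample_thr]
      if (length(low) && low[1L] < end_idx) {
        end_idx <- low[1L]
        truncated <- FALSE
        close <- NA_integer_
      }
    }
    interior <- which(pidx >= pidx[i] & pidx < end_idx)
    last_int <- interior[length(interior)]
    # valleys between consecutive interior peaks
    pair_ids <- if (length(interior) >= 2L) interior[-length(interior)] else integer(0)
    pair_ok <- vv[pair_ids] > valley_floor
    label <- length(interior) >= min_interior &&
      all(pv[interior] < peak_ceiling) &&
      (if (identical(pair_rule, "any")) {
        length(pair_ok) > 0L && any(pair_ok)
      } else {
        all(pair_ok)  # vacuously TRUE with no pairs
      })
    rows[[length(rows) + 1L]] <- list(
      start = pidx[i], end = end_idx, W = end_idx - pidx[i],
      label = label, truncated = truncated, peak_ids = interior
    )
    i <- if (truncated) np + 1L else max(i + 1L, if (is.na(close)) last_int + 1L else close)
  }

  out <- data.frame(
    start = vapply(rows, `[[`, integer(1), "start"),
    end = vapply(rows, `[[`, integer(1), "end"),
    W = vapply(rows, `[[`, integer(1), "W"),
    label = vapply(rows, `[[`, logical(1), "label"),
    truncated = vapply(rows, `[[`, logical(1), "truncated")
  )
  names(out)[names(out) == "label"] <- label_col
  out$peak_ids <- lapply(rows, `[[`, "peak_ids")
  out
}

#' Classify a candidate window as leg shaking or fast walking
#'
#' Fast (brisk) walking mimics the acceleration profile of leg shaking but
#' the leg does not oscillate about the joint, so the x-axis angular
#' velocity stays quiet. The variance of gyro-x over the window separates
#' the two: variance strictly above `cfg$var_cut` (10) means leg shaking,
#' otherwise fast walking. Variance is population variance (divisor N) by
#' default; set `cfg$var_type = "sample"` for the n-1 convention.
#'
#' @param window one row of the data.frame from
#'   [detect_leg_shake_candidates()] (or any list with `start` and `end`).
#' @param gyro_x numeric vector, the x-axis angular velocity channel.
#' @param cfg a [threshold_config()].
#' @return `"leg_shake"` or `"fast_walk"`.
#' @export
classify_candidate <- function(window, gyro_x, cfg = threshold_config()) {
  s <- window$start[1L]
  e <- window$end[1L]
  if (s < 1L || e - 1L > length(gyro_x)) stop("window indices outside gyro_x")
  seg <- gyro_x[s:(e - 1L)]
  if (length(seg) < 2L) {
    warning("window shorter than 2 samples; variance undefined, labeling fast_walk")
    return("fast_walk")
  }
  v <- if (identical(cfg$var_type, "sample")) {
    stats::var(seg)
  } else {
    mean((seg - mean(seg))^2)
  }
  if (v > cfg$var_cut) "leg_shake" else "fast_walk"
}

#' Moment features of a gyroscope window
#'
#' Mean, variance, standard deviation, kurtosis and skewness of an angular
#' velocity window — the feature set whose cluster structure motivated the
#' variance cut used by [classify_candidate()]. Skewness and kurtosis are
#' standardized central moments, with kurtosis reported as excess kurtosis
#' (a normal distribution scores 0). A constant window has zero variance;
#' its skewness and kurtosis are defined as 0 with a warning.
#'
#' @param x numeric vector of length >= 2.
#' @param var_type `"population"` (divisor N, default) or `"sample"` (N-1).
#' @return A named list of class `feature_vector`:
#'   `mean`, `var`, `std`, `kurt`, `skew`.
#' @examples
#' extract_features(c(0, 2))  # mean 1, population var 1
#' @export
extract_features <- function(x, var_type = c("population", "sample")) {
  var_type <- match.arg(var_type)
  x <- as.numeric(x)
  if (length(x) < 2L) stop("feature window must have at least 2 samples")
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  v <- if (var_type == "sample") m2 * n / (n - 1) else m2
  if (m2 == 0) {
    warning("constant window: skewness and kurtosis defined as 0")
    skew <- 0
    kurt <- 0
  } else {
    skew <- m3 / m2^1.5
    kurt <- m4 / m2^2 - 3
  }
  structure(list(mean = mu, var = v, std = sqrt(v), kurt = kurt, skew = skew),
            class = "feature_vector")
}

#' K-means clustering of behavior feature vectors
#'
#' Exploratory clustering of window features (e.g. into standing leg shake,
#' lying leg shake, and brisk walking). This analysis motivates the variance
#' cut used at runtime; it is not part of the step-counting pipeline itself.
#' Lloyd's algorithm with 10 random restarts; deterministic given `seed`.
#'
#' @param features a matrix/data.frame of feature rows, or a list of
#'   `feature_vector` objects from [extract_features()].
#' @param k number of clusters (default 3).
#' @param seed integer RNG seed.
#' @return A list with `cluster` (integer assignments) and `centers`
#'   (k x n_features matrix).
#' @export
cluster_behaviors <- function(features, k = 3, seed = 1) {
  if (is.list(features) && !is.data.frame(features) &&
      all(vapply(features, inherits, logical(1), "feature_vector"))) {
    features <- do.call(rbind, lapply(features, function(f) unlist(unclass(f))))
  }
  mat <- as.matrix(as.data.frame(features))
  if (nrow(mat) < k) stop("need at least k = ", k, " feature rows")
  ux <- unique(mat)
  if (nrow(ux) < k) {
    warning("fewer distinct points than clusters; centroids are duplicated")
    centers <- ux[rep(seq_len(nrow(ux)), length.out = k), , drop = FALSE]
    d <- vapply(seq_len(nrow(ux)), function(j) {
      rowSums((mat - matrix(ux[j, ], nrow(mat), ncol(mat), byrow = TRUE))^2)
    }, numeric(nrow(mat)))
    return(list(cluster = max.col(-as.matrix(d)), centers = centers))
  }
  set.seed(seed)
  km <- stats::kmeans(mat, centers = k, nstart = 10, iter.max = 100,
                      algorithm = "Lloyd")
  list(cluster = km$cluster, centers = km$centers)
}

#' Accuracy, precision and recall of a binary behavior classifier
#'
#' Standard confusion-matrix metrics:
#' accuracy = (TP+TN)/(TP+FP+FN+TN), precision = TP/(TP+FP),
#' recall = TP/(TP+FN). A metric with a zero denominator is returned as
#' `NaN` (flagged undefined) rather than an arbitrary value.
#'
#' @param predicted,actual vectors of equal length with two label values.
#' @param positive the label treated as positive; defaults to
#'   `"leg_shake"` when present, else the first unique value of `actual`.
#' @return A list: `accuracy`, `precision`, `recall`, and the counts
#'   `TP`, `FP`, `FN`, `TN`.
#' @export
classification_metrics <- function(predicted, actual, positive = NULL) {
  if (length(predicted) != length(actual)) {
    stop("predicted and actual must have equal length")
  }
  if (is.null(positive)) {
    positive <- if ("leg_shake" %in% actual) "leg_shake" else unique(actual)[1L]
  }
  p <- predicted == positive
  a <- actual == positive
  TP <- sum(p & a)
  FP <- sum(p & !a)
  FN <- sum(!p & a)
  TN <- sum(!p & !a)
  safe_div <- function(num, den) if (den == 0) NaN else num / den
  list(accuracy = safe_div(TP + TN, TP + FP + FN + TN),
       precision = safe_div(TP, TP + FP),
       recall = safe_div(TP, TP + FN),
       TP = TP, FP = FP, FN = FN, TN = TN)
}
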