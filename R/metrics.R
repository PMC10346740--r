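#' Rounding helpers
#'
#' `round_half_away()` rounds to the nearest integer with halves away from
#' zero (2.5 -> 3, -2.5 -> -3), the convention used when converting
#' fractional running steps to a count. `round_half_up()` rounds to `digits`
#' decimals with halves up in magnitude, the convention of the field-trial
#' tables (base R `round()` rounds halves to even, which does not reproduce
#' them).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5 + 1e-9)
}

#' @rdname round_half_away
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Relative step-count error in percent
#'
#' `|predicted - true| / true * 100` — the per-trial accuracy measure used
#' to validate step counts against manual video counts. The absolute value
#' makes over- and under-counting comparable.
#'
#' @param true true count(s), positive.
#' @param pred predicted count(s).
#' @return Percent error(s); `NaN` (flagged undefined) where `true <= 0`.
#' @examples
#' relative_error(147, 155)  # 5.44...
#' @export
relative_error <- function(true, pred) {
  out <- ifelse(true > 0, abs(pred - true) / true * 100, NaN)
  if (anyNA(out) || any(is.nan(out))) {
    if (any(true <= 0)) warning("relative error undefined where true <= 0")
  }
  out
}

#' Error table comparing predicted step counts against truth
#'
#' Builds the per-trial relative errors for one or more prediction columns
#' and their mean. Per-trial errors are rounded to `round_digits` decimals
#' (half-up) before averaging — the reporting convention of the field
#' tables, where printed means are averages of the printed 2 d.p. rows. Set
#' `round_digits = NULL` to average at full precision.
#'
#' @param true numeric vector of true counts.
#' @param ... one or more numeric vectors (or a single matrix/data.frame)
#'   of predicted counts, same length as `true`.
#' @param round_digits decimals for per-trial errors (default 2).
#' @return An object of class `error_table`: a list with `true`, `predicted`
#'   (matrix), `relative_errors` (matrix, percent), and `summary` (named
#'   vector of mean relative errors, one per prediction column).
#' @export
error_table <- function(true, ..., round_digits = 2) {
  preds <- list(...)
  if (length(preds) == 1L && (is.matrix(preds[[1L]]) || is.data.frame(preds[[1L]]))) {
    preds <- as.list(as.data.frame(preds[[1L]]))
  }
  if (!length(preds)) stop("at least one prediction column is required")
  if (!length(true)) stop("empty error table")
  pm <- do.call(cbind, lapply(preds, as.numeric))
  if (nrow(pm) != length(true)) stop("prediction length mismatch")
  if (is.null(colnames(pm)) || any(!nzchar(colnames(pm)))) {
    colnames(pm) <- paste0("pred", seq_len(ncol(pm)))
  }
  re <- apply(pm, 2, function(p) relative_error(true, p))
  re <- matrix(re, nrow = length(true), dimnames = dimnames(pm))
  if (!is.null(round_digits)) re <- round_half_up(re, round_digits)
  structure(list(true = as.numeric(true), predicted = pm,
                 relative_errors = re,
                 summary = colMeans(re)),
            class = "error_table")
}

#' @export
print.error_table <- function(x, ...) {
  cat(sprintf("<error_table> %d trials, %d prediction column(s)\n",
              length(x$true), ncol(x$predicted)))
  df <- data.frame(true = x$true, x$predicted, check.names = FALSE)
  for (cn in colnames(x$relative_errors)) {
    df[[paste0("RE_", cn, " (%)")]] <- x$relative_errors[, cn]
  }
  print(df, row.names = FALSE)
  cat("mean relative error (%):",
      paste(sprintf("%s=%.3f", names(x$summary), x$summary), collapse = "  "),
      "\n")
  invisible(x)
}

#' Mean relative error
#'
#' Unweighted arithmetic mean of per-trial relative errors, in percent.
#'
#' @param x an [error_table()] (returns its per-column means) or a numeric
#'   vector of relative errors.
#' @return Named numeric vector (one mean per prediction column) or a
#'   single number.
#' @export
mean_relative_error <- function(x) {
  if (inherits(x, "error_table")) return(x$summary)
  x <- as.numeric(x)
  if (!length(x)) stop("empty error vector")
  mean(x)
}

#' MSE, RMSE and MAE of signed step errors
#'
#' Summaries of the signed prediction errors from the running-step scale
#' factor sweep. The divisor is `n - 1` by default: that is the convention
#' the field-trial summary table was computed with (its MAE of 1.14 over 8
#' errors summing to 8 in absolute value equals 8/7), and it is kept for
#' fidelity. `divisor = "n"` gives the textbook convention.
#'
#' @param errors numeric vector of signed errors, length >= 2.
#' @param divisor `"n_minus_1"` (default) or `"n"`.
#' @return A list with `mse`, `rmse`, `mae`.
#' @examples
#' mse_rmse_mae(c(2, -1, 0, 1, 1, 1, 2, 0))  # mse 1.714..., rmse 1.309..., mae 1.142...
#' @export
mse_rmse_mae <- function(errors, divisor = c("n_minus_1", "n")) {
  divisor <- match.arg(divisor)
  e <- as.numeric(errors)
  if (length(e) < 2L) stop("need at least 2 errors")
  d <- if (divisor == "n_minus_1") length(e) - 1L else length(e)
  mse <- sum(e^2) / d
  list(mse = mse, rmse = sqrt(mse), mae = sum(abs(e)) / d)
}

#' Leg-shake detection error rate
#'
#' SER = detection errors / detections: the fraction of windows flagged as
#' leg shaking that were misdetections.
#'
#' @param errors number of erroneous detections.
#' @param detections total number of detections, > 0.
#' @return The rate in `[0, 1]`; `NaN` (flagged undefined) when
#'   `detections == 0`.
#' @examples
#' detection_error_rate(2, 25)  # 0.08
#' @export
detection_error_rate <- function(errors, detections) {
  if (any(errors > detections)) stop("errors cannot exceed detections")
  if (any(errors < 0) || any(detections < 0)) stop("counts must be non-negative")
  ifelse(detections > 0, errors / detections, NaN)
}
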