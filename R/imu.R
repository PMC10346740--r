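#' Construct a six-axis IMU time series
#'
#' Container for a uniformly sampled six-axis inertial trace: tri-axis
#' acceleration in m/s2 and tri-axis angular velocity in the device's units
#' (rad/s for the reference hardware). Timestamps, when supplied, are seconds
#' and must be strictly increasing; the series is nevertheless treated as
#' uniformly sampled at `fs`.
#'
#' @param acc_x,acc_y,acc_z numeric vectors, acceleration per axis (m/s2).
#' @param gyro_x,gyro_y,gyro_z numeric vectors, angular velocity per axis.
#'   Default zero.
#' @param timestamps optional numeric vector of seconds, strictly increasing.
#' @param fs sampling frequency in Hz (default 32).
#' @return An object of class `imu_series`.
#' @examples
#' imu_series(acc_x = c(3, 0), acc_y = c(4, 0), acc_z = c(0, 9.8))
#' @export
imu_series <- function(acc_x, acc_y, acc_z,
                       gyro_x = numeric(length(acc_x)),
                       gyro_y = numeric(length(acc_x)),
                       gyro_z = numeric(length(acc_x)),
                       timestamps = NULL, fs = 32) {
  n <- length(acc_x)
  if (n < 1L) stop("imu_series requires at least one sample")
  lens <- lengths(list(acc_x, acc_y, acc_z, gyro_x, gyro_y, gyro_z))
  if (any(lens != n)) stop("all six channels must have equal length")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be > 0")
  if (!is.null(timestamps)) {
    if (length(timestamps) != n) stop("timestamps length mismatch")
    if (n > 1L && any(diff(timestamps) <= 0)) {
      stop("timestamps must be strictly increasing")
    }
  }
  structure(
    list(acc_x = as.numeric(acc_x), acc_y = as.numeric(acc_y),
         acc_z = as.numeric(acc_z),
         gyro_x = as.numeric(gyro_x), gyro_y = as.numeric(gyro_y),
         gyro_z = as.numeric(gyro_z),
         timestamps = timestamps, fs = fs),
    class = "imu_series"
  )
}

#' @export
length.imu_series <- function(x) length(x$acc_x)

#' @export
print.imu_series <- function(x, ...) {
  cat(sprintf("<imu_series> %d samples @ %g Hz (%.2f s)%s\n",
              length(x), x$fs, length(x) / x$fs,
              if (is.null(x$timestamps)) ", no timestamps" else ""))
  invisible(x)
}

#' Read a six-axis IMU trace from CSV
#'
#' Expects a header row with a time column plus the six channels. The time
#' column may be raw float seconds or a "yyyy/m/d h:m:s.ms" datetime string,
#' which is converted to seconds since the first sample.
#'
#' @param path CSV file path.
#' @param columns named character vector mapping the canonical names
#'   `time, acc_x, acc_y, acc_z, gyro_x, gyro_y, gyro_z` to the file's column
#'   names. Defaults to the canonical names themselves.
#' @param fs sampling frequency in Hz.
#' @param sep field delimiter.
#' @return An [imu_series()].
#' @export
read_imu_csv <- function(path, columns = NULL, fs = 32, sep = ",") {
  canon <- c("time", "acc_x", "acc_y", "acc_z", "gyro_x", "gyro_y", "gyro_z")
  map <- stats::setNames(canon, canon)
  if (!is.null(columns)) map[names(columns)] <- columns
  df <- utils::read.csv(path, sep = sep, check.names = FALSE,
                        stringsAsFactors = FALSE)
  need <- map[setdiff(canon, "time")]
  missing_cols <- setdiff(unname(need), names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0L) stop("empty IMU file: ", path)
  ts <- NULL
  if (map[["time"]] %in% names(df)) {
    raw <- df[[map[["time"]]]]
    ts <- if (is.numeric(raw)) as.numeric(raw) else parse_clock_time(raw)
  }
  imu_series(
    acc_x = df[[map[["acc_x"]]]], acc_y = df[[map[["acc_y"]]]],
    acc_z = df[[map[["acc_z"]]]],
    gyro_x = df[[map[["gyro_x"]]]], gyro_y = df[[map[["gyro_y"]]]],
    gyro_z = df[[map[["gyro_z"]]]],
    timestamps = ts, fs = fs
  )
}

# "yyyy/m/d h:m:s.ms" -> seconds since the first sample
parse_clock_time <- function(x) {
  t <- as.POSIXct(strptime(x, format = "%Y/%m/%d %H:%M:%OS", tz = "UTC"))
  if (anyNA(t)) stop("unparseable time values (expected yyyy/m/d h:m:s.ms)")
  as.numeric(t) - as.numeric(t[1])
}

#' Write an IMU trace to CSV
#'
#' Inverse of [read_imu_csv()]; the time column is written as float seconds.
#'
#' @param series an [imu_series()].
#' @param path output file path.
#' @param digits significant digits for the numeric columns.
#' @return `path`, invisibly.
#' @export
write_imu_csv <- function(series, path, digits = 7) {
  stopifnot(inherits(series, "imu_series"))
  n <- length(series)
  ts <- series$timestamps %||% (seq_len(n) - 1) / series$fs
  df <- data.frame(
    time = formatC(ts, digits = digits, format = "g"),
    acc_x = formatC(series$acc_x, digits = digits, format = "g"),
    acc_y = formatC(series$acc_y, digits = digits, format = "g"),
    acc_z = formatC(series$acc_z, digits = digits, format = "g"),
    gyro_x = formatC(series$gyro_x, digits = digits, format = "g"),
    gyro_y = formatC(series$gyro_y, digits = digits, format = "g"),
    gyro_z = formatC(series$gyro_z, digits = digits, format = "g")
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Split an IMU trace at recording gaps
#'
#' The pipeline assumes uniform sampling at `fs`. A timestamp gap longer than
#' `2/fs` indicates dropped samples; such traces are split into contiguous
#' segments that are processed independently (a warning reports the split).
#'
#' @param series an [imu_series()].
#' @return A list of `imu_series` segments (length 1 when no gaps).
#' @export
split_on_gaps <- function(series) {
  stopifnot(inherits(series, "imu_series"))
  ts <- series$timestamps
  if (is.null(ts) || length(ts) < 2L) return(list(series))
  gap_after <- which(diff(ts) > 2 / series$fs)
  if (!length(gap_after)) return(list(series))
  warning(sprintf("%d recording gap(s) > %g s found; splitting into %d segments",
                  length(gap_after), 2 / series$fs, length(gap_after) + 1L))
  bounds <- c(0L, gap_after, length(series))
  lapply(seq_len(length(bounds) - 1L), function(i) {
    idx <- (bounds[i] + 1L):bounds[i + 1L]
    imu_series(series$acc_x[idx], series$acc_y[idx], series$acc_z[idx],
               series$gyro_x[idx], series$gyro_y[idx], series$gyro_z[idx],
               timestamps = ts[idx], fs = series$fs)
  })
}
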