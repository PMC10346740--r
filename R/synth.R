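#' Specify one synthetic behavior segment
#'
#' A segment of a synthetic six-axis trace. Defaults encode the waveform
#' regimes the detection thresholds were calibrated for, at 32 Hz:
#'
#' * `walk`: one raised-cosine pulse per 29 samples (the baseline step
#'   length), pulse peaks 14-18 m/s2 on a 9.8 gravity baseline.
#' * `run`: continuous oscillation at 2.1 steps per 29 samples, peaks
#'   31-36, valleys 21-25 (opens the running window and passes its
#'   peak-valley rule).
#' * `leg_shake`: fast oscillation (one cycle per 10 samples), peaks 16-20,
#'   valleys 13-15.5 (small peak-valley gap, elevated valleys), x-gyro
#'   noise sd `sqrt(30)` so the window variance sits near 30, above the cut.
#' * `fast_walk`: acceleration profile of a leg-shake candidate but x-gyro
#'   noise sd `sqrt(2)` (window variance near 2, below the cut).
#' * `stationary`: gravity plus noise.
#'
#' Amplitudes are validated against the thresholds that define each
#' behavior: a `run` segment whose peaks cannot exceed 30 m/s2, for
#' instance, is rejected at construction.
#'
#' @param behavior one of `"stationary"`, `"walk"`, `"fast_walk"`, `"run"`,
#'   `"leg_shake"`.
#' @param duration segment length in seconds.
#' @param peak_amp length-2 range (m/s2) the per-cycle peak amplitudes are
#'   drawn from; `NULL` for the behavior default.
#' @param valley_amp length-2 range for per-cycle valley levels (oscillatory
#'   behaviors).
#' @param gyro_x_sd standard deviation of the x-gyro channel.
#' @param noise_sd per-axis Gaussian noise sd (m/s2), default 0.2.
#' @param shape pulse shape: `"raised_cosine"` (default), `"triangle"`, or
#'   `"gauss"`.
#' @return An object of class `segment_spec`.
#' @export
segment_spec <- function(behavior, duration,
                         peak_amp = NULL, valley_amp = NULL,
                         gyro_x_sd = NULL, noise_sd = 0.2,
                         shape = c("raised_cosine", "triangle", "gauss")) {
  behavior <- match.arg(behavior,
                        c("stationary", "walk", "fast_walk", "run", "leg_shake"))
  shape <- match.arg(shape)
  if (!is.numeric(duration) || duration <= 0) stop("duration must be > 0")
  defaults <- switch(behavior,
    stationary = list(peak_amp = NULL, valley_amp = NULL, gyro_x_sd = 0.1),
    walk = list(peak_amp = c(14, 18), valley_amp = NULL, gyro_x_sd = 0.5),
    run = list(peak_amp = c(31, 36), valley_amp = c(21, 25), gyro_x_sd = 2),
    leg_shake = list(peak_amp = c(16, 20), valley_amp = c(13, 15.5),
                     gyro_x_sd = sqrt(30)),
    fast_walk = list(peak_amp = c(16, 20), valley_amp = c(13, 15.5),
                     gyro_x_sd = sqrt(2))
  )
  peak_amp <- peak_amp %||% defaults$peak_amp
  valley_amp <- valley_amp %||% defaults$valley_amp
  gyro_x_sd <- gyro_x_sd %||% defaults$gyro_x_sd
  rng2 <- function(r) if (length(r) == 1L) c(r, r) else sort(r[1:2])
  if (!is.null(peak_amp)) peak_amp <- rng2(peak_amp)
  if (!is.null(valley_amp)) valley_amp <- rng2(valley_amp)

  # feasibility against the thresholds that define the behavior
  if (behavior == "walk" && peak_amp[1] <= 12) {
    stop("walk pulses must exceed the step threshold 12 m/s2")
  }
  if (behavior == "run") {
    if (peak_amp[1] <= 30) stop("run peaks must exceed thr1 = 30 m/s2")
    if (valley_amp[1] <= 20) stop("run valleys must exceed thr4 = 20 m/s2")
    if (valley_amp[2] >= peak_amp[1]) stop("run valleys must stay below peaks")
  }
  if (behavior %in% c("leg_shake", "fast_walk")) {
    if (peak_amp[1] <= 12 || peak_amp[2] >= 39) {
      stop(behavior, " peaks must lie strictly between thr5 = 12 and thr8 = 39")
    }
    if (valley_amp[1] <= 12) stop(behavior, " valleys must exceed thr7 = 12")
    if (valley_amp[2] >= peak_amp[1]) stop(behavior, " valleys must stay below peaks")
  }
  structure(list(behavior = behavior, duration = duration,
                 peak_amp = peak_amp, valley_amp = valley_amp,
                 gyro_x_sd = gyro_x_sd, noise_sd = noise_sd, shape = shape),
            class = "segment_spec")
}

pulse_shape <- function(u, shape) {
  switch(shape,
    raised_cosine = 0.5 * (1 - cos(2 * pi * u)),
    triangle = 1 - abs(2 * u - 1),
    gauss = exp(-((u - 0.5)^2) / (2 * 0.15^2))
  )
}

# one pulse per `period` samples on a flat baseline; returns profile + count
walk_profile <- function(n, period, width, baseline, amp_range, shape) {
  prof <- rep(baseline, n)
  starts <- seq(1L, n - width, by = period)
  for (s in starts) {
    amp <- runif(1, amp_range[1], amp_range[2])
    u <- (0:(width - 1L)) / (width - 1L)
    prof[s:(s + width - 1L)] <- baseline + (amp - baseline) * pulse_shape(u, shape)
  }
  list(profile = prof, steps = length(starts))
}

# continuous valley-peak-valley oscillation with per-cycle drawn levels
oscillation_profile <- function(n, period, peak_range, valley_range, shape) {
  bounds <- unique(round(seq(1, n, by = period)))
  if (n - bounds[length(bounds)] >= period / 2) {
    bounds <- c(bounds, n)           # remnant long enough to hold a cycle
  } else {
    bounds[length(bounds)] <- n      # stretch the last cycle to the end
    bounds <- unique(bounds)
  }
  k <- length(bounds) - 1L
  if (k < 1L) return(list(profile = rep(mean(valley_range), n), steps = 0L))
  vals <- runif(k + 1L, valley_range[1], valley_range[2])
  prof <- numeric(n)
  for (c_i in seq_len(k)) {
    s <- bounds[c_i]
    e <- bounds[c_i + 1L]
    m <- e - s
    pk <- runif(1, peak_range[1], peak_range[2])
    if (m < 4L) {  # cycle remnant too short for a pulse: bridge the valleys
      prof[s:e] <- seq(vals[c_i], vals[c_i + 1L], length.out = m + 1L)
      next
    }
    half <- max(1L, floor(m / 2))
    # rise from valley to peak over the first half-cycle,
    # fall to the next valley over the second
    up <- vals[c_i] + (pk - vals[c_i]) *
      pulse_shape(0.5 * (0:half) / half, shape)
    down <- vals[c_i + 1L] + (pk - vals[c_i + 1L]) *
      pulse_shape(0.5 + 0.5 * (0:(m - half)) / (m - half), shape)
    prof[s:(s + half)] <- up
    prof[(s + half):e] <- down
  }
  prof[n] <- vals[k + 1L]
  list(profile = prof, steps = k)
}

#' Generate a labeled synthetic six-axis trace
#'
#' Concatenates the requested behavior segments into an [imu_series()] with
#' known ground truth. The magnitude profile is carried on the z axis
#' (vertical leg motion); x and y carry noise only, so the combined
#' acceleration reproduces the profile up to noise. Only the x gyro carries
#' behavior signal; y and z gyro are low-level noise. Deterministic given
#' `seed`.
#'
#' @param specs a list of [segment_spec()] objects (a single spec is
#'   accepted).
#' @param fs sampling frequency in Hz (default 32).
#' @param seed integer RNG seed.
#' @return A list with `series` (an [imu_series()]) and `truth`, a
#'   `gait_truth` object: a per-segment data.frame (`behavior`, `start`,
#'   `end`, `steps`) and `total_steps` (leg-shake segments contribute 0).
#' @examples
#' g <- generate_trace(list(segment_spec("walk", 10)), seed = 42)
#' g$truth$total_steps
#' @export
generate_trace <- function(specs, fs = 32, seed = 1) {
  if (inherits(specs, "segment_spec")) specs <- list(specs)
  if (!length(specs)) stop("at least one segment spec is required")
  stopifnot(all(vapply(specs, inherits, logical(1), "segment_spec")))
  set.seed(as.integer(seed))
  g <- 9.8
  prof_all <- numeric(0)
  gyro_sd_all <- numeric(0)
  noise_sd_all <- numeric(0)
  seg_rows <- vector("list", length(specs))
  pos <- 0L
  for (si in seq_along(specs)) {
    sp <- specs[[si]]
    n <- max(2L, round(sp$duration * fs))
    res <- switch(sp$behavior,
      stationary = list(profile = rep(g, n), steps = 0L),
      walk = walk_profile(n, period = 29L, width = 13L, baseline = g,
                          amp_range = sp$peak_amp, shape = sp$shape),
      run = oscillation_profile(n, period = 29 / 2.1,
                                peak_range = sp$peak_amp,
                                valley_range = sp$valley_amp, shape = sp$shape),
      leg_shake = ,
      fast_walk = oscillation_profile(n, period = 10,
                                      peak_range = sp$peak_amp,
                                      valley_range = sp$valley_amp,
                                      shape = sp$shape)
    )
    prof_all <- c(prof_all, res$profile)
    gyro_sd_all <- c(gyro_sd_all, rep(sp$gyro_x_sd, n))
    noise_sd_all <- c(noise_sd_all, rep(sp$noise_sd, n))
    counted <- if (sp$behavior == "leg_shake") 0L else res$steps
    seg_rows[[si]] <- data.frame(
      segment = si, behavior = sp$behavior,
      start = pos + 1L, end = pos + n,
      cycles = res$steps, steps = counted
    )
    pos <- pos + n
  }
  n_tot <- length(prof_all)
  series <- imu_series(
    acc_x = rnorm(n_tot, 0, noise_sd_all),
    acc_y = rnorm(n_tot, 0, noise_sd_all),
    acc_z = prof_all + rnorm(n_tot, 0, noise_sd_all),
    gyro_x = rnorm(n_tot, 0, gyro_sd_all),
    gyro_y = rnorm(n_tot, 0, 0.1),
    gyro_z = rnorm(n_tot, 0, 0.1),
    timestamps = (seq_len(n_tot) - 1) / fs,
    fs = fs
  )
  segments <- do.call(rbind, seg_rows)
  truth <- structure(list(segments = segments,
                          total_steps = sum(segments$steps),
                          fs = fs, seed = as.integer(seed)),
                     class = "gait_truth")
  list(series = series, truth = truth)
}

#' @export
print.gait_truth <- function(x, ...) {
  cat(sprintf("<gait_truth> %d segment(s), %d true steps (seed %d)\n",
              nrow(x$segments), x$total_steps, x$seed))
  print(x$segments, row.names = FALSE)
  invisible(x)
}

#' Write or read a synthetic fixture (CSV trace + JSON ground truth)
#'
#' `write_fixture()` writes `<prefix>.csv` in the dialect of
#' [read_imu_csv()] and `<prefix>.truth.json`; `read_fixture()` round-trips
#' them.
#'
#' @param trace result of [generate_trace()] (or a list with `series` and
#'   `truth`).
#' @param prefix output path prefix.
#' @return `write_fixture()`: the two paths, invisibly. `read_fixture()`: a
#'   list with `series` and `truth`.
#' @export
write_fixture <- function(trace, prefix) {
  csv <- paste0(prefix, ".csv")
  js <- paste0(prefix, ".truth.json")
  write_imu_csv(trace$series, csv)
  tr <- trace$truth
  jsonlite::write_json(
    list(segments = tr$segments, total_steps = tr$total_steps,
         fs = tr$fs, seed = tr$seed),
    js, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(c(csv = csv, truth = js))
}

#' @rdname write_fixture
#' @export
read_fixture <- function(prefix) {
  series <- read_imu_csv(paste0(prefix, ".csv"))
  raw <- jsonlite::read_json(paste0(prefix, ".truth.json"), simplifyVector = TRUE)
  truth <- structure(list(segments = raw$segments,
                          total_steps = raw$total_steps,
                          fs = raw$fs, seed = raw$seed),
                     class = "gait_truth")
  list(series = series, truth = truth)
}
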