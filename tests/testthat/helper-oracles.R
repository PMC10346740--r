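# Independent brute-force oracles, kept deliberately naive: they evaluate
# every defining inequality directly, one index at a time.

brute_peaks <- function(x, n, thr) {
  idx <- integer(0)
  for (i in seq_along(x)) {
    if (i <= n || i > length(x) - n) next
    ok <- x[i] > thr
    if (ok) {
      for (k in 1:n) {
        if (!(x[i - k + 1] > x[i - k])) { ok <- FALSE; break }
      }
    }
    if (ok) {
      for (k in 1:n) {
        if (!(x[i + k - 1] > x[i + k])) { ok <- FALSE; break }
      }
    }
    if (ok) idx <- c(idx, i)
  }
  idx
}

brute_valleys <- function(x, n) {
  idx <- integer(0)
  for (i in seq_along(x)) {
    if (i <= n || i > length(x) - n) next
    ok <- TRUE
    for (k in 1:n) {
      if (!(x[i - k + 1] < x[i - k])) { ok <- FALSE; break }
    }
    if (ok) {
      for (k in 1:n) {
        if (!(x[i + k - 1] < x[i + k])) { ok <- FALSE; break }
      }
    }
    if (ok) idx <- c(idx, i)
  }
  idx
}

brute_moments <- function(x) {
  n <- length(x)
  mu <- 0
  for (v in x) mu <- mu + v
  mu <- mu / n
  m2 <- m3 <- m4 <- 0
  for (v in x) {
    d <- v - mu
    m2 <- m2 + d^2
    m3 <- m3 + d^3
    m4 <- m4 + d^4
  }
  m2 <- m2 / n; m3 <- m3 / n; m4 <- m4 / n
  list(mean = mu, var = m2, std = sqrt(m2),
       kurt = if (m2 == 0) 0 else m4 / m2^2 - 3,
       skew = if (m2 == 0) 0 else m3 / m2^1.5)
}

# hand-assembled extrema set for rule tests (values chosen per scenario)
make_extrema <- function(peak_idx, peak_val, pair_valley_val,
                         pair_valley_idx = peak_idx + 5L, thr = 12) {
  structure(list(
    peak_indices = as.integer(peak_idx),
    peak_values = as.numeric(peak_val),
    valley_indices = as.integer(pair_valley_idx),
    valley_values = as.numeric(pair_valley_val),
    above_thr = peak_val > thr,
    n_peak = 4L, n_valley = 2L, thr = thr
  ), class = "extrema_set")
}

# standard mixed-behavior trace layout used in recovery tests
mixed_specs <- function() {
  list(segment_spec("walk", 20), segment_spec("stationary", 3),
       segment_spec("run", 8), segment_spec("stationary", 3),
       segment_spec("leg_shake", 6), segment_spec("stationary", 3),
       segment_spec("fast_walk", 6), segment_spec("stationary", 3),
       segment_spec("walk", 15))
}
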