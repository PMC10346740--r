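test_that("segment specs reject amplitudes incompatible with their behavior", {
  expect_error(segment_spec("run", 5, peak_amp = c(25, 28)), "thr1")
  expect_error(segment_spec("run", 5, valley_amp = c(15, 18)), "thr4")
  expect_error(segment_spec("leg_shake", 5, peak_amp = c(35, 45)), "between")
  expect_error(segment_spec("leg_shake", 5, valley_amp = c(8, 10)), "thr7")
  expect_error(segment_spec("walk", 5, peak_amp = c(10, 11)), "threshold")
  expect_error(segment_spec("walk", 0), "duration")
  expect_s3_class(segment_spec("walk", 5), "segment_spec")
})

test_that("generation is deterministic under a fixed seed", {
  g1 <- generate_trace(mixed_specs(), seed = 99)
  g2 <- generate_trace(mixed_specs(), seed = 99)
  expect_identical(g1$series$acc_z, g2$series$acc_z)
  expect_identical(g1$series$gyro_x, g2$series$gyro_x)
  expect_identical(g1$truth$segments, g2$truth$segments)
  g3 <- generate_trace(mixed_specs(), seed = 100)
  expect_false(identical(g1$series$acc_z, g3$series$acc_z))
})

test_that("stationary traces count zero steps", {
  g <- generate_trace(list(segment_spec("stationary", 20)), seed = 5)
  expect_equal(g$truth$total_steps, 0)
  expect_equal(count_steps(g$series)$total_steps, 0)
})

test_that("walk segments at default noise produce no false behavior windows", {
  for (seed in 1:5) {
    g <- generate_trace(list(segment_spec("walk", 25)), seed = seed)
    mag <- prepare_magnitude(g$series)
    ex <- detect_extrema(mag)
    run <- detect_running(ex, signal = mag)
    expect_equal(sum(run$is_running), 0)
    cand <- detect_leg_shake_candidates(ex, mag, running_windows = run)
    expect_equal(nrow(cand), 0)
  }
})

test_that("an injected running burst is recovered as one window covering it", {
  g <- generate_trace(list(segment_spec("stationary", 4),
                           segment_spec("run", 10),
                           segment_spec("stationary", 4)), seed = 8)
  mag <- prepare_magnitude(g$series)
  ex <- detect_extrema(mag)
  run <- detect_running(ex, signal = mag)
  run <- run[run$is_running, ]
  expect_equal(nrow(run), 1)
  seg <- g$truth$segments[g$truth$segments$behavior == "run", ]
  burst_cov <- (min(run$end, seg$end) - max(run$start, seg$start)) /
    (seg$end - seg$start)
  expect_gte(burst_cov, 0.9)
  # window-length step estimate near the constructed truth
  expect_lte(abs(running_steps(run$W) - seg$steps), 1)
})

test_that("leg shake and fast walk are perfectly discriminated at default variance separation", {
  labels <- character(0)
  predicted <- character(0)
  for (seed in 1:10) {
    for (beh in c("leg_shake", "fast_walk")) {
      g <- generate_trace(list(segment_spec("stationary", 2),
                               segment_spec(beh, 6),
                               segment_spec("stationary", 2)), seed = seed)
      mag <- prepare_magnitude(g$series)
      ex <- detect_extrema(mag)
      run <- detect_running(ex, signal = mag)
      cand <- detect_leg_shake_candidates(ex, mag, running_windows = run)
      expect_equal(nrow(cand), 1)
      labels <- c(labels, beh)
      predicted <- c(predicted, classify_candidate(cand[1, ], g$series$gyro_x))
    }
  }
  expect_equal(predicted, labels)

  # accuracy does not improve when the variance separation collapses
  acc_at <- function(sd_shake, sd_fast) {
    hits <- 0; tot <- 0
    for (seed in 1:6) {
      for (beh in c("leg_shake", "fast_walk")) {
        sd <- if (beh == "leg_shake") sd_shake else sd_fast
        g <- generate_trace(list(segment_spec("stationary", 2),
                                 segment_spec(beh, 6, gyro_x_sd = sd),
                                 segment_spec("stationary", 2)), seed = seed)
        mag <- prepare_magnitude(g$series)
        ex <- detect_extrema(mag)
        cand <- detect_leg_shake_candidates(ex, mag)
        if (!nrow(cand)) next
        tot <- tot + 1
        hits <- hits + (classify_candidate(cand[1, ], g$series$gyro_x) == beh)
      }
    }
    hits / tot
  }
  wide <- acc_at(sqrt(30), sqrt(2))
  narrow <- acc_at(sqrt(12), sqrt(8))
  expect_equal(wide, 1)
  expect_lte(narrow, wide)
})

test_that("fixtures round-trip through CSV + JSON losslessly", {
  g <- generate_trace(list(segment_spec("walk", 8),
                           segment_spec("stationary", 2)), seed = 17)
  prefix <- file.path(tempdir(), "fix-a")
  write_fixture(g, prefix)
  back <- read_fixture(prefix)
  expect_equal(back$series$acc_z, g$series$acc_z, tolerance = 1e-6)
  expect_equal(back$series$gyro_x, g$series$gyro_x, tolerance = 1e-6)
  expect_equal(back$truth$total_steps, g$truth$total_steps)
  expect_equal(sum(back$truth$segments$steps), back$truth$total_steps)

  # identical seed, byte-identical CSV
  prefix2 <- file.path(tempdir(), "fix-b")
  write_fixture(generate_trace(list(segment_spec("walk", 8),
                                    segment_spec("stationary", 2)), seed = 17),
                prefix2)
  expect_identical(readLines(paste0(prefix, ".csv")),
                   readLines(paste0(prefix2, ".csv")))
})
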