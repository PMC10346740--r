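cfg <- threshold_config()

test_that("a sustained high-peak burst with elevated valleys is labeled running", {
  # peaks 32/35/33/31 with valleys 22/24/23 between them, then a peak of 10
  ex <- make_extrema(peak_idx = c(10, 24, 38, 52, 66),
                     peak_val = c(32, 35, 33, 31, 10),
                     pair_valley_val = c(22, 24, 23, 8, 7))
  w <- detect_running(ex, cfg)
  expect_equal(nrow(w), 1)
  expect_true(w$is_running)
  expect_equal(w$start, 10L)
  expect_equal(w$end, 66L)        # closes at the low peak
  expect_equal(w$W, 56L)          # sample-index difference
  expect_equal(w$peak_ids[[1]], 1:4)
  expect_false(w$truncated)
})

test_that("running windows need thr1 to open and elevated valleys to qualify", {
  # no peak above 30: nothing opens
  ex <- make_extrema(c(10, 24, 38), c(25, 28, 10), c(20, 8, 7))
  expect_equal(nrow(detect_running(ex, cfg)), 0)

  # one interior valley at 15 (< thr4 = 20): window found but not running
  ex <- make_extrema(c(10, 24, 38, 52, 66),
                     c(32, 35, 33, 31, 10),
                     c(22, 15, 23, 8, 7))
  w <- detect_running(ex, cfg)
  expect_equal(nrow(w), 1)
  expect_false(w$is_running)

  # with pair_rule = "any" a single qualifying pair suffices
  w2 <- detect_running(ex, threshold_config(pair_rule = "any"))
  expect_true(w2$is_running)
})

test_that("the reduced pair rule acc_v > thr4 equals the printed difference form", {
  set.seed(21)
  for (i in 1:100) {
    acc_p <- runif(1, 20, 40)
    acc_v <- runif(1, 10, 30)
    expect_identical(acc_p - acc_v < acc_p - cfg$thr4, acc_v > cfg$thr4)
  }
})

test_that("a still-open running window is truncated at the end of the series", {
  ex <- make_extrema(c(10, 24, 38), c(32, 35, 33), c(22, 24, 23))
  sig <- magnitude_series(rep(25, 100), fs = 32)
  w <- detect_running(ex, cfg, signal = sig)
  expect_equal(nrow(w), 1)
  expect_true(w$truncated)
  expect_equal(w$end, 101L)
})

test_that("moderate oscillation with elevated valleys is a leg-shake candidate", {
  # peaks 14/16/15 with valleys 13/13 between, closing drop to a peak below 12
  ex <- make_extrema(c(10, 20, 30, 40), c(14, 16, 15, 9), c(13, 13, 8, 7))
  sig <- magnitude_series(rep(13, 50), fs = 32)
  w <- detect_leg_shake_candidates(ex, sig, cfg)
  expect_equal(nrow(w), 1)
  expect_equal(w$start, 10L)
  expect_equal(w$end, 40L)
  expect_equal(w$peak_ids[[1]], 1:3)

  # regional peak restriction: one peak at 45 >= thr8 disqualifies the window
  ex2 <- make_extrema(c(10, 20, 30, 40), c(14, 45, 15, 9), c(13, 13, 8, 7))
  expect_equal(nrow(detect_leg_shake_candidates(ex2, sig, cfg)), 0)

  # empty extrema stream
  ex3 <- make_extrema(integer(0), numeric(0), numeric(0))
  expect_equal(nrow(detect_leg_shake_candidates(ex3, sig, cfg)), 0)
})

test_that("an isolated step (single peak, then baseline) is not a candidate", {
  ex <- make_extrema(c(10, 20), c(15, 9), c(9, 7))
  sig <- magnitude_series(rep(10, 30), fs = 32)
  expect_equal(nrow(detect_leg_shake_candidates(ex, sig, cfg)), 0)
})

test_that("candidates overlapping a running window are discarded", {
  ex <- make_extrema(c(10, 24, 38, 52, 66),
                     c(32, 35, 33, 31, 10),
                     c(22, 24, 23, 8, 7))
  sig <- magnitude_series(rep(25, 100), fs = 32)
  run <- detect_running(ex, cfg, signal = sig)
  cand <- detect_leg_shake_candidates(ex, sig, cfg, running_windows = run)
  expect_equal(nrow(cand), 0)
})

test_that("gyro variance separates leg shaking from fast walking at the cut", {
  win <- list(start = 1L, end = 101L)
  set.seed(22)
  scale_to_var <- function(x, v) {
    x <- x - mean(x)
    x / sqrt(mean(x^2)) * sqrt(v)
  }
  g <- scale_to_var(rnorm(100), 26.88633)
  expect_equal(classify_candidate(win, g, cfg), "leg_shake")
  expect_equal(classify_candidate(win, rep(0.3, 100), cfg), "fast_walk")
  # boundary: variance exactly 10 is fast walking (strict >)
  g10 <- rep(c(-2, 2, -4, 4), 25)  # population variance exactly 10
  expect_equal(mean((g10 - mean(g10))^2), 10)
  expect_equal(classify_candidate(win, g10, cfg), "fast_walk")
  # degenerate single-sample window
  expect_warning(
    lab <- classify_candidate(list(start = 1L, end = 2L), rnorm(5), cfg),
    "variance undefined")
  expect_equal(lab, "fast_walk")
})

test_that("moment features match a direct-summation oracle", {
  expect_warning(f <- extract_features(c(1, 1, 1, 1)), "constant")
  expect_equal(unclass(f)[c("mean", "var", "std", "kurt", "skew")],
               list(mean = 1, var = 0, std = 0, kurt = 0, skew = 0))
  f <- extract_features(c(0, 2))
  expect_equal(f$mean, 1)
  expect_equal(f$var, 1)  # population variance

  set.seed(23)
  for (i in 1:20) {
    x <- rnorm(64, sd = runif(1, 0.5, 5))
    f <- extract_features(x)
    o <- brute_moments(x)
    for (nm in names(o)) expect_equal(f[[nm]], o[[nm]], tolerance = 1e-9)
    expect_equal(f$std^2, f$var, tolerance = 1e-9)
  }
  # sample-variance flavour available
  expect_equal(extract_features(c(0, 2), var_type = "sample")$var, 2)
})

test_that("k-means recovers well-separated feature blobs and degenerate inputs are handled", {
  set.seed(24)
  x <- matrix(c(rnorm(30, -10, 0.1), rnorm(30, 0, 0.1), rnorm(30, 10, 0.1)),
              ncol = 1)
  truth <- rep(1:3, each = 30)
  res <- cluster_behaviors(x, k = 3, seed = 5)
  expect_equal(length(unique(res$cluster)), 3)
  # each blob lands in a single cluster
  for (b in 1:3) expect_equal(length(unique(res$cluster[truth == b])), 1)
  # determinism given seed
  res2 <- cluster_behaviors(x, k = 3, seed = 5)
  expect_identical(res$cluster, res2$cluster)

  expect_warning(dup <- cluster_behaviors(matrix(1, 5, 2), k = 3), "distinct")
  expect_true(all(dup$cluster == dup$cluster[1]))

  res1 <- cluster_behaviors(x, k = 1)
  expect_equal(as.numeric(res1$centers), mean(x))

  expect_error(cluster_behaviors(x[1:2, , drop = FALSE], k = 3), "at least")
})

test_that("confusion metrics follow their defining formulas, flagging empty denominators", {
  m <- classification_metrics(c("p", "p", "n", "n"), c("p", "p", "n", "n"),
                              positive = "p")
  expect_equal(m[c("accuracy", "precision", "recall")],
               list(accuracy = 1, precision = 1, recall = 1))

  pred <- c(rep("p", 10), rep("n", 10))
  act <- c(rep("p", 9), "n", "p", rep("n", 9))
  m <- classification_metrics(pred, act, positive = "p")
  expect_equal(m$precision, 0.9)
  expect_equal(m$recall, 0.9)
  expect_equal(m$accuracy, 0.9)

  # nothing predicted positive and no positives present
  m <- classification_metrics(rep("n", 4), rep("n", 4), positive = "p")
  expect_true(is.nan(m$precision))
  expect_true(is.nan(m$recall))
  expect_error(classification_metrics(c("a", "b"), "a"), "equal length")

  # property: accuracy == (TP+TN)/total over random confusion settings
  set.seed(25)
  for (i in 1:50) {
    n <- sample(4:40, 1)
    pred <- sample(c("p", "n"), n, replace = TRUE)
    act <- sample(c("p", "n"), n, replace = TRUE)
    m <- classification_metrics(pred, act, positive = "p")
    expect_equal(m$accuracy, (m$TP + m$TN) / n)
  }
})
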