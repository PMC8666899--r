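fs <- 62.5

test_that("threshold parameter validation and documented defaults", {
  p <- threshold_params()
  expect_equal(p$alpha, 0.4)
  expect_equal(p$n_breaths, 15L)
  expect_error(threshold_params(alpha = 0), "alpha")
  expect_error(threshold_params(n_breaths = 0), "n_breaths")
  expect_error(threshold_params(refractory = -1), "refractory")
})

test_that("zero signal yields no breaths; short signal errors", {
  filt <- as_filtered(numeric(60 * fs), fs)
  train <- detect_breaths(filt)
  expect_length(train$breath_times, 0)
  expect_error(detect_breaths(as_filtered(numeric(5 * fs), fs)),
               "init_window")
})

test_that("a clean sinusoid is detected once per cycle", {
  t <- (0:(120 * fs - 1)) / fs
  filt <- as_filtered(sin(2 * pi * 1 * t), fs)
  train <- detect_breaths(filt)
  truth <- 0:119  # upward zero crossings
  m <- match_events(train$breath_times, truth, tol = 0.25)
  expect_gte(m$sensitivity, 0.95)
  expect_lte(m$fdr, 0.05)
  expect_true(all(diff(train$breath_times) >= threshold_params()$refractory))
})

test_that("detector matches the per-sample brute-force reference exactly", {
  set.seed(20)
  for (rep in 1:4) {
    n <- round(30 * fs)
    t <- (0:(n - 1)) / fs
    x <- sin(2 * pi * stats::runif(1, 0.5, 1.2) * t) *
      (1 + 0.2 * sin(2 * pi * t / 25)) + 0.08 * stats::rnorm(n)
    mask <- rep(FALSE, n)
    if (rep %% 2 == 0) mask[round(10 * fs):round(12 * fs)] <- TRUE
    filt <- as_filtered(x, fs, mask)
    train <- detect_breaths(filt)
    ref <- ref_detect_breaths(x, fs, mask)
    expect_identical(train$breath_times, ref$times)
    expect_equal(train$threshold_trace, ref$thr, tolerance = 1e-12)
  }
})

test_that("threshold is positive wherever trailing signal is non-zero", {
  sim <- simulate_recording(simulation_config(duration = 120, seed = 21))
  filt <- preprocess(sim$recording)
  train <- detect_breaths(filt)
  expect_true(all(train$threshold_trace > 0))
})

test_that("no detected breath lies inside a masked artefact span", {
  sim <- simulate_recording(simulation_config(duration = 200, seed = 22))
  sim <- inject_movement_artefact(sim$recording, sim$truth, 90, 6, 10)
  filt <- preprocess(sim$recording)
  train <- detect_breaths(filt)
  masked_t <- which(filt$mask)
  if (length(masked_t)) {
    idx <- round(train$breath_times * fs) + 1
    expect_false(any(idx %in% masked_t))
  }
})

test_that("increasing alpha trades false positives for false negatives", {
  sim <- simulate_recording(
    simulation_config(duration = 300, noise_sd = 0.15, seed = 23))
  filt <- preprocess(sim$recording)
  truth <- sim$truth$breath_times
  fp <- fn <- numeric(0)
  # matching tolerance must exceed the threshold-crossing phase delay at
  # high alpha (a higher threshold is crossed later in the same breath)
  for (a in c(0.2, 0.4, 0.8, 1.2)) {
    train <- detect_breaths(filt, threshold_params(alpha = a))
    m <- match_events(train$breath_times, truth, tol = 0.6)
    fp <- c(fp, round(m$fdr * length(train$breath_times)))
    fn <- c(fn, round((1 - m$sensitivity) * length(truth)))
  }
  expect_true(all(diff(fp) <= 0))
  expect_true(all(diff(fn) >= 0))
})

test_that("IBIs tile the gaps between breaths and honour the mask rule", {
  train <- structure(list(breath_times = 0:10, rate = fs, duration = 11),
                     class = "breath_train")
  ibis <- compute_ibis(train)
  expect_equal(nrow(ibis$intervals), 10L)
  expect_true(all(ibis$intervals$duration == 1))
  expect_true(all(ibis$intervals$valid))
  expect_equal(ibis$intervals$start, as.numeric(0:9))

  # an interval 60% covered by mask is invalid at the default tolerance
  n <- round(12 * fs)
  mask <- rep(FALSE, n)
  mask[round(3 * fs):round(3.6 * fs)] <- TRUE  # covers 60% of [3, 4]
  filt <- as_filtered(numeric(n), fs, mask)
  ibis2 <- compute_ibis(train, filt)
  expect_false(ibis2$intervals$valid[4])
  expect_true(all(ibis2$intervals$valid[-4]))
})

test_that("pause extraction filters by duration and validity", {
  iv <- data.frame(start = c(0, 1, 2, 8, 20), end = c(1, 2, 8, 20, 50),
                   duration = c(1, 1, 6, 12, 30),
                   valid = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  ibis <- structure(list(intervals = iv), class = "ibi_series")
  p5 <- detect_pauses(ibis, 5)
  expect_equal(p5$duration, c(6, 12))
  expect_equal(nrow(detect_pauses(ibis, 20)), 0L)  # the 30 s one is invalid
  empty <- structure(list(intervals = iv[0, ]), class = "ibi_series")
  expect_equal(nrow(detect_pauses(empty, 5)), 0L)
  expect_error(detect_pauses(ibis, 0), "min_duration")
})

test_that("an injected apnoea appears as one long valid interval", {
  sim <- simulate_recording(simulation_config(duration = 300, seed = 24))
  sim <- inject_pause(sim$recording, sim$truth, 120, 25,
                      "apnoea-no-response")
  filt <- preprocess(sim$recording)
  ibis <- compute_ibis(detect_breaths(filt), filt)
  long <- ibis$intervals[ibis$intervals$valid & ibis$intervals$duration >= 20, ]
  expect_equal(nrow(long), 1L)
  # the gate snaps outward to breath onsets, so the achieved gap can
  # exceed the requested 25 s by up to two breath periods
  expect_gte(long$duration, 24)
  expect_lte(long$duration, 25 + 2 * 60 / 50 + 0.5)
})

test_that("respiratory rate recovers the breathing rate", {
  train <- structure(list(breath_times = seq(0, 59.999, by = 1), rate = fs,
                          duration = 60), class = "breath_train")
  rr <- respiratory_rate(train, window = 30, step = 1)
  expect_true(all(abs(rr$rate[rr$time >= 30] - 60) <= 2))
  empty <- structure(list(breath_times = numeric(0), rate = fs,
                          duration = 60), class = "breath_train")
  expect_true(all(respiratory_rate(empty)$rate == 0))

  sim <- simulate_recording(
    simulation_config(duration = 300, breath_rate_mean = 45, seed = 25))
  filt <- preprocess(sim$recording)
  rr2 <- respiratory_rate(detect_breaths(filt), window = 30)
  expect_equal(mean(rr2$rate[rr2$time >= 30]), 45, tolerance = 2 / 45)
})
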