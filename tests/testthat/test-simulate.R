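test_that("deterministic periodic breathing gives one breath per second", {
  sim <- simulate_recording(quiet_cfg(duration = 60, breath_rate_mean = 60))
  bt <- sim$truth$breath_times
  expect_true(abs(length(bt) - 60) <= 1)
  expect_true(all(abs(diff(bt) - 1.0) < 1e-3))
  expect_true(all(diff(bt) > 0))
})

test_that("null configuration produces an identically zero IP", {
  sim <- simulate_recording(
    simulation_config(duration = 30, breath_amplitude = 0, noise_sd = 0,
                      cardiac_amplitude_ratio = 0))
  expect_equal(max(abs(sim$recording$ip)), 0)
})

test_that("identical configs give bit-identical recordings and truths", {
  cfg <- simulation_config(duration = 60, seed = 42)
  a <- simulate_recording(cfg)
  b <- simulate_recording(cfg)
  expect_identical(a$recording$ip, b$recording$ip)
  expect_identical(a$truth$breath_times, b$truth$breath_times)
  c <- simulate_recording(simulation_config(duration = 60, seed = 43))
  expect_false(identical(a$recording$ip, c$recording$ip))
})

test_that("invalid configurations name the offending field", {
  expect_error(simulation_config(duration = -1), "duration")
  expect_error(simulation_config(breath_rate_mean = 5), "breath_rate_mean")
  expect_error(simulation_config(ip_rate = 5, cardiac_rate = 150),
               "ip_rate")
  expect_error(simulation_config(noise_sd = -0.1), "noise_sd")
})

test_that("jitter-free spectrum peaks only at breath and cardiac frequencies", {
  cfg <- simulation_config(duration = 120, breath_rate_mean = 48,
                           breath_rate_jitter = 0, amplitude_drift = 0,
                           cardiac_rate = 150,
                           cardiac_amplitude_ratio = 0.3, noise_sd = 0)
  sim <- simulate_recording(cfg)
  x <- sim$recording$ip
  n <- length(x)
  spec <- Mod(stats::fft(x - mean(x)))^2
  freqs <- (0:(n - 1)) * cfg$ip_rate / n
  half <- freqs <= cfg$ip_rate / 2
  f_peak <- freqs[half][which.max(spec[half])]
  expect_equal(f_peak, 48 / 60, tolerance = 0.02)
  # second peak (cardiac): exclude the breathing neighbourhood
  away <- half & abs(freqs - f_peak) > 0.3
  f_peak2 <- freqs[away][which.max(spec[away])]
  expect_equal(f_peak2, 150 / 60, tolerance = 0.05)
})

test_that("injected apnoea with response shapes HR and SpO2 nadirs", {
  sim <- simulate_recording(simulation_config(duration = 200, seed = 5))
  sim <- inject_pause(sim$recording, sim$truth, 50, 25,
                      "apnoea-with-response", hr_response = 90,
                      spo2_response = 75)
  hr <- sim$recording$hr
  spo2 <- sim$recording$spo2
  i60 <- 51:111  # samples covering [50, 110] s at 1 Hz
  expect_equal(min(hr[i60]), 90, tolerance = 1e-6)
  expect_equal(min(spo2[i60]), 75, tolerance = 1e-6)
  expect_true(all(hr[1:45] == 150))
  # no ground-truth breaths inside the pause
  expect_false(any(sim$truth$breath_times > 50 & sim$truth$breath_times < 75))
})

test_that("low-amplitude episodes keep their ground-truth breaths", {
  sim <- simulate_recording(simulation_config(duration = 200, seed = 6))
  before <- sim$truth$breath_times
  sim <- inject_pause(sim$recording, sim$truth, 80, 25,
                      "low-amplitude-false-alarm")
  expect_identical(sim$truth$breath_times, before)
  inside <- sim$truth$breath_times > 85 & sim$truth$breath_times < 100
  expect_true(any(inside))
})

test_that("pause injection enforces duration, bounds and overlap rules", {
  sim <- simulate_recording(simulation_config(duration = 200, seed = 7))
  expect_error(inject_pause(sim$recording, sim$truth, 50, 10,
                            "apnoea-with-response"), ">= 20")
  expect_error(inject_pause(sim$recording, sim$truth, 190, 25,
                            "apnoea-no-response"), "outside")
  sim <- inject_pause(sim$recording, sim$truth, 50, 25, "apnoea-no-response")
  expect_error(inject_pause(sim$recording, sim$truth, 60, 25,
                            "apnoea-no-response"), "overlap")
  # a plain pause may be short
  sim2 <- inject_pause(sim$recording, sim$truth, 120, 8, "pause")
  expect_equal(nrow(sim2$truth$pause_intervals), 2L)
})

test_that("movement artefacts reach the requested magnitude and are validated", {
  sim <- simulate_recording(simulation_config(duration = 120, seed = 8))
  amp0 <- max(abs(sim$recording$components$breathing))
  sim2 <- inject_movement_artefact(sim$recording, sim$truth, 60, 5, 10)
  fs <- sim2$recording$ip_rate
  idx <- (round(60 * fs) + 1):round(65 * fs)
  expect_gte(max(abs(sim2$recording$ip[idx])), 10 * amp0 * 0.95)
  expect_error(inject_movement_artefact(sim$recording, sim$truth, 118, 5, 10),
               "outside")
  expect_error(inject_movement_artefact(sim$recording, sim$truth, 60, 5, 1),
               "magnitude")
})

test_that("ground-truth intervals stay inside the recording and never overlap", {
  for (seed in 1:5) {
    sim <- simulate_recording(simulation_config(duration = 300, seed = seed))
    sim <- inject_pause(sim$recording, sim$truth, 40 + 7 * seed, 22,
                        "apnoea-no-response")
    sim <- inject_pause(sim$recording, sim$truth, 150, 10, "pause")
    sim <- inject_movement_artefact(sim$recording, sim$truth, 250, 4, 8)
    tr <- sim$truth
    for (df in list(tr$pause_intervals, tr$artefact_intervals)) {
      expect_true(all(df$start >= 0 & df$end <= tr$duration))
      if (nrow(df) > 1) {
        o <- order(df$start)
        expect_true(all(df$start[o][-1] >= df$end[o][-nrow(df)]))
      }
    }
    expect_true(all(diff(tr$breath_times) > 0))
    ap <- tr$pause_intervals[tr$pause_intervals$kind != "low-amplitude-false-alarm", ]
    for (j in seq_len(nrow(ap)))
      expect_false(any(tr$breath_times > ap$start[j] &
                         tr$breath_times < ap$end[j]))
  }
})

test_that("feature-set generator has the promised class geometry", {
  fs1 <- simulate_feature_set(40, 40, separation = 6, seed = 1)
  fs2 <- simulate_feature_set(40, 40, separation = 6, seed = 1)
  expect_identical(fs1$features, fs2$features)
  expect_equal(levels(fs1$labels), c("apnoea", "false_alarm"))
  expect_equal(length(unique(fs1$subject_ids)), 15L)
  ap <- fs1$features[fs1$labels == "apnoea", ]
  fa <- fs1$features[fs1$labels == "false_alarm", ]
  expect_lt(mean(ap$rms_during), mean(ap$rms_pre10))
  expect_lt(mean(ap$delta_hr60), -10)
  expect_lt(abs(mean(fa$delta_hr60)), 5)
  expect_true(all(as.matrix(fs1$features[, 1:3]) >= 0))
  # separation 0: identical class distributions up to sampling noise
  fs0 <- simulate_feature_set(200, 200, separation = 0, seed = 2)
  m_ap <- colMeans(fs0$features[fs0$labels == "apnoea", ])
  m_fa <- colMeans(fs0$features[fs0$labels == "false_alarm", ])
  expect_lt(max(abs((m_ap - m_fa) / c(0.05, 0.15, 0.15, 8, 4))), 0.5)
})

test_that("large separation yields a linearly separable sample", {
  # brute-force check: a perceptron must converge on separable data
  fs <- simulate_feature_set(50, 50, separation = 6, seed = 3)
  x <- scale(as.matrix(fs$features))
  y <- ifelse(fs$labels == "apnoea", 1, -1)
  w <- rep(0, ncol(x)); b <- 0
  separable <- FALSE
  for (epoch in 1:500) {
    errs <- 0
    for (i in seq_len(nrow(x))) {
      if (y[i] * (sum(w * x[i, ]) + b) <= 0) {
        w <- w + y[i] * x[i, ]; b <- b + y[i]; errs <- errs + 1
      }
    }
    if (errs == 0) { separable <- TRUE; break }
  }
  expect_true(separable)
})
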