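#' Simulation configuration for synthetic infant recordings
#'
#' Builds and validates the parameter set for [simulate_recording()].  The
#' defaults describe a stable preterm infant on an impedance pneumograph:
#' quasi-periodic breathing around 50 breaths/min with mild rate jitter and
#' slow amplitude drift, a cardiac-frequency oscillation at the infant's
#' heart rate superimposed on the respiratory waveform, and additive white
#' measurement noise.
#'
#' @param duration Recording length in seconds.
#' @param ip_rate Sampling rate of the impedance pneumograph (IP) channel,
#'   Hz.  Must be at least four times the cardiac frequency so the cardiac
#'   component is representable.
#' @param numeric_rate Sampling rate of the heart-rate and SpO2 numerics, Hz.
#' @param breath_rate_mean Mean breathing rate, breaths/min (must lie in
#'   (10, 120)).
#' @param breath_rate_jitter Fractional SD of the instantaneous breathing
#'   rate (AR(1)-modulated).
#' @param breath_amplitude Breathing waveform amplitude, arbitrary impedance
#'   units.
#' @param amplitude_drift Slow multiplicative amplitude drift, expressed as a
#'   maximal fraction per minute.
#' @param cardiac_rate Heart rate, bpm.  Also the baseline of the HR numeric
#'   channel: the cardiac contamination of the IP and the HR numeric come
#'   from the same heart.
#' @param cardiac_amplitude_ratio Cardiac oscillation amplitude as a fraction
#'   of `breath_amplitude`.
#' @param noise_sd SD of additive white noise, arbitrary units.
#' @param spo2_baseline Baseline oxygen saturation, percent.
#' @param seed Integer seed; identical configs produce bit-identical
#'   recordings.
#' @return A `simulation_config` object (validated list).
#' @export
simulation_config <- function(duration = 300, ip_rate = 62.5,
                              numeric_rate = 1, breath_rate_mean = 50,
                              breath_rate_jitter = 0.1, breath_amplitude = 1,
                              amplitude_drift = 0.1, cardiac_rate = 150,
                              cardiac_amplitude_ratio = 0.2, noise_sd = 0.05,
                              spo2_baseline = 97, seed = 1L) {
  cfg <- list(duration = duration, ip_rate = ip_rate,
              numeric_rate = numeric_rate,
              breath_rate_mean = breath_rate_mean,
              breath_rate_jitter = breath_rate_jitter,
              breath_amplitude = breath_amplitude,
              amplitude_drift = amplitude_drift,
              cardiac_rate = cardiac_rate,
              cardiac_amplitude_ratio = cardiac_amplitude_ratio,
              noise_sd = noise_sd, spo2_baseline = spo2_baseline,
              seed = as.integer(seed))
  for (f in c("duration", "ip_rate", "numeric_rate", "breath_rate_mean",
              "breath_rate_jitter", "breath_amplitude", "amplitude_drift",
              "cardiac_rate", "cardiac_amplitude_ratio", "noise_sd",
              "spo2_baseline")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stopf("simulation_config: field '%s' must be a finite number", f)
  }
  if (cfg$duration <= 0)
    stopf("simulation_config: field 'duration' must be > 0")
  if (cfg$ip_rate < 4 * cfg$cardiac_rate / 60)
    stopf("simulation_config: field 'ip_rate' must be >= 4 x cardiac frequency (%.2f Hz)",
          cfg$cardiac_rate / 60)
  if (cfg$numeric_rate <= 0)
    stopf("simulation_config: field 'numeric_rate' must be > 0")
  if (cfg$breath_rate_mean <= 10 || cfg$breath_rate_mean >= 120)
    stopf("simulation_config: field 'breath_rate_mean' must lie in (10, 120) breaths/min")
  for (f in c("breath_amplitude", "cardiac_amplitude_ratio", "noise_sd",
              "breath_rate_jitter", "amplitude_drift"))
    if (cfg[[f]] < 0)
      stopf("simulation_config: field '%s' must be >= 0", f)
  structure(cfg, class = "simulation_config")
}

#' Simulate a synthetic impedance-pneumograph recording
#'
#' Generates one subject's synchronized IP / heart-rate / SpO2 channels
#' together with exhaustive ground truth.  The breathing waveform is a
#' phase-accumulator sinusoid: the instantaneous rate is
#' `breath_rate_mean * (1 + jitter * AR(1))`, the phase is its cumulative
#' integral, and a ground-truth breath time is every upward zero-crossing of
#' the phase (phase = 2 pi k), matching detection by upward threshold
#' crossing.  A cardiac-frequency sinusoid and white noise are added; HR and
#' SpO2 are constant baselines until events are injected with
#' [inject_pause()].
#'
#' @param config A [simulation_config()].
#' @param subject_id Subject identifier stored in the recording.
#' @return A list with elements `recording` (a `physio_recording`) and
#'   `truth` (a `ground_truth`).
#' @seealso [inject_pause()], [inject_movement_artefact()]
#' @export
simulate_recording <- function(config = simulation_config(),
                               subject_id = "sim01") {
  if (!inherits(config, "simulation_config"))
    config <- do.call(simulation_config, as.list(config))
  with_seed(config$seed, {
    fs <- config$ip_rate
    n <- round(config$duration * fs)
    t <- (seq_len(n) - 1) / fs

    # AR(1)-modulated instantaneous breathing rate (correlation time ~5 s)
    rho <- exp(-1 / (fs * 5))
    innov <- stats::rnorm(n) * sqrt(1 - rho^2)
    ar1 <- as.numeric(stats::filter(innov, rho, method = "recursive"))
    f_inst <- pmax(config$breath_rate_mean / 60 *
                     (1 + config$breath_rate_jitter * ar1), 0.05)
    phase <- -pi / 2 + 2 * pi * cumsum(f_inst) / fs

    # slow sinusoidal amplitude drift whose maximal slope is
    # amplitude_drift per minute (modulation period 240 s)
    drift_m <- config$amplitude_drift * (240 / 60) / (2 * pi)
    amp <- config$breath_amplitude * (1 + drift_m * sin(2 * pi * t / 240))

    breathing <- amp * sin(phase)
    noise <- config$noise_sd * stats::rnorm(n)

    breath_times <- phase_crossings(phase, fs)

    n_num <- max(1L, round(config$duration * config$numeric_rate))
    hr <- rep(config$cardiac_rate, n_num)
    spo2 <- rep(config$spo2_baseline, n_num)

    cardiac_amp <- config$cardiac_amplitude_ratio * config$breath_amplitude
    cardiac <- cardiac_wave(hr, config$numeric_rate, n, fs, cardiac_amp)
    recording <- new_physio_recording(
      subject_id = subject_id,
      ip = breathing + cardiac + noise, ip_rate = fs,
      hr = hr, spo2 = spo2, numeric_rate = config$numeric_rate,
      duration = config$duration, cardiac_amp = cardiac_amp,
      components = list(breathing = breathing, cardiac = cardiac,
                        cardiac_scale = rep(1, n),
                        noise = noise, artefact = numeric(n)))
    truth <- new_ground_truth(breath_times = breath_times,
                              duration = config$duration)
    list(recording = recording, truth = truth)
  })
}

# Times at which an increasing phase crosses 2*pi*k (upward zero crossing of
# sin(phase)), by linear interpolation between samples.
phase_crossings <- function(phase, fs) {
  ph <- phase / (2 * pi)
  k <- floor(ph)
  idx <- which(diff(k) >= 1)
  if (!length(idx)) return(numeric(0))
  kc <- k[idx + 1L]  # crossed integer (rate jitter keeps steps <= 1)
  (idx - 1L + (kc - ph[idx]) / (ph[idx + 1L] - ph[idx])) / fs
}

new_physio_recording <- function(subject_id, ip, ip_rate, hr, spo2,
                                 numeric_rate, duration, start_time = 0,
                                 components = NULL, cardiac_amp = NULL) {
  structure(list(subject_id = subject_id, ip = ip, ip_rate = ip_rate,
                 hr = hr, spo2 = spo2, numeric_rate = numeric_rate,
                 start_time = start_time, duration = duration,
                 components = components, cardiac_amp = cardiac_amp),
            class = "physio_recording")
}

# Cardiac oscillation whose instantaneous frequency follows the HR numeric
# (phase accumulator), so bradycardia dips move the cardiac tone exactly as
# the HR-steered notch expects.
cardiac_wave <- function(hr, numeric_rate, n, fs, amp) {
  t <- (seq_len(n) - 1) / fs
  t_hr <- (seq_along(hr) - 1) / numeric_rate
  f_c <- if (length(hr) == 1L) rep(hr / 60, n)
         else stats::approx(t_hr, hr / 60, xout = t, rule = 2)$y
  amp * sin(2 * pi * cumsum(f_c) / fs)
}

# Recompose the IP channel from simulator components.
rebuild_ip <- function(recording) {
  comp <- recording$components
  recording$ip <- comp$breathing + comp$cardiac * comp$cardiac_scale +
    comp$noise + comp$artefact
  recording
}

empty_intervals <- function(extra = character(0)) {
  cols <- c("start", "end", extra)
  df <- as.data.frame(matrix(numeric(0), nrow = 0, ncol = length(cols)))
  names(df) <- cols
  if ("kind" %in% extra) df$kind <- character(0)
  df
}

new_ground_truth <- function(breath_times, duration) {
  structure(list(
    breath_times = breath_times,
    pause_intervals = data.frame(start = numeric(0), end = numeric(0),
                                 kind = character(0),
                                 gap_start = numeric(0),
                                 gap_end = numeric(0),
                                 stringsAsFactors = FALSE),
    artefact_intervals = data.frame(start = numeric(0), end = numeric(0)),
    hr_events = data.frame(start = numeric(0), nadir = numeric(0)),
    spo2_events = data.frame(start = numeric(0), nadir = numeric(0)),
    duration = duration), class = "ground_truth")
}

#' @export
print.physio_recording <- function(x, ...) {
  cat(sprintf("physio_recording '%s': %.1f s, IP %.4g Hz (%d samples), numerics %.4g Hz\n",
              x$subject_id, x$duration, x$ip_rate, length(x$ip),
              x$numeric_rate))
  invisible(x)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: %d breaths, %d pauses, %d artefacts over %.1f s\n",
              length(x$breath_times), nrow(x$pause_intervals),
              nrow(x$artefact_intervals), x$duration))
  invisible(x)
}

pause_kinds <- c("pause", "apnoea-with-response", "apnoea-no-response",
                 "low-amplitude-false-alarm")

#' Inject a breathing pause or low-amplitude episode into a simulated recording
#'
#' For `kind = "apnoea-with-response"`, `"apnoea-no-response"` or `"pause"`
#' the breathing component is removed over the interval (the cardiac
#' component is retained at half its ratio, the noise floor stays) and the
#' ground-truth breath times inside the interval are deleted.  The
#' suppression gate is snapped outward to breath onsets (where the
#' breathing waveform is zero), so the cut is step-free and every retained
#' breath keeps its full lobe; the achieved breath-free gap is recorded in
#' the truth as `gap_start` / `gap_end` alongside the requested interval.  Apnoea kinds
#' must last at least 20 s; a plain `"pause"` may be any positive duration.
#' For `kind = "low-amplitude-false-alarm"` the breathing amplitude is
#' scaled to a small nonzero fraction (default 0.1) but the breaths remain in
#' the ground truth as present-yet-undetectable, emulating artefactually
#' low-amplitude signal from poor electrode placement or shallow breathing.
#'
#' Optional heart-rate and SpO2 responses carve raised-cosine dips reaching
#' the nadir 30 s after pause onset and recovering by 90 s.
#'
#' @param recording,truth Output of [simulate_recording()].
#' @param start,duration Pause placement, seconds.
#' @param kind One of `"pause"`, `"apnoea-with-response"`,
#'   `"apnoea-no-response"`, `"low-amplitude-false-alarm"`.
#' @param hr_response,spo2_response Optional nadirs (bpm / percent) for the
#'   physiological response.
#' @param low_amplitude_fraction Residual breathing amplitude for the
#'   low-amplitude kind.
#' @return Updated `list(recording, truth)`.
#' @export
inject_pause <- function(recording, truth, start, duration, kind,
                         hr_response = NULL, spo2_response = NULL,
                         low_amplitude_fraction = 0.1) {
  kind <- match.arg(kind, pause_kinds)
  if (duration <= 0) stopf("inject_pause: duration must be > 0")
  end <- start + duration
  if (start < 0 || end > recording$duration)
    stopf("inject_pause: interval [%.1f, %.1f] outside recording [0, %.1f]",
          start, end, recording$duration)
  if (startsWith(kind, "apnoea") && duration < 20)
    stopf("inject_pause: apnoea kinds require duration >= 20 s (got %.1f s)",
          duration)
  pi_df <- truth$pause_intervals
  if (nrow(pi_df) && any(intervals_overlap(start, end, pi_df$start, pi_df$end)))
    stopf("inject_pause: interval overlaps an existing pause")
  comp <- recording$components
  if (is.null(comp))
    stopf("inject_pause: recording lacks simulator components")

  n <- length(recording$ip)
  t <- (seq_len(n) - 1) / recording$ip_rate
  if (kind == "low-amplitude-false-alarm") {
    inside <- t >= start & t < end
    comp$breathing[inside] <- comp$breathing[inside] * low_amplitude_fraction
  } else {
    # snap the suppression gate to breath onsets (upward zero-crossings of
    # the breathing phase): the waveform is zero at both gate edges, so the
    # cut introduces no step, and every retained truth breath keeps its
    # full lobe -- a half-clipped breath would be in the truth yet
    # undetectable, corrupting the achieved gap boundaries
    bt <- truth$breath_times
    cand_s <- bt[bt >= start]
    gate_s <- if (length(cand_s)) min(cand_s) else start
    cand_e <- bt[bt >= end]
    gate_e <- if (length(cand_e)) min(cand_e) else end
    inside <- t >= gate_s & t < gate_e
    comp$breathing[inside] <- 0
    comp$cardiac_scale[inside] <- comp$cardiac_scale[inside] * 0.5
    truth$breath_times <- bt[bt < gate_s | bt >= gate_e]
  }
  recording$components <- comp

  # achieved breath-free gap (pause boundaries as a detector sees them)
  before <- truth$breath_times[truth$breath_times <= start]
  after <- truth$breath_times[truth$breath_times >= end]
  gap_start <- if (length(before)) max(before) else 0
  gap_end <- if (length(after)) min(after) else truth$duration
  if (kind == "low-amplitude-false-alarm") { gap_start <- start; gap_end <- end }
  truth$pause_intervals <- rbind(
    truth$pause_intervals,
    data.frame(start = start, end = end, kind = kind,
               gap_start = gap_start, gap_end = gap_end,
               stringsAsFactors = FALSE))

  if (!is.null(hr_response)) {
    tn <- (seq_along(recording$hr) - 1) / recording$numeric_rate
    dip <- raised_cosine_dip(tn - start)
    recording$hr <- pmin(recording$hr,
                         recording$hr - (recording$hr - hr_response) * dip)
    truth$hr_events <- rbind(truth$hr_events,
                             data.frame(start = start, nadir = hr_response))
    if (!is.null(recording$cardiac_amp))
      recording$components$cardiac <- cardiac_wave(
        recording$hr, recording$numeric_rate, n, recording$ip_rate,
        recording$cardiac_amp)
  }
  if (!is.null(spo2_response)) {
    tn <- (seq_along(recording$spo2) - 1) / recording$numeric_rate
    dip <- raised_cosine_dip(tn - start)
    recording$spo2 <- pmin(recording$spo2,
                           recording$spo2 -
                             (recording$spo2 - spo2_response) * dip)
    truth$spo2_events <- rbind(truth$spo2_events,
                               data.frame(start = start,
                                          nadir = spo2_response))
  }
  recording <- rebuild_ip(recording)
  list(recording = recording, truth = truth)
}

#' Inject a movement artefact into a simulated recording
#'
#' Adds a large low-frequency excursion (half-sine bump peaking at
#' `magnitude` times the breathing amplitude) over the interval, emulating
#' large-amplitude changes caused by movements of the infant, and appends the
#' interval to the ground-truth artefact list.
#'
#' @inheritParams inject_pause
#' @param magnitude Peak excursion in multiples of the breathing amplitude;
#'   must be >= 3 so the artefact is distinguishable from breathing.
#' @return Updated `list(recording, truth)`.
#' @export
inject_movement_artefact <- function(recording, truth, start, duration,
                                     magnitude) {
  if (magnitude < 3)
    stopf("inject_movement_artefact: magnitude must be >= 3 (got %.2f)",
          magnitude)
  if (duration <= 0) stopf("inject_movement_artefact: duration must be > 0")
  end <- start + duration
  if (start < 0 || end > recording$duration)
    stopf("inject_movement_artefact: interval [%.1f, %.1f] outside recording",
          start, end)
  ai <- truth$artefact_intervals
  if (nrow(ai) && any(intervals_overlap(start, end, ai$start, ai$end)))
    stopf("inject_movement_artefact: interval overlaps an existing artefact")
  comp <- recording$components
  if (is.null(comp))
    stopf("inject_movement_artefact: recording lacks simulator components")
  n <- length(recording$ip)
  t <- (seq_len(n) - 1) / recording$ip_rate
  amp0 <- max(abs(comp$breathing))
  if (amp0 == 0) amp0 <- 1
  inside <- t >= start & t <= end
  bump <- numeric(n)
  bump[inside] <- magnitude * amp0 * sin(pi * (t[inside] - start) / duration)
  comp$artefact <- comp$artefact + bump
  recording$components <- comp
  recording <- rebuild_ip(recording)
  truth$artefact_intervals <- rbind(ai, data.frame(start = start, end = end))
  list(recording = recording, truth = truth)
}

#' Crop a recording to a time window
#'
#' Slices all channels (and simulator components, if present) to
#' `[start, end)`, shifting `start_time` accordingly.  Used to carve
#' before/after epochs out of a long recording for [compare_epochs()].
#'
#' @param recording A `physio_recording`.
#' @param start,end Window in seconds relative to the recording start.
#' @return A `physio_recording` covering the window.
#' @export
crop_recording <- function(recording, start, end) {
  if (start < 0 || end > recording$duration || end <= start)
    stopf("crop_recording: invalid window [%.1f, %.1f]", start, end)
  i_ip <- which((seq_along(recording$ip) - 1) / recording$ip_rate >= start &
                  (seq_along(recording$ip) - 1) / recording$ip_rate < end)
  i_num <- which((seq_along(recording$hr) - 1) / recording$numeric_rate >=
                   start &
                 (seq_along(recording$hr) - 1) / recording$numeric_rate < end)
  comp <- recording$components
  if (!is.null(comp)) comp <- lapply(comp, function(v) v[i_ip])
  new_physio_recording(
    subject_id = recording$subject_id,
    ip = recording$ip[i_ip], ip_rate = recording$ip_rate,
    hr = recording$hr[i_num], spo2 = recording$spo2[i_num],
    numeric_rate = recording$numeric_rate,
    duration = end - start,
    start_time = recording$start_time + start,
    components = comp)
}

#' Simulate an apnoea-classifier feature set
#'
#' Draws two multivariate-Gaussian classes in the five-dimensional feature
#' space used by the apnoea classifier (RMS of the filtered IP during / 10 s
#' before / 10 s after the episode, and the 60 s changes in heart rate and
#' SpO2).  True apnoeas have low `rms_during`, non-low `rms_pre10` /
#' `rms_post10` and negative HR/SpO2 deltas; false alarms have uniformly low
#' RMS and deltas near zero.  The Mahalanobis distance between the class
#' means equals `separation`, so `separation = 0` gives indistinguishable
#' classes.  Subjects are assigned round-robin for leave-one-subject-out
#' evaluation.
#'
#' @param n_true,n_false Episode counts per class (>= 1).
#' @param separation Class-mean Mahalanobis distance (dimensionless).
#' @param seed Integer seed.
#' @param n_subjects Number of subjects for the round-robin assignment.
#' @return A list: `features` (data frame, 5 columns), `labels` (factor with
#'   levels `apnoea`, `false_alarm`), `subject_ids` (character).
#' @export
simulate_feature_set <- function(n_true, n_false, separation, seed = 1L,
                                 n_subjects = 15L) {
  if (n_true < 1 || n_false < 1)
    stopf("simulate_feature_set: n_true and n_false must be >= 1")
  if (separation < 0) stopf("simulate_feature_set: separation must be >= 0")
  feat_names <- c("rms_during", "rms_pre10", "rms_post10", "delta_hr60",
                  "delta_spo2_60")
  # canonical class structure in physical units
  mu_true0 <- c(0.05, 0.80, 0.80, -40, -15)
  mu_false0 <- c(0.15, 0.15, 0.15, 0, 0)
  sigma <- c(0.05, 0.15, 0.15, 8, 4)
  d <- mu_true0 - mu_false0
  s0 <- sqrt(sum((d / sigma)^2))
  # the false-alarm class sits at its canonical means; the true-apnoea
  # class moves away along the canonical direction as separation grows
  shift <- (separation / s0) * d
  with_seed(seed, {
    n <- n_true + n_false
    z <- matrix(stats::rnorm(n * 5), n, 5)
    lab <- rep(c("apnoea", "false_alarm"), c(n_true, n_false))
    mu <- matrix(mu_false0, n, 5, byrow = TRUE) +
      outer(as.numeric(lab == "apnoea"), shift)
    x <- mu + z %*% diag(sigma)
    x[, 1:3] <- pmax(x[, 1:3], 0)  # RMS features are nonnegative
    colnames(x) <- feat_names
    list(features = as.data.frame(x),
         labels = factor(lab, levels = c("apnoea", "false_alarm")),
         subject_ids = sprintf("S%02d",
                               rep_len(seq_len(n_subjects), n)))
  })
}
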