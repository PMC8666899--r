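# Shared fixtures and independent reference implementations used as
# oracles.  Everything here is deliberately naive: straight transcriptions
# of definitions, recomputed from scratch, with no shared code paths with
# the package internals they check.

quiet_cfg <- function(...) {
  simulation_config(breath_rate_jitter = 0, amplitude_drift = 0,
                    cardiac_amplitude_ratio = 0, noise_sd = 0, ...)
}

# An ibi_series built directly from a vector of interval durations.
make_ibis <- function(durations, valid = TRUE) {
  start <- c(0, cumsum(durations))[seq_along(durations)]
  structure(list(intervals = data.frame(
    start = start, end = start + durations, duration = durations,
    valid = rep_len(valid, length(durations)))), class = "ibi_series")
}

# A plain filtered_ip wrapper around a raw vector (no preprocessing).
as_filtered <- function(x, rate, mask = NULL) {
  structure(list(signal = x, rate = rate,
                 mask = if (is.null(mask)) logical(length(x)) else mask,
                 cardiac_freq_trace = rep(2.5, length(x))),
            class = "filtered_ip")
}

# Amplitude of the `freq` component of `x` by direct projection onto the
# complex exponential (independent of any package FFT helper).
tone_amplitude <- function(x, rate, freq) {
  n <- length(x)
  t <- (0:(n - 1)) / rate
  2 * Mod(sum(x * exp(-2i * pi * freq * t))) / n
}

# Brute-force confusion-matrix metrics from first principles.
ref_metrics <- function(pred, act, positive) {
  tp <- 0; fp <- 0; fn <- 0; tn <- 0
  for (i in seq_along(pred)) {
    if (pred[i] == positive && act[i] == positive) tp <- tp + 1
    if (pred[i] == positive && act[i] != positive) fp <- fp + 1
    if (pred[i] != positive && act[i] == positive) fn <- fn + 1
    if (pred[i] != positive && act[i] != positive) tn <- tn + 1
  }
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  list(accuracy = (tp + tn) / (tp + fp + fn + tn),
       fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
       fnr = if (fn + tp > 0) fn / (fn + tp) else NA_real_,
       mcc = if (den == 0) 0 else (tp * tn - fp * fn) / den)
}

# Hochberg step-up recursion written directly from its definition:
# starting from the largest p, adj_(i) = min(adj_(i+1), (m - i + 1) p_(i)).
ref_hochberg <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- numeric(m)
  prev <- Inf
  for (r in seq_len(m)) {       # r-th largest
    i <- m - r + 1              # rank from the smallest
    a <- min(prev, (m - i + 1) * p[o[r]], 1)
    adj[o[r]] <- a
    prev <- a
  }
  adj
}

# Per-sample brute-force re-implementation of the adaptive threshold
# detector.  At every sample the SD window is recomputed from scratch; the
# detection rules (upward crossing, re-arm below zero, refractory,
# suspension in masked spans) are transcribed independently.
ref_detect_breaths <- function(x, fs, mask = NULL, alpha = 0.4, N = 15,
                               refractory = 0.3, init_window = 15) {
  n <- length(x)
  if (is.null(mask)) mask <- rep(FALSE, n)
  init_n <- round(init_window * fs)
  breaths <- integer(0)
  armed <- TRUE
  thr_at_sample <- numeric(n)
  for (i in 1:n) {
    # threshold in force: recomputed from scratch from the breaths so far
    nb <- length(breaths)
    if (nb == 0) {
      w <- x[1:init_n][!mask[1:init_n]]
    } else if (nb < N) {
      last <- breaths[nb]
      w <- x[max(1, last - init_n + 1):last]
      w <- w[!mask[max(1, last - init_n + 1):last]]
    } else {
      i1 <- breaths[nb - N + 1]
      w <- x[i1:breaths[nb]][!mask[i1:breaths[nb]]]
    }
    thr <- if (length(w) >= 2 && is.finite(stats::sd(w)))
      alpha * stats::sd(w) else Inf
    thr_at_sample[i] <- thr
    if (mask[i]) next
    if (!armed) {
      if (x[i] < 0) armed <- TRUE
    } else if (x[i] > thr) {
      armed <- FALSE
      if (nb == 0 || (i - breaths[nb]) / fs >= refractory)
        breaths <- c(breaths, i)
    }
  }
  list(times = (breaths - 1) / fs, thr = thr_at_sample)
}

# Greedy one-to-one matching of detected to true event times.
match_events <- function(detected, truth, tol = 0.25) {
  used <- rep(FALSE, length(truth))
  hit <- rep(FALSE, length(detected))
  for (i in seq_along(detected)) {
    d <- abs(truth - detected[i])
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= tol) {
      used[j] <- TRUE
      hit[i] <- TRUE
    }
  }
  list(sensitivity = mean(used), fdr = 1 - mean(hit))
}
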