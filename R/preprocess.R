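#' Preprocessing parameters
#'
#' Tunables for [preprocess()]: the first pipeline stage, which removes
#' movement artefacts and cardiac-frequency noise from the IP signal and
#' zeroes it.
#'
#' @param baseline_cutoff_hz Baseline-removal cutoff, Hz: all spectral
#'   content below this frequency (including DC) is removed.
#' @param k_mad Artefact threshold in multiples of the rolling MAD-based
#'   scale.
#' @param mask_window_s Rolling window for the robust scale estimate, s.
#' @param mask_pad_s Dilation of the artefact mask each side, s.
#' @param notch_halfwidth_hz Half-width of the cardiac notch, Hz.
#' @param notch_frame_s STFT frame length for the time-varying notch, s.
#' @return A validated `preprocess_params` list.
#' @export
preprocess_params <- function(baseline_cutoff_hz = 0.1, k_mad = 6,
                              mask_window_s = 20, mask_pad_s = 0.5,
                              notch_halfwidth_hz = 0.3, notch_frame_s = 32) {
  p <- list(baseline_cutoff_hz = baseline_cutoff_hz, k_mad = k_mad,
            mask_window_s = mask_window_s, mask_pad_s = mask_pad_s,
            notch_halfwidth_hz = notch_halfwidth_hz,
            notch_frame_s = notch_frame_s)
  for (f in names(p))
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || !is.finite(p[[f]]) ||
        p[[f]] <= 0)
      stopf("preprocess_params: field '%s' must be a positive number", f)
  structure(p, class = "preprocess_params")
}

#' Mask movement artefacts in an IP signal
#'
#' Flags samples whose magnitude, after running-median baseline removal,
#' exceeds `k_mad` times a rolling MAD-based scale.  The scale is estimated
#' in two passes: samples flagged by the first pass are excluded from the
#' second scale estimate, so long large artefacts cannot inflate their own
#' threshold.  Each flagged excursion is grown outward through samples above
#' a third of the threshold (dual-threshold hysteresis), so the full extent
#' of an artefact is masked rather than only its core, and the mask is
#' dilated by `pad` seconds each side.  The mask is monotone in `k_mad`: a
#' larger `k_mad` always yields a subset mask.
#'
#' @param ip Numeric IP signal.
#' @param rate Sampling rate, Hz.
#' @param k_mad Threshold in multiples of the robust scale (> 0).
#' @param pad Mask dilation, seconds each side.
#' @param window Rolling window for the scale estimate, seconds.
#' @return Logical mask, `TRUE` = unusable sample.
#' @export
mask_artefacts <- function(ip, rate, k_mad = 6, pad = 0.5, window = 20) {
  if (k_mad <= 0) stopf("mask_artefacts: k_mad must be > 0")
  n <- length(ip)
  if (n == 0L) return(logical(0))
  # baseline: running median over `window` seconds (slow drift only)
  k <- min(2L * floor(window * rate / 2L) + 1L, 2L * floor((n - 1) / 2) + 1L)
  base <- if (k >= 3) stats::runmed(ip, k, endrule = "median") else ip * 0
  resid <- ip - base
  # floor the rolling scale at half the recording-wide MAD: genuinely quiet
  # spans (apnoeas, shallow breathing) are low-amplitude signal, not
  # artefact, and must not shrink the scale until neighbouring breaths
  # look like outliers
  floor_scale <- 0.5 * stats::mad(resid)
  scale1 <- pmax(rolling_mad(resid, rate, window), floor_scale)
  mask1 <- scale1 > 0 & abs(resid) > k_mad * scale1
  scale2 <- pmax(rolling_mad(resid, rate, window,
                             exclude = dilate_mask(mask1, round(pad * rate))),
                 floor_scale)
  strong <- scale2 > 0 & abs(resid) > k_mad * scale2
  # dual-threshold hysteresis: grow each strong excursion outward through
  # samples above a third of the threshold (still far above breathing
  # amplitude), so the full extent of an artefact is masked, not just its
  # core
  weak <- scale2 > 0 & abs(resid) > k_mad / 3 * scale2
  mask <- weak_runs_with_strong(weak, strong)
  dilate_mask(mask, round(pad * rate))
}

# Keep the runs of `weak` that contain at least one `strong` sample.
weak_runs_with_strong <- function(weak, strong) {
  if (!any(strong)) return(logical(length(weak)))
  r <- rle(weak)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  scs <- c(0L, cumsum(as.integer(strong)))
  has_strong <- (scs[ends + 1L] - scs[starts]) > 0L
  inverse.rle(list(lengths = r$lengths, values = r$values & has_strong))
}

# Rolling MAD of `x` over `window` seconds, evaluated on a coarse grid
# (hop window/40) and linearly interpolated back to every sample.  Samples
# flagged in `exclude` do not contribute to the estimate.
rolling_mad <- function(x, rate, window, exclude = NULL) {
  n <- length(x)
  half <- max(1L, round(window * rate / 2))
  hop <- max(1L, round(window * rate / 40))
  centers <- unique(c(seq(1L, n, by = hop), n))
  vals <- vapply(centers, function(c0) {
    i1 <- max(1L, c0 - half); i2 <- min(n, c0 + half)
    v <- x[i1:i2]
    if (!is.null(exclude)) v <- v[!exclude[i1:i2]]
    if (length(v) < 8L) return(NA_real_)
    stats::mad(v)
  }, numeric(1))
  if (all(is.na(vals))) return(numeric(n))
  vals <- stats::approx(centers[!is.na(vals)], vals[!is.na(vals)],
                        xout = centers, rule = 2)$y
  stats::approx(centers, vals, xout = seq_len(n), rule = 2)$y
}

#' Zero the baseline of an IP signal
#'
#' Removes all spectral content below `cutoff` (including DC) by zeroing the
#' corresponding Fourier bins.  Because bin-zeroing is an orthogonal
#' projection, the operation is exactly idempotent and rejects constant
#' offsets completely; content well above the cutoff passes unchanged.
#'
#' @param ip Numeric signal.
#' @param rate Sampling rate, Hz.
#' @param cutoff Cutoff frequency, Hz; must satisfy `0 < cutoff < rate/2`.
#' @return The zero-baselined signal (same length).
#' @export
zero_baseline <- function(ip, rate, cutoff = 0.1) {
  if (cutoff <= 0 || cutoff >= rate / 2)
    stopf("zero_baseline: cutoff must lie in (0, rate/2)")
  n <- length(ip)
  if (n < 2L) return(ip * 0)
  f <- bin_freqs(n, rate)
  X <- stats::fft(ip)
  X[abs(f) < cutoff] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

# Signed frequency of each FFT bin of an n-point transform at `rate` Hz.
bin_freqs <- function(n, rate) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k * rate / n
}

#' Estimate the instantaneous cardiac frequency
#'
#' Returns a per-IP-sample trace of the cardiac frequency in Hz, used to
#' steer the cardiac notch.  Where the heart-rate numeric is present it is
#' simply `hr / 60` interpolated to the IP timebase; where it is absent the
#' frequency is taken as the short-time spectral peak of the IP signal
#' restricted to the 1.5-4.5 Hz band.  The trace is clipped to
#' `[1.5, 4.5]` Hz, the plausible neonatal cardiac band.
#'
#' @param hr Heart-rate numeric (bpm), possibly containing `NA`, or `NULL`.
#' @param hr_rate Sampling rate of `hr`, Hz.
#' @param ip IP signal (used when `hr` is absent), or `NULL`.
#' @param ip_rate IP sampling rate, Hz.
#' @param n_out Length of the returned trace (defaults to `length(ip)`).
#' @return Numeric trace of length `n_out`, in Hz.
#' @export
estimate_cardiac_frequency <- function(hr = NULL, hr_rate = 1, ip = NULL,
                                       ip_rate = NULL,
                                       n_out = length(ip)) {
  have_hr <- !is.null(hr) && any(is.finite(hr))
  have_ip <- !is.null(ip) && length(ip) > 0
  if (!have_hr && !have_ip)
    stopf("estimate_cardiac_frequency: both HR and IP channels are empty")
  if (n_out == 0L && have_ip) n_out <- length(ip)
  if (have_hr) {
    t_hr <- (seq_along(hr) - 1) / hr_rate
    ok <- is.finite(hr)
    dur <- if (have_ip) length(ip) / ip_rate else max(t_hr) + 1 / hr_rate
    t_out <- seq(0, dur, length.out = n_out + 1L)[seq_len(n_out)]
    tr <- if (sum(ok) == 1L) rep(hr[ok] / 60, n_out)
          else stats::approx(t_hr[ok], hr[ok] / 60, xout = t_out,
                             rule = 2)$y
    return(pmin(pmax(tr, 1.5), 4.5))
  }
  # HR absent: short-time spectral peak of the IP in the cardiac band
  fs <- ip_rate
  n <- length(ip)
  frame <- min(n, max(16L, round(30 * fs)))
  hop <- max(1L, frame %/% 2L)
  starts <- unique(c(seq(1L, max(1L, n - frame + 1L), by = hop),
                     max(1L, n - frame + 1L)))
  f <- bin_freqs(frame, fs)
  band <- which(f >= 1.5 & f <= 4.5)
  if (!length(band))
    stopf("estimate_cardiac_frequency: IP rate too low to resolve the cardiac band")
  ctrs <- numeric(length(starts)); vals <- numeric(length(starts))
  for (j in seq_along(starts)) {
    seg <- ip[starts[j]:(starts[j] + frame - 1L)]
    spec <- Mod(stats::fft(seg - mean(seg)))^2
    vals[j] <- f[band[which.max(spec[band])]]
    ctrs[j] <- starts[j] + (frame - 1) / 2
  }
  tr <- if (length(starts) == 1L) rep(vals, n)
        else stats::approx(ctrs, vals, xout = seq_len(n), rule = 2)$y
  tr <- pmin(pmax(tr, 1.5), 4.5)
  if (n_out != n)
    tr <- stats::approx(seq_len(n), tr, xout = seq(1, n,
                                                   length.out = n_out),
                        rule = 2)$y
  tr
}

#' Remove cardiac-frequency noise from an IP signal
#'
#' Applies a time-varying spectral notch centred on the instantaneous
#' cardiac frequency.  The signal is processed in overlapping Hann-windowed
#' frames (constant-overlap-add at 50% hop); in each frame the Fourier bins
#' within `halfwidth` of the frame's cardiac frequency (plus the window's
#' spectral mainlobe width) are zeroed.  Power within `halfwidth` of the
#' cardiac frequency is suppressed by well over 20 dB while the breathing
#' band below ~1.2 Hz is left essentially untouched.
#'
#' @param ip Numeric signal.
#' @param rate Sampling rate, Hz.
#' @param cardiac_freq_trace Per-sample cardiac frequency, Hz (same length
#'   as `ip`).
#' @param halfwidth Notch half-width, Hz.
#' @param frame_s Frame length, seconds (frequency resolution of the notch).
#' @return The notch-filtered signal (same length).
#' @export
remove_cardiac_noise <- function(ip, rate, cardiac_freq_trace,
                                 halfwidth = 0.3, frame_s = 32) {
  n <- length(ip)
  if (length(cardiac_freq_trace) != n)
    stopf("remove_cardiac_noise: trace length (%d) != signal length (%d)",
          length(cardiac_freq_trace), n)
  if (n == 0L) return(ip)
  frame <- 2L * floor(frame_s * rate / 2)
  if (n <= frame) {
    # short signal: single whole-signal notch
    f0 <- stats::median(cardiac_freq_trace)
    f <- bin_freqs(n, rate)
    X <- stats::fft(ip)
    X[abs(abs(f) - f0) <= halfwidth + 2 * rate / n] <- 0
    return(Re(stats::fft(X, inverse = TRUE)) / n)
  }
  hop <- frame %/% 2L
  # reflect-pad by one hop each side so every original sample is covered by
  # two Hann frames (their windows summing to 1)
  xp <- c(rev(ip[2:(hop + 1L)]), ip, rev(ip[(n - hop):(n - 1L)]))
  trp <- c(rev(cardiac_freq_trace[2:(hop + 1L)]), cardiac_freq_trace,
           rev(cardiac_freq_trace[(n - hop):(n - 1L)]))
  np <- length(xp)
  win <- 0.5 - 0.5 * cos(2 * pi * (0:(frame - 1L)) / frame)  # periodic Hann
  f <- bin_freqs(frame, rate)
  mainlobe <- 2 * rate / frame
  out <- numeric(np + frame)
  starts <- seq(1L, np, by = hop)
  for (s in starts) {
    idx <- s:(s + frame - 1L)
    seg <- ifelse(idx <= np, xp[pmin(idx, np)], 0)
    f0 <- stats::median(trp[idx[idx <= np]])
    X <- stats::fft(seg * win)
    X[abs(abs(f) - f0) <= halfwidth + mainlobe] <- 0
    out[idx] <- out[idx] + Re(stats::fft(X, inverse = TRUE)) / frame
  }
  out[(hop + 1L):(hop + n)]
}

#' Preprocess a recording into a filtered IP signal
#'
#' Runs the first pipeline stage on a `physio_recording`: movement-artefact
#' masking, baseline zeroing, cardiac-frequency estimation and the
#' time-varying cardiac notch.  Masked spans are bridged by linear
#' interpolation before the spectral filters are applied (so a large
#' artefact cannot leak across the whole spectrum) and are set to zero in
#' the output signal; they are excluded from all downstream SD/RMS
#' computations via the mask.  The returned signal has zero mean over the
#' unmasked samples.
#'
#' @param recording A `physio_recording`.
#' @param params A [preprocess_params()] object.
#' @return A `filtered_ip` object: `signal`, `rate`, `mask` (per-sample
#'   logical, `TRUE` = unusable), `cardiac_freq_trace` (Hz).
#' @export
preprocess <- function(recording, params = preprocess_params()) {
  if (!inherits(recording, "physio_recording"))
    stopf("preprocess: expected a physio_recording")
  n <- length(recording$ip)
  if (n == 0L) stopf("preprocess: recording has zero-length IP channel")
  fs <- recording$ip_rate
  mask <- mask_artefacts(recording$ip, fs, k_mad = params$k_mad,
                         pad = params$mask_pad_s,
                         window = params$mask_window_s)
  x <- recording$ip
  if (any(mask) && !all(mask)) {
    idx <- seq_len(n)
    x[mask] <- stats::approx(idx[!mask], x[!mask], xout = idx[mask],
                             rule = 2)$y
  }
  x <- zero_baseline(x, fs, params$baseline_cutoff_hz)
  trace <- estimate_cardiac_frequency(hr = recording$hr,
                                      hr_rate = recording$numeric_rate,
                                      ip = x, ip_rate = fs, n_out = n)
  x <- remove_cardiac_noise(x, fs, trace,
                            halfwidth = params$notch_halfwidth_hz,
                            frame_s = params$notch_frame_s)
  if (!all(mask)) {
    x <- x - mean(x[!mask])   # exact zero mean over usable samples
    x[mask] <- 0
  }
  structure(list(signal = x, rate = fs, mask = mask,
                 cardiac_freq_trace = trace,
                 subject_id = recording$subject_id),
            class = "filtered_ip")
}

#' @export
print.filtered_ip <- function(x, ...) {
  cat(sprintf("filtered_ip: %d samples at %.4g Hz, %.1f%% masked, cardiac %.2f-%.2f Hz\n",
              length(x$signal), x$rate, 100 * mean(x$mask),
              min(x$cardiac_freq_trace), max(x$cardiac_freq_trace)))
  invisible(x)
}
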