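#' Adaptive-threshold parameters
#'
#' Parameters of the adaptive amplitude threshold used by
#' [detect_breaths()].  The threshold is `alpha` times the SD of the
#' filtered IP signal over the span of the previous `n_breaths` detected
#' breaths; the defaults (`alpha = 0.4`, `n_breaths = 15`) are the operating
#' point at which breath-detection false positives and false negatives are
#' best balanced.
#'
#' @param alpha Threshold multiplier (dimensionless, > 0).
#' @param n_breaths Number of previous breaths whose span defines the SD
#'   window (>= 1).
#' @param refractory Minimum spacing between detected breaths, s (> 0);
#'   guards against residual cardiac oscillation double-triggering.
#' @param init_window Bootstrap window, s: until `n_breaths` breaths have
#'   accumulated, the SD is computed over this much trailing signal.
#' @return A validated `threshold_params` list.
#' @export
threshold_params <- function(alpha = 0.4, n_breaths = 15, refractory = 0.3,
                             init_window = 15) {
  p <- list(alpha = alpha, n_breaths = as.integer(n_breaths),
            refractory = refractory, init_window = init_window)
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0)
    stopf("threshold_params: alpha must be > 0")
  if (is.na(p$n_breaths) || p$n_breaths < 1L)
    stopf("threshold_params: n_breaths must be >= 1")
  if (!is.numeric(refractory) || refractory <= 0)
    stopf("threshold_params: refractory must be > 0")
  if (!is.numeric(init_window) || init_window <= 0)
    stopf("threshold_params: init_window must be > 0")
  structure(p, class = "threshold_params")
}

#' Detect breaths by adaptive threshold crossing
#'
#' A breath is the point at which the filtered IP signal crosses the current
#' threshold upward: one breath per excursion above the threshold, where the
#' zero-centred signal must return below zero before the next excursion can
#' count (hysteresis, so noise chatter around the threshold cannot
#' double-count a breath).  Crossings within `refractory` seconds of the
#' last accepted breath are discarded.  After each accepted breath the
#' threshold is recomputed as `alpha` times the SD of the non-masked
#' filtered signal spanning the most recent `n_breaths` detected breaths
#' (before that many breaths exist, the SD is taken over the trailing
#' `init_window` seconds).  During masked artefact spans detection is
#' suspended and the threshold frozen, so artefacts neither produce breaths
#' nor corrupt the adaptive threshold.
#'
#' @param filtered A `filtered_ip` from [preprocess()] (or any list with
#'   `signal`, `rate` and optionally `mask`).
#' @param params A [threshold_params()] object.
#' @return A `breath_train`: `breath_times` (s), `threshold_trace`
#'   (per-sample threshold in force), `rate`, `duration`.
#' @export
detect_breaths <- function(filtered, params = threshold_params()) {
  x <- filtered$signal
  fs <- filtered$rate
  mask <- filtered$mask %||% logical(length(x))
  n <- length(x)
  if (n / fs < params$init_window)
    stopf("detect_breaths: signal (%.1f s) shorter than init_window (%.1f s)",
          n / fs, params$init_window)
  alpha <- params$alpha
  N <- params$n_breaths
  refr <- params$refractory
  init_n <- round(params$init_window * fs)

  sd_span <- function(i1, i2) {
    v <- x[i1:i2][!mask[i1:i2]]
    if (length(v) < 2L) return(NA_real_)
    stats::sd(v)
  }

  s0 <- sd_span(1L, init_n)
  thr <- if (is.finite(s0)) alpha * s0 else Inf
  trace <- numeric(n)
  breaths_i <- integer(0)
  armed <- TRUE
  for (i in seq_len(n)) {
    trace[i] <- thr
    if (mask[i]) next
    if (!armed) {
      # hysteresis: re-arm only once the signal returns below zero, so
      # noise chatter around the threshold cannot double-count a breath
      if (x[i] < 0) armed <- TRUE
    } else if (x[i] > thr) {
      armed <- FALSE  # one breath per excursion above threshold
      t_i <- (i - 1L) / fs
      nb <- length(breaths_i)
      if (nb == 0L || t_i - (breaths_i[nb] - 1L) / fs >= refr) {
        breaths_i <- c(breaths_i, i)
        nb <- nb + 1L
        i1 <- if (nb >= N) breaths_i[nb - N + 1L] else max(1L, i - init_n + 1L)
        s <- sd_span(i1, i)
        if (is.finite(s)) thr <- alpha * s
      }
    }
  }
  structure(list(breath_times = (breaths_i - 1L) / fs,
                 threshold_trace = trace, rate = fs, duration = n / fs,
                 subject_id = filtered$subject_id),
            class = "breath_train")
}

#' @export
print.breath_train <- function(x, ...) {
  cat(sprintf("breath_train: %d breaths over %.1f s (mean rate %.1f breaths/min)\n",
              length(x$breath_times), x$duration,
              60 * length(x$breath_times) / x$duration))
  invisible(x)
}

#' Compute interbreath intervals
#'
#' One interval per consecutive pair of detected breaths.  An interval is
#' flagged invalid when artefact-masked samples cover more than
#' `max_artefact_overlap` of it: a prolonged loss of signal due to artefacts
#' must not masquerade as a true pause in breathing.  Invalid intervals are
#' excluded from all distribution statistics and from pause/apnoea
#' extraction.
#'
#' @param train A `breath_train` from [detect_breaths()].
#' @param filtered The `filtered_ip` whose mask applies, or `NULL` (all
#'   intervals valid).
#' @param max_artefact_overlap Maximal tolerated masked fraction per
#'   interval.
#' @return An `ibi_series`: data frame `intervals` with columns `start`,
#'   `end`, `duration`, `valid`.
#' @export
compute_ibis <- function(train, filtered = NULL, max_artefact_overlap = 0.1) {
  bt <- train$breath_times
  if (length(bt) == 0L)
    return(structure(list(intervals = data.frame(start = numeric(0),
                                                 end = numeric(0),
                                                 duration = numeric(0),
                                                 valid = logical(0))),
                     class = "ibi_series"))
  if (length(bt) < 2L)
    stopf("compute_ibis: need at least two breaths")
  start <- bt[-length(bt)]
  end <- bt[-1L]
  valid <- rep(TRUE, length(start))
  if (!is.null(filtered) && any(filtered$mask)) {
    fs <- filtered$rate
    mcs <- c(0L, cumsum(as.integer(filtered$mask)))
    i1 <- pmax(1L, floor(start * fs) + 1L)
    i2 <- pmin(length(filtered$mask), floor(end * fs) + 1L)
    frac <- (mcs[i2 + 1L] - mcs[i1]) / pmax(i2 - i1 + 1L, 1L)
    valid <- frac <= max_artefact_overlap
  }
  structure(list(intervals = data.frame(start = start, end = end,
                                        duration = end - start,
                                        valid = valid),
                 subject_id = train$subject_id),
            class = "ibi_series")
}

#' @export
print.ibi_series <- function(x, ...) {
  iv <- x$intervals
  cat(sprintf("ibi_series: %d intervals (%d valid), durations %.2f-%.2f s\n",
              nrow(iv), sum(iv$valid),
              if (nrow(iv)) min(iv$duration) else NA,
              if (nrow(iv)) max(iv$duration) else NA))
  invisible(x)
}

#' Extract pauses in breathing
#'
#' Valid interbreath intervals at least `min_duration` long, in recording
#' order.  `min_duration = 5` gives the pauses-in-breathing set;
#' `min_duration = 20` gives the candidate central apnoeas.
#'
#' @param ibis An `ibi_series`.
#' @param min_duration Minimal duration, s (> 0).
#' @return Data frame with columns `start`, `end`, `duration`.
#' @export
detect_pauses <- function(ibis, min_duration = 5) {
  if (min_duration <= 0) stopf("detect_pauses: min_duration must be > 0")
  iv <- ibis$intervals
  iv <- iv[iv$valid & iv$duration >= min_duration,
           c("start", "end", "duration"), drop = FALSE]
  rownames(iv) <- NULL
  iv
}

#' Respiratory-rate trace from detected breaths
#'
#' Rate at each step is `60 *` (number of breaths in the trailing window)
#' `/ window`, in breaths per minute; zero where the window contains no
#' breaths.
#'
#' @param train A `breath_train`.
#' @param window Trailing window length, s (> 0).
#' @param step Evaluation step, s.
#' @return Data frame with columns `time` (s) and `rate` (breaths/min).
#' @export
respiratory_rate <- function(train, window = 30, step = 1) {
  if (window <= 0) stopf("respiratory_rate: window must be > 0")
  times <- seq(step, train$duration, by = step)
  bt <- sort(train$breath_times)
  if (length(bt) == 0L)
    return(data.frame(time = times, rate = numeric(length(times))))
  # breaths in (t - window, t]; during warm-up (t < window) normalise by
  # the elapsed time so the trace is not biased low
  counts <- findInterval(times, bt) - findInterval(times - window, bt)
  data.frame(time = times, rate = 60 * counts / pmin(times, window))
}
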