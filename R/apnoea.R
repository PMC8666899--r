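#' Extract candidate central apnoeas
#'
#' Candidate apnoeas are valid interbreath intervals of at least
#' `threshold` seconds (20 s by default).  These include both true central
#' apnoeas and artefactually low-amplitude episodes; separating the two is
#' the job of the classifier ([train_classifier()]).
#'
#' @param ibis An `ibi_series` from [compute_ibis()].
#' @param threshold Minimal IBI duration, s.
#' @return Data frame with columns `subject_id`, `start`, `end`, `duration`.
#' @export
extract_candidates <- function(ibis, threshold = 20) {
  cand <- detect_pauses(ibis, min_duration = threshold)
  data.frame(subject_id = rep(ibis$subject_id %||% NA_character_,
                              nrow(cand)),
             cand, stringsAsFactors = FALSE)
}

#' Extract classifier features for a candidate apnoea
#'
#' The five features of the apnoea/false-alarm classifier: the RMS of the
#' filtered IP signal during the episode, in the 10 s before it and in the
#' 10 s after it (masked samples excluded), and the signed changes in heart
#' rate and oxygen saturation over the 60 s from the episode onset.  The
#' change is the window minimum minus the median over the 10 s before
#' onset, so a bradycardia or desaturation gives a negative delta whose
#' magnitude is the depth of the dip.
#'
#' A feature whose window is less than half covered by usable data is
#' returned as `NA` and the candidate is flagged `missing`; such candidates
#' are excluded from training and classified as indeterminate.
#'
#' @param candidate One-row data frame (or list) with `start` and `end`, s.
#' @param filtered The subject's `filtered_ip`.
#' @param hr,spo2 Numeric channels (bpm / percent).
#' @param numeric_rate Sampling rate of `hr` and `spo2`, Hz.
#' @param pre_window,post_window IP context windows, s.
#' @param response_window HR/SpO2 response window from onset, s.
#' @return One-row data frame: `rms_during`, `rms_pre10`, `rms_post10`,
#'   `delta_hr60`, `delta_spo2_60`, `missing`.
#' @export
extract_features <- function(candidate, filtered, hr, spo2,
                             numeric_rate = 1, pre_window = 10,
                             post_window = 10, response_window = 60) {
  start <- candidate$start
  end <- candidate$end
  dur_sig <- length(filtered$signal) / filtered$rate
  dur_num <- length(hr) / numeric_rate

  rms_win <- function(a, b) {
    i1 <- max(1L, floor(a * filtered$rate) + 1L)
    i2 <- min(length(filtered$signal), floor(b * filtered$rate))
    want <- round((b - a) * filtered$rate)
    if (i2 < i1) return(NA_real_)
    idx <- i1:i2
    idx <- idx[!filtered$mask[idx]]
    if (length(idx) < want / 2) return(NA_real_)
    sqrt(mean(filtered$signal[idx]^2))
  }
  num_win <- function(ch, a, b) {
    i1 <- max(1L, floor(a * numeric_rate) + 1L)
    i2 <- min(length(ch), floor(b * numeric_rate) + 1L)
    want <- (b - a) * numeric_rate
    if (i2 < i1) return(NULL)
    v <- ch[i1:i2]
    v <- v[is.finite(v)]
    if (length(v) < want / 2) return(NULL)
    v
  }
  delta_ch <- function(ch) {
    base <- num_win(ch, start - pre_window, start)
    resp <- num_win(ch, start, start + response_window)
    if (is.null(base) || is.null(resp)) return(NA_real_)
    min(resp) - stats::median(base)
  }

  out <- data.frame(
    rms_during = rms_win(start, end),
    rms_pre10 = if (start - pre_window < -pre_window / 2) NA_real_
                else rms_win(max(0, start - pre_window), start),
    rms_post10 = if (end + post_window > dur_sig + post_window / 2) NA_real_
                 else rms_win(end, min(dur_sig, end + post_window)),
    delta_hr60 = delta_ch(hr),
    delta_spo2_60 = delta_ch(spo2))
  out$missing <- any(is.na(out))
  out
}

#' Extract features for all candidates in a recording
#'
#' Convenience wrapper applying [extract_features()] to every row of a
#' candidate table.
#'
#' @param candidates Data frame from [extract_candidates()].
#' @param filtered,hr,spo2,numeric_rate,... Passed to [extract_features()].
#' @return Data frame: candidate columns plus the five features and
#'   `missing`.
#' @export
extract_features_all <- function(candidates, filtered, hr, spo2,
                                 numeric_rate = 1, ...) {
  if (nrow(candidates) == 0L) {
    out <- cbind(candidates,
                 data.frame(rms_during = numeric(0), rms_pre10 = numeric(0),
                            rms_post10 = numeric(0), delta_hr60 = numeric(0),
                            delta_spo2_60 = numeric(0), missing = logical(0)))
    return(out)
  }
  feats <- do.call(rbind, lapply(seq_len(nrow(candidates)), function(i)
    extract_features(candidates[i, ], filtered, hr, spo2,
                     numeric_rate = numeric_rate, ...)))
  cbind(candidates, feats)
}

#' Flag bradycardia and desaturation co-occurrence for pauses
#'
#' Each pause is flagged `bradycardia = TRUE` if the heart rate falls below
#' 100 bpm at any point from the pause start to 60 s past its end, and
#' `desaturation = TRUE` if SpO2 falls below 80% likewise.  Prolonged pauses
#' accompanied by both are the episodes of greatest clinical concern.
#'
#' @param pauses Data frame with `start` and `end` columns, s.
#' @param hr,spo2 Numeric channels.
#' @param numeric_rate Sampling rate of the numerics, Hz.
#' @param hr_threshold Bradycardia threshold, bpm.
#' @param spo2_threshold Desaturation threshold, percent.
#' @param follow Seconds past the pause end to search.
#' @return `pauses` with logical columns `bradycardia` and `desaturation`
#'   appended.
#' @export
cooccurrence_events <- function(pauses, hr, spo2, numeric_rate = 1,
                                hr_threshold = 100, spo2_threshold = 80,
                                follow = 60) {
  below <- function(ch, a, b, thr) {
    i1 <- max(1L, floor(a * numeric_rate) + 1L)
    i2 <- min(length(ch), floor(b * numeric_rate) + 1L)
    if (i2 < i1) return(FALSE)
    any(ch[i1:i2] < thr, na.rm = TRUE)
  }
  pauses$bradycardia <- vapply(seq_len(nrow(pauses)), function(i)
    below(hr, pauses$start[i], pauses$end[i] + follow, hr_threshold),
    logical(1))
  pauses$desaturation <- vapply(seq_len(nrow(pauses)), function(i)
    below(spo2, pauses$start[i], pauses$end[i] + follow, spo2_threshold),
    logical(1))
  pauses
}

#' Find bradycardia episodes
#'
#' Maximal runs of heart rate below `threshold` lasting at least
#' `min_duration` seconds.  A run of k consecutive sub-threshold samples at
#' `rate` Hz is taken to span `k / rate` seconds.
#'
#' @param hr Heart-rate numeric, bpm.
#' @param rate Sampling rate of `hr`, Hz.
#' @param threshold Bradycardia threshold, bpm.
#' @param min_duration Minimal episode duration, s.
#' @return Data frame with columns `start`, `end`, `duration` (s).
#' @export
find_bradycardias <- function(hr, rate = 1, threshold = 100,
                              min_duration = 15) {
  low <- !is.na(hr) & hr < threshold
  if (!any(low))
    return(data.frame(start = numeric(0), end = numeric(0),
                      duration = numeric(0)))
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths / rate >= min_duration
  data.frame(start = (starts[keep] - 1L) / rate,
             end = ends[keep] / rate,
             duration = r$lengths[keep] / rate)
}
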