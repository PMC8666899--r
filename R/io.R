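# CSV interchange.  One row per IP sample; HR/SpO2 values appear on the
# rows whose time matches a numeric sample, other rows leave those cells
# empty.  This mirrors monitor exports where the waveform and the numerics
# run at different rates in one table.

#' Write a recording to CSV
#'
#' Columns: `time_s`, `ip`, `hr`, `spo2`; header row; numeric channels
#' empty except at their own sample times.
#'
#' @param recording A `physio_recording`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(recording, path) {
  n <- length(recording$ip)
  t <- (seq_len(n) - 1) / recording$ip_rate
  hr_col <- rep(NA_real_, n)
  spo2_col <- rep(NA_real_, n)
  idx <- round((seq_along(recording$hr) - 1) / recording$numeric_rate *
                 recording$ip_rate) + 1L
  ok <- idx >= 1L & idx <= n
  hr_col[idx[ok]] <- recording$hr[ok]
  spo2_col[idx[ok]] <- recording$spo2[ok]
  df <- data.frame(time_s = t, ip = recording$ip, hr = hr_col,
                   spo2 = spo2_col)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a recording from CSV
#'
#' Expects the column layout of [write_recording_csv()].  Sampling rates
#' are inferred from the time stamps.  Missing numeric values are
#' forward-filled for up to `max_ffill` seconds; longer gaps stay `NA`.
#'
#' @param path CSV file.
#' @param subject_id Subject identifier to attach.
#' @param max_ffill Maximal forward-fill span for the numerics, s.
#' @return A `physio_recording`.
#' @export
read_recording_csv <- function(path, subject_id = NULL, max_ffill = 5) {
  df <- utils::read.csv(path)
  need <- c("time_s", "ip", "hr", "spo2")
  if (!all(need %in% names(df)))
    stopf("read_recording_csv: %s must have columns %s", path,
          paste(need, collapse = ", "))
  if (nrow(df) < 2L) stopf("read_recording_csv: %s has too few rows", path)
  ip_rate <- 1 / stats::median(diff(df$time_s))
  has_hr <- which(!is.na(df$hr) | !is.na(df$spo2))
  if (length(has_hr) >= 2L) {
    # numeric time stamps are snapped to the waveform grid, so estimate the
    # rate from the full span and snap to an integer rate when close
    span <- diff(range(df$time_s[has_hr]))
    numeric_rate <- (length(has_hr) - 1L) / span
    if (abs(numeric_rate - round(numeric_rate)) < 0.05 * numeric_rate)
      numeric_rate <- round(numeric_rate)
    t_num <- (seq_len(max(1L, round(nrow(df) / ip_rate * numeric_rate))) -
                1) / numeric_rate
    hr <- ffill_series(df$time_s[has_hr], df$hr[has_hr], t_num, max_ffill)
    spo2 <- ffill_series(df$time_s[has_hr], df$spo2[has_hr], t_num,
                         max_ffill)
  } else {
    numeric_rate <- 1
    hr <- spo2 <- NA_real_
  }
  new_physio_recording(subject_id = subject_id %||%
                         sub("\\.csv$", "", basename(path)),
                       ip = df$ip, ip_rate = ip_rate, hr = hr, spo2 = spo2,
                       numeric_rate = numeric_rate,
                       duration = nrow(df) / ip_rate,
                       start_time = df$time_s[1])
}

# Resample an irregular numeric series onto grid `t_out` by carrying the
# last observation forward, at most `max_gap` seconds.
ffill_series <- function(t_obs, v_obs, t_out, max_gap) {
  keep <- !is.na(v_obs)
  t_obs <- t_obs[keep]; v_obs <- v_obs[keep]
  if (!length(t_obs)) return(rep(NA_real_, length(t_out)))
  i <- findInterval(t_out, t_obs)
  out <- rep(NA_real_, length(t_out))
  ok <- i >= 1L
  ok[ok] <- (t_out[ok] - t_obs[i[ok]]) <= max_gap
  out[ok] <- v_obs[i[ok]]
  out
}

#' Write ground-truth annotations
#'
#' One CSV per annotation kind: `breaths.csv` (`breath_time_s`),
#' `pauses.csv` (`start_s`, `end_s`, `kind`, `gap_start_s`, `gap_end_s`),
#' `artefacts.csv` (`start_s`, `end_s`).
#'
#' @param truth A `ground_truth`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_truth_csv <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(breath_time_s = truth$breath_times),
                   file.path(dir, "breaths.csv"), row.names = FALSE)
  p <- truth$pause_intervals
  utils::write.csv(data.frame(start_s = p$start, end_s = p$end,
                              kind = p$kind, gap_start_s = p$gap_start,
                              gap_end_s = p$gap_end),
                   file.path(dir, "pauses.csv"), row.names = FALSE)
  a <- truth$artefact_intervals
  utils::write.csv(data.frame(start_s = a$start, end_s = a$end),
                   file.path(dir, "artefacts.csv"), row.names = FALSE)
  invisible(dir)
}

#' Write detected breaths, IBIs and pauses
#'
#' `breaths.csv` has `breath_time_s`; `ibis.csv` has `ibi_start_s`,
#' `ibi_end_s`, `duration_s`, `valid`; `pauses.bed` is BED-like 3-column
#' text (`subject`, `start_s`, `end_s`) for interval tooling.
#'
#' @param train A `breath_train`.
#' @param ibis An `ibi_series`.
#' @param pauses Data frame from [detect_pauses()].
#' @param dir Output directory.
#' @param subject_id Subject label for the BED-like file.
#' @return `dir`, invisibly.
#' @export
write_detection_csv <- function(train, ibis, pauses, dir,
                                subject_id = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  subject_id <- subject_id %||% train$subject_id %||% "subject"
  utils::write.csv(data.frame(breath_time_s = train$breath_times),
                   file.path(dir, "breaths.csv"), row.names = FALSE)
  iv <- ibis$intervals
  utils::write.csv(data.frame(ibi_start_s = iv$start, ibi_end_s = iv$end,
                              duration_s = iv$duration, valid = iv$valid),
                   file.path(dir, "ibis.csv"), row.names = FALSE)
  writeLines(sprintf("%s\t%.3f\t%.3f", subject_id, pauses$start,
                     pauses$end),
             file.path(dir, "pauses.bed"))
  invisible(dir)
}
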