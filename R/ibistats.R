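#' Summarise an IBI distribution
#'
#' Computes the distribution summaries used for epoch comparisons: mean,
#' median and SD of the valid interbreath intervals, the proportions of
#' IBIs strictly longer than 5 s and strictly longer than 10 s, and the
#' time-averaged respiratory rate.
#'
#' @param ibis An `ibi_series` from [compute_ibis()].
#' @param rr_trace Optional respiratory-rate trace from
#'   [respiratory_rate()]; if `NULL`, `mean_rr` is `NA`.
#' @return An `ibi_summary` list: `mean_ibi`, `median_ibi`, `sd_ibi`,
#'   `prop_gt5`, `prop_gt10`, `mean_rr`, `n_ibis`.
#' @export
ibi_summary <- function(ibis, rr_trace = NULL) {
  d <- ibis$intervals$duration[ibis$intervals$valid]
  if (length(d) == 0L)
    stopf("ibi_summary: no valid interbreath intervals")
  structure(list(mean_ibi = mean(d),
                 median_ibi = stats::median(d),
                 sd_ibi = stats::sd(d),
                 prop_gt5 = mean(d > 5),
                 prop_gt10 = mean(d > 10),
                 mean_rr = if (is.null(rr_trace)) NA_real_
                           else mean(rr_trace$rate),
                 n_ibis = length(d)),
            class = "ibi_summary")
}

#' @export
print.ibi_summary <- function(x, ...) {
  cat(sprintf("ibi_summary: n=%d, mean %.2f s, median %.2f s, SD %.2f s, >5 s %.2f%%, >10 s %.2f%%, RR %.1f bpm\n",
              x$n_ibis, x$mean_ibi, x$median_ibi, x$sd_ibi,
              100 * x$prop_gt5, 100 * x$prop_gt10, x$mean_rr))
  invisible(x)
}

#' Paired sign-flip permutation test
#'
#' A paired non-parametric t-test: the statistic is the one-sample t of the
#' within-subject differences `after - before`, and the null distribution
#' is built by randomly flipping the sign of each subject's difference
#' (exchangeability under the paired null).  When `2^n <= n_perm` the full
#' sign-flip enumeration is used and the p-value is exact; otherwise
#' `n_perm` random flips are drawn and the p-value uses the add-one
#' convention `p = (1 + #extreme) / (1 + n_perm)`, which guarantees
#' validity and `p > 0` at finite `n_perm`.
#'
#' @param before,after Paired per-subject values (equal length, n >= 2).
#' @param n_perm Number of random permutations (>= 100).
#' @param seed Integer seed for the random flips.
#' @param alternative `"two.sided"`, `"greater"` (after > before) or
#'   `"less"`.
#' @return A `permutation_result`: `t_statistic`, `p`, `n_permutations`,
#'   `exact`, `alternative`, `seed`.
#' @export
paired_permutation_test <- function(before, after, n_perm = 10000,
                                    seed = NULL,
                                    alternative = c("two.sided", "greater",
                                                    "less")) {
  alternative <- match.arg(alternative)
  if (length(before) != length(after))
    stopf("paired_permutation_test: before/after length mismatch")
  n <- length(before)
  if (n < 2L) stopf("paired_permutation_test: need n >= 2 pairs")
  if (n_perm < 100) stopf("paired_permutation_test: n_perm must be >= 100")
  d <- as.numeric(after) - as.numeric(before)

  t_of <- function(m, ss) {
    # t for flipped differences with mean m; ss = sum(d^2) is flip-invariant
    v <- (ss - n * m^2) / (n - 1)
    ifelse(v > 0, m / sqrt(v / n), ifelse(m == 0, 0, sign(m) * Inf))
  }
  ss <- sum(d^2)
  t_obs <- t_of(mean(d), ss)

  exact <- 2^n <= n_perm
  if (exact) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  } else {
    signs <- with_seed(seed,
      matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n))
  }
  t_null <- t_of(drop(signs %*% d) / n, ss)

  eps <- 1e-12 * (abs(t_obs) + 1)
  extreme <- switch(alternative,
                    two.sided = abs(t_null) >= abs(t_obs) - eps,
                    greater = t_null >= t_obs - eps,
                    less = t_null <= t_obs + eps)
  p <- if (exact) sum(extreme) / nrow(signs)
       else (1 + sum(extreme)) / (1 + n_perm)
  structure(list(t_statistic = t_obs, p = p,
                 n_permutations = nrow(signs), exact = exact,
                 alternative = alternative, seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("sign-flip permutation test (%s%s): t = %.3f, p = %.4g (%d permutations)\n",
              x$alternative, if (x$exact) ", exact" else "", x$t_statistic,
              x$p, x$n_permutations))
  invisible(x)
}

#' Hochberg step-up multiple-comparison adjustment
#'
#' Adjusted p-values controlling the family-wise error rate; order
#' preserving, each adjusted value at least its input, capped at 1.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values in the input order.
#' @export
hochberg_correct <- function(p_values) {
  if (any(!is.finite(p_values) | p_values <= 0 | p_values > 1))
    stopf("hochberg_correct: p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "hochberg")
}

#' Compare IBI metrics between two epochs across a cohort
#'
#' Runs the full pipeline (preprocess, detect breaths, IBIs,
#' respiratory rate, summarise) on each subject's before and after epochs,
#' then tests each of the six metrics (mean respiratory rate; mean, median
#' and SD of the IBIs; percentages of IBIs over 5 s and over 10 s) with a
#' paired sign-flip permutation test and adjusts the six p-values with
#' Hochberg's method.
#'
#' Epochs can be given as two matched lists of recordings (`before`,
#' `after`) or as one list plus `epoch_before` / `epoch_after` windows
#' (`c(start, end)` in seconds), cropped with [crop_recording()].  Subjects
#' are matched by `subject_id`; mismatched sets are an error.
#'
#' @param before List of `physio_recording`s (the before epoch, or the full
#'   recordings when windows are given).
#' @param after Optional list of after-epoch recordings.
#' @param epoch_before,epoch_after Optional windows `c(start, end)`, s.
#' @param n_perm,seed,alternative Passed to [paired_permutation_test()].
#' @param preprocess_params,threshold_params Stage parameters.
#' @param rr_window Respiratory-rate window, s.
#' @return An `epoch_comparison`: `table` (one row per metric: group means
#'   before/after, t-statistic, uncorrected and corrected p), `summaries`
#'   (per-subject before/after `ibi_summary` pairs).
#' @export
compare_epochs <- function(before, after = NULL, epoch_before = NULL,
                           epoch_after = NULL, n_perm = 10000, seed = NULL,
                           alternative = "two.sided",
                           preprocess_params = ibidetect::preprocess_params(),
                           threshold_params = ibidetect::threshold_params(),
                           rr_window = 30) {
  if (is.null(after)) {
    if (is.null(epoch_before) || is.null(epoch_after))
      stopf("compare_epochs: supply either `after` recordings or both epoch windows")
    after <- lapply(before, crop_recording, start = epoch_after[1],
                    end = epoch_after[2])
    before <- lapply(before, crop_recording, start = epoch_before[1],
                     end = epoch_before[2])
  }
  ids_b <- vapply(before, function(r) r$subject_id, character(1))
  ids_a <- vapply(after, function(r) r$subject_id, character(1))
  if (!setequal(ids_b, ids_a) || anyDuplicated(ids_b) ||
      length(ids_b) != length(ids_a))
    stopf("compare_epochs: before/after subject sets do not match")
  after <- after[match(ids_b, ids_a)]

  summarise_epoch <- function(rec) {
    filt <- preprocess(rec, preprocess_params)
    train <- detect_breaths(filt, threshold_params)
    ibis <- compute_ibis(train, filt)
    rr <- respiratory_rate(train, window = rr_window)
    ibi_summary(ibis, rr)
  }
  sum_b <- lapply(before, summarise_epoch)
  sum_a <- lapply(after, summarise_epoch)

  metrics <- c(mean_rr = "Mean respiratory rate (bpm)",
               mean_ibi = "Mean IBI (s)",
               median_ibi = "Median IBI (s)",
               sd_ibi = "SD IBI (s)",
               prop_gt5 = "IBI >5 s (%)",
               prop_gt10 = "IBI >10 s (%)")
  get_vec <- function(sums, key) {
    v <- vapply(sums, function(s) s[[key]], numeric(1))
    if (startsWith(key, "prop")) 100 * v else v
  }
  rows <- lapply(names(metrics), function(key) {
    b <- get_vec(sum_b, key)
    a <- get_vec(sum_a, key)
    pt <- paired_permutation_test(b, a, n_perm = n_perm, seed = seed,
                                  alternative = alternative)
    data.frame(metric = metrics[[key]], key = key,
               mean_before = mean(b), mean_after = mean(a),
               t_statistic = pt$t_statistic, p = pt$p,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$p_corrected <- hochberg_correct(tab$p)
  rownames(tab) <- NULL
  structure(list(table = tab,
                 summaries = list(before = sum_b, after = sum_a,
                                  subject_ids = ids_b),
                 n_subjects = length(ids_b), n_perm = n_perm,
                 alternative = alternative),
            class = "epoch_comparison")
}

#' @export
print.epoch_comparison <- function(x, ...) {
  cat(sprintf("epoch_comparison: n = %d subjects, %s sign-flip test, %d permutations\n\n",
              x$n_subjects, x$alternative, x$n_perm))
  tab <- x$table
  tab$mean_before <- round(tab$mean_before, 2)
  tab$mean_after <- round(tab$mean_after, 2)
  tab$t_statistic <- round(tab$t_statistic, 2)
  tab$p <- signif(tab$p, 2)
  tab$p_corrected <- signif(tab$p_corrected, 2)
  print(tab[, c("metric", "mean_before", "mean_after", "t_statistic", "p",
                "p_corrected")], row.names = FALSE)
  invisible(x)
}

#' Write an epoch comparison as CSV and Markdown
#'
#' @param comparison An `epoch_comparison`.
#' @param csv_path,md_path Output paths (either may be `NULL`).
#' @return Invisibly, the comparison.
#' @export
write_epoch_comparison <- function(comparison, csv_path = NULL,
                                   md_path = NULL) {
  tab <- comparison$table
  if (!is.null(csv_path))
    utils::write.csv(tab, csv_path, row.names = FALSE)
  if (!is.null(md_path)) {
    fmt <- function(v, d = 3) formatC(v, digits = d, format = "g")
    lines <- c(
      "| Metric | Mean before | Mean after | t-statistic | Uncorrected p | Corrected p |",
      "|---|---|---|---|---|---|",
      sprintf("| %s | %s | %s | %s | %s | %s |", tab$metric,
              fmt(tab$mean_before), fmt(tab$mean_after),
              fmt(tab$t_statistic), fmt(tab$p), fmt(tab$p_corrected)))
    writeLines(lines, md_path)
  }
  invisible(comparison)
}
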