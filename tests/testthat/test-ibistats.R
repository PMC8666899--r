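test_that("IBI summaries match hand-computed values", {
  s <- ibi_summary(make_ibis(rep(1, 10)))
  expect_equal(s$mean_ibi, 1); expect_equal(s$median_ibi, 1)
  expect_equal(s$sd_ibi, 0)
  expect_equal(s$prop_gt5, 0); expect_equal(s$prop_gt10, 0)

  s2 <- ibi_summary(make_ibis(c(0.8, 1.0, 1.2, 6.0, 12.0)))
  expect_equal(s2$mean_ibi, 4.2)
  expect_equal(s2$median_ibi, 1.2)
  expect_equal(s2$prop_gt5, 0.4)
  expect_equal(s2$prop_gt10, 0.2)
  expect_equal(s2$sd_ibi, sqrt(sum((c(0.8, 1, 1.2, 6, 12) - 4.2)^2) / 4))

  # strict inequality at the boundary
  s3 <- ibi_summary(make_ibis(c(5, 10, 5.01, 10.01)))
  expect_equal(s3$prop_gt5, 0.75)  # exactly 5 s is not "longer than 5 s"
  expect_equal(s3$prop_gt10, 0.25)

  expect_error(ibi_summary(make_ibis(c(1, 2), valid = FALSE)), "valid")
})

test_that("identical epochs give t = 0 and p = 1", {
  x <- c(1.2, 0.9, 1.4, 1.1, 1.0)
  r <- paired_permutation_test(x, x, n_perm = 500, seed = 1)
  expect_equal(r$t_statistic, 0)
  expect_equal(r$p, 1)
})

test_that("exhaustive sign-flip enumeration reproduces the exact p-value", {
  before <- c(0, 0, 0, 0)
  after <- c(1, 2, 3, 4)
  r <- paired_permutation_test(before, after, n_perm = 1000, seed = 1,
                               alternative = "greater")
  expect_true(r$exact)
  expect_equal(r$n_permutations, 16L)
  expect_equal(r$p, 1 / 16)
  r2 <- paired_permutation_test(before, after, n_perm = 1000, seed = 1)
  expect_equal(r2$p, 2 / 16)  # two-sided counts the mirrored flip
  # brute-force enumeration oracle, written out directly
  d <- after - before
  ts <- apply(expand.grid(rep(list(c(-1, 1)), 4)), 1, function(s) {
    ds <- s * d
    mean(ds) / (stats::sd(ds) / 2)
  })
  t_obs <- mean(d) / (stats::sd(d) / 2)
  expect_equal(r$p, mean(ts >= t_obs - 1e-12))
})

test_that("negating all differences flips t and keeps the two-sided p", {
  set.seed(2)
  before <- rnorm(12); after <- before + rnorm(12, 0.5)
  r1 <- paired_permutation_test(before, after, n_perm = 2000, seed = 9)
  r2 <- paired_permutation_test(after, before, n_perm = 2000, seed = 9)
  expect_equal(r1$t_statistic, -r2$t_statistic)
  expect_equal(r1$p, r2$p)
})

test_that("p-values are invariant to subject order and paired shifts", {
  set.seed(3)
  before <- rnorm(10); after <- before + rnorm(10, 0.3)
  r <- paired_permutation_test(before, after, n_perm = 2000, seed = 11)
  o <- sample(10)
  r_perm <- paired_permutation_test(before[o], after[o], n_perm = 2000,
                                    seed = 11)
  expect_equal(r$p, r_perm$p)
  shift <- rnorm(10)  # a common per-subject shift leaves differences alone
  r_shift <- paired_permutation_test(before + shift, after + shift,
                                     n_perm = 2000, seed = 11)
  expect_equal(r$p, r_shift$p)
  expect_equal(r$t_statistic, r_shift$t_statistic)
})

test_that("Hochberg adjustment agrees with the step-up recursion oracle", {
  expect_equal(hochberg_correct(0.03), 0.03)
  expect_equal(hochberg_correct(c(0.01, 0.03, 0.04)), c(0.03, 0.04, 0.04))
  expect_equal(hochberg_correct(rep(0.02, 5)), rep(0.02, 5))
  set.seed(4)
  for (i in 1:1000) {
    p <- stats::runif(sample(1:10, 1))
    adj <- hochberg_correct(p)
    expect_equal(adj, ref_hochberg(p), tolerance = 1e-12)
    expect_true(all(adj >= p & adj <= 1))
    expect_equal(order(adj[order(p)]), seq_along(p))  # order preserved
  }
  expect_error(hochberg_correct(c(0.5, 0)), "p-values")
})

test_that("epoch comparison of identical cohorts is null everywhere", {
  recs <- lapply(1:4, function(i)
    simulate_recording(simulation_config(duration = 120, seed = 60 + i),
                       subject_id = sprintf("S%02d", i))$recording)
  cmp <- compare_epochs(recs, recs, n_perm = 200, seed = 1)
  expect_true(all(cmp$table$t_statistic == 0))
  expect_true(all(cmp$table$p_corrected == 1))
})

test_that("epoch comparison rejects mismatched subject sets", {
  recs <- lapply(1:3, function(i)
    simulate_recording(simulation_config(duration = 120, seed = 70 + i),
                       subject_id = sprintf("S%02d", i))$recording)
  expect_error(compare_epochs(recs[1:2], recs[c(1, 3)]), "match")
})

test_that("epoch windows crop recordings correctly", {
  sim <- simulate_recording(simulation_config(duration = 240, seed = 80))
  part <- crop_recording(sim$recording, 60, 180)
  expect_equal(part$duration, 120)
  expect_equal(length(part$ip), round(120 * part$ip_rate))
  expect_equal(part$start_time, 60)
  i0 <- round(60 * sim$recording$ip_rate) + 1
  expect_equal(part$ip[1:100], sim$recording$ip[i0:(i0 + 99)])
  expect_error(crop_recording(sim$recording, -5, 100), "window")
})

test_that("epoch comparison output has the six-metric report shape", {
  recs_b <- lapply(1:4, function(i)
    simulate_recording(simulation_config(duration = 120, seed = 90 + i),
                       subject_id = sprintf("S%02d", i))$recording)
  recs_a <- lapply(1:4, function(i)
    simulate_recording(simulation_config(duration = 120,
                                         breath_rate_mean = 42,
                                         seed = 190 + i),
                       subject_id = sprintf("S%02d", i))$recording)
  cmp <- compare_epochs(recs_b, recs_a, n_perm = 200, seed = 2)
  expect_equal(nrow(cmp$table), 6L)
  expect_true(all(c("mean_before", "mean_after", "t_statistic", "p",
                    "p_corrected") %in% names(cmp$table)))
  expect_true(all(cmp$table$p_corrected >= cmp$table$p))
  # slower after-breathing must show as lower RR and longer mean IBI
  expect_lt(cmp$table$mean_after[1], cmp$table$mean_before[1])
  expect_gt(cmp$table$mean_after[2], cmp$table$mean_before[2])
  csvf <- tempfile(fileext = ".csv"); mdf <- tempfile(fileext = ".md")
  write_epoch_comparison(cmp, csvf, mdf)
  expect_equal(nrow(utils::read.csv(csvf)), 6L)
  expect_match(readLines(mdf)[1], "Corrected p")
})
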