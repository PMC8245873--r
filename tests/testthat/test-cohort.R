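test_that("geometric mean and SD follow the log-scale definitions", {
  expect_equal(geometric_mean(c(2, 2, 2)), 2)
  expect_equal(geometric_mean(c(1, 4)), 2)
  expect_error(geometric_mean(c(1, 0)), "positive")
  expect_error(geometric_sd(c(1, -2)), "positive")
  expect_equal(geometric_sd(c(1, 1, 1)), 1)

  set.seed(123)
  x <- stats::rlnorm(1e5, meanlog = 0.5, sdlog = 0.3)
  expect_equal(geometric_mean(x), exp(0.5), tolerance = 0.01)
  expect_equal(geometric_sd(x), exp(0.3), tolerance = 0.01)
})

test_that("FaS summaries report zero dispersion for identical curves and reject undefined days", {
  fam <- m5_family(c(3, 5, 8))
  rid_df <- cohort_rid(fam, days = 1:30)
  fs <- summarize_fas(rid_df)
  expect_equal(fs$cv_pct, rep(0, 30), tolerance = 1e-8)
  expect_error(summarize_fas(rid_df, days = 31), "no FaS")

  fs_g <- summarize_fas(rid_df, cv = "geometric")
  expect_equal(fs_g$cv_pct, rep(0, 30), tolerance = 1e-6)
  expect_equal(fs_g$sd_fas, rep(1, 30), tolerance = 1e-8)
})

test_that("a perfect predictor yields r2 = 1 and 100% within every threshold", {
  # subjects sharing kinetics but differing in plasma pool size have
  # identical FaS curves, so the group coefficient predicts each TBS
  # exactly while assigned TBS still varies
  fam <- m5_family(c(2, 4.5, 7, 9))
  rep_ <- evaluate_sampling_days(cohort_rid(fam), days = 1:30)
  expect_equal(rep_$regressions$r_squared, rep(1, 30), tolerance = 1e-9)
  expect_equal(rep_$regressions$slope, rep(1, 30), tolerance = 1e-6)
  expect_equal(rep_$pct_within$pct_within,
               rep(100, nrow(rep_$pct_within)))
  expect_equal(rep_$regressions$rank_r_squared, rep(1, 30))
  # every day is an exact tie; earliest selected day wins for everyone
  expect_equal(rep_$best_day_frequency$count[1], 4)
  expect_length(rep_$ties, 4)
})

test_that("within-threshold percentages match hand-enumerated relative errors", {
  # predictions are exact for an m5 family; shrink the reported assigned
  # values so the relative errors become exactly 10%, -30%, +30%
  fam <- m5_family(c(2, 5, 9))
  rid_df <- cohort_rid(fam, days = 1:7)
  asg <- attr(rid_df, "assigned")
  asg$assigned_tbs <- asg$assigned_tbs / c(1.1, 0.7, 1.3)
  rep_ <- evaluate_sampling_days(rid_df, assigned = asg, days = 1:7,
                                 selected_days = c(4, 7))
  # relative errors are 10%, 30%, 30%: one subject within 25%, all
  # within 50%
  p <- rep_$pct_within
  expect_equal(p$pct_within[p$threshold == 25], rep(100 / 3, 7))
  expect_equal(p$pct_within[p$threshold == 50], rep(100, 7))
})

test_that("accuracy report invariants hold on a generated cohort", {
  co <- generate_cohort(cohort_design(n_subjects = 10, seed = 31))
  rep_ <- evaluate_sampling_days(cohort_rid(co), days = 1:30)

  # threshold monotonicity at every day
  for (d in 1:30) {
    p <- rep_$pct_within[rep_$pct_within$day == d, ]
    p <- p[order(p$threshold), "pct_within"]
    expect_true(all(diff(p) >= 0))
  }
  # best-day counts account for every subject
  expect_equal(sum(rep_$best_day_frequency$count), 10)
  # GM of predictions equals GM of assigned at every day
  pr <- rep_$tbs_summary[rep_$tbs_summary$series == "predicted", ]
  as_ <- rep_$tbs_summary[rep_$tbs_summary$series == "assigned", ]
  expect_equal(pr$gmean, rep(as_$gmean, nrow(pr)), tolerance = 1e-12)
})

test_that("evaluation requires at least 3 subjects and assigned values", {
  fam <- m5_family(c(3, 6))
  rid_df <- cohort_rid(fam)
  expect_error(evaluate_sampling_days(rid_df), "at least 3")
  co <- generate_cohort(cohort_design(n_subjects = 3, seed = 2))
  rid_df2 <- cohort_rid(co)
  attr(rid_df2, "assigned") <- NULL
  expect_error(evaluate_sampling_days(rid_df2), "assigned")
})

test_that("FaS dispersion shrinks as stores equilibrate", {
  co <- generate_cohort(cohort_design(n_subjects = 20, seed = 1))
  fs <- summarize_fas(cohort_rid(co))
  expect_lt(fs$cv_pct[fs$day == 21], fs$cv_pct[fs$day == 7])
})

test_that("biexponential fitting recovers exact parameters from noiseless data", {
  t <- 0:29
  y <- 1.2 * exp(-0.9 * t) + 0.6 * exp(-0.05 * t)
  fit <- fit_biexponential(t, y)
  expect_equal(fit$A1, 1.2, tolerance = 1e-6)
  expect_equal(fit$k1, 0.9, tolerance = 1e-6)
  expect_equal(fit$A2, 0.6, tolerance = 1e-6)
  expect_equal(fit$k2, 0.05, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_gt(fit$k1, fit$k2)
})

test_that("biexponential fitting tolerates multiplicative noise", {
  t <- 0:29
  set.seed(99)
  y <- (1.2 * exp(-0.9 * t) + 0.6 * exp(-0.05 * t)) *
    exp(stats::rnorm(30, 0, 0.01))
  fit <- fit_biexponential(t, y)
  truth <- c(1.2, 0.9, 0.6, 0.05)
  est <- c(fit$A1, fit$k1, fit$A2, fit$k2)
  expect_true(all(abs(est - truth) / truth < 0.1))
})

test_that("biexponential fitting validates its input", {
  expect_error(fit_biexponential(1:4, c(1, 2, 3, 4)), ">= 5")
  expect_error(fit_biexponential(1:5, c(1, 2, -1, 4, 5)), "positive")
})

test_that("the cohort FaS decline is near-perfectly biexponential", {
  co <- generate_cohort(cohort_design(n_subjects = 20, seed = 1))
  fs <- summarize_fas(cohort_rid(co))
  fit <- fit_biexponential(fs$day, fs$gm_fas)
  expect_gt(fit$r_squared, 0.999)
})
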