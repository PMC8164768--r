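# Calibration and discrimination machinery.

test_that("E/O exact Poisson intervals reproduce published worked rows", {
  # overall rows: printed ratios and intervals at 2-decimal precision
  overall_ckb <- eo_ratio_ci(760, 751)
  expect_equal(round(overall_ckb$ratio, 2), 1.01)
  expect_equal(round(overall_ckb$ci_low, 2), 0.94)
  expect_equal(round(overall_ckb$ci_high, 2), 1.09)
  overall_swhs <- eo_ratio_ci(1320, 1409)
  expect_equal(round(overall_swhs$ratio, 2), 0.94)
  expect_equal(round(overall_swhs$ci_low, 2), 0.89)
  expect_equal(round(overall_swhs$ci_high, 2), 0.99)
  # the exact interval (not a normal approximation) is what reproduces the
  # published subgroup bounds, e.g. 0.68-0.96 for the oldest age band
  old <- eo_ratio_ci(111, 138)
  expect_equal(round(old$ci_low, 2), 0.68)
  expect_equal(round(old$ci_high, 2), 0.96)
  normal_low <- 111 / (138 + 1.96 * sqrt(138))
  expect_equal(round(normal_low, 2), 0.69)  # approximation drifts
  expect_identical(eo_ratio_ci(57, 57)$ratio, 1)
  expect_error(eo_ratio_ci(0, 10), "positive")
  expect_error(eo_ratio_ci(10, 0), "positive integer")
  expect_error(eo_ratio_ci(10, 2.5), "positive integer")
})

test_that("expected cases are additive over any partition and match single
           projections", {
  m <- default_model
  co <- simulate_cohort(sim_config(n = 3000, seed = 55))
  ec <- expected_cases(co, m, default_rates, by = "residence")
  expect_equal(sum(ec$by_group$E), ec$total, tolerance = 1e-12)
  expect_equal(expected_cases(co[0, ], m, default_rates)$total, 0)
  one <- co[7, , drop = FALSE]
  p1 <- project(one[rr_predictors()], one$entry_age,
                one$exit_age - one$entry_age, one$residence, m,
                default_rates)
  expect_equal(expected_cases(one, m, default_rates)$total, p1$probability,
               tolerance = 1e-12)
})

test_that("calibration deciles partition the sample and scale with the
           predictions", {
  set.seed(14)
  n <- 100000
  # prediction spread chosen so every decile expects >1000 events, making
  # the +-10% self-calibration band a >3 sigma check per bin
  pred <- rbeta(n, 6, 14)
  obs <- rbinom(n, 1, pred)
  dec <- calibration_deciles(pred, obs)
  expect_equal(sum(dec$n), n)
  expect_true(all(abs(dec$n - n / 10) <= 1))
  # outcomes drawn from the predictions themselves: near-unity ratios
  expect_true(all(dec$ratio > 0.9 & dec$ratio < 1.1))
  # rescaling predictions rescales E, leaves O alone
  dec2 <- calibration_deciles(pred / 2, obs)
  expect_equal(dec2$E, dec$E / 2, tolerance = 1e-9)
  expect_equal(dec2$O, dec$O)
  expect_error(calibration_deciles(rep(0.5, 100), rbinom(100, 1, 0.5)),
               "constant")
  expect_error(calibration_deciles(c(runif(11), 1.5), rbinom(12, 1, 0.5)),
               "0, 1")
})

test_that("AUC equals brute-force pair enumeration, with the textbook edge
           cases", {
  expect_equal(auc_10yr(c(0.8, 0.4, 0.6, 0.3, 0.2),
                        c(TRUE, TRUE, FALSE, FALSE, FALSE))$auc, 5 / 6)
  set.seed(26)
  for (i in 1:10) {
    n <- sample(20:200, 1)
    pred <- round(runif(n), 2)   # heavy ties
    status <- rbinom(n, 1, 0.3) == 1
    if (!any(status) || all(status)) next
    expect_identical(auc_10yr(pred, status)$auc, oracle_auc(pred, status))
  }
  expect_equal(auc_10yr(rep(0.5, 10), c(rep(TRUE, 3), rep(FALSE, 7)))$auc,
               0.5)
  expect_equal(auc_10yr(c(1, 1, 0, 0), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_error(auc_10yr(1:3 / 10, c(TRUE, TRUE, TRUE)), "control")
})

test_that("ten-year eligibility follows the cumulative/dynamic rule", {
  rec <- data.frame(
    entry_age = c(40, 40, 40, 40, 40),
    exit_age = c(45, 55, 47, 49, 52),
    event = c("bc", "bc", "censored", "death", "censored"))
  s <- ten_year_status(rec)
  expect_identical(s, c(TRUE, FALSE, NA, NA, FALSE))
  s2 <- ten_year_status(rec, deaths_as_controls = TRUE)
  expect_identical(s2, c(TRUE, FALSE, NA, FALSE, FALSE))
})

test_that("adjusted AUC pools within-stratum comparisons by pair counts", {
  pred <- c(0.9, 0.2, 0.8, 0.1, 0.7, 0.6, 0.5)
  status <- c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE)
  one <- adjusted_auc(pred, status, rep("a", 7))
  expect_identical(one$auc, auc_10yr(pred, status)$auc)
  # two strata with hand-enumerable pairs
  strata <- c("a", "a", "a", "b", "b", "b", "b")
  a_auc <- oracle_auc(pred[1:3], status[1:3])       # 1 case x 2 controls
  b_auc <- oracle_auc(pred[4:7], status[4:7])       # 1 case x 3 controls
  want <- (a_auc * 2 + b_auc * 3) / 5
  expect_equal(adjusted_auc(pred, status, strata)$auc, want)
  # stratum-constant predictions carry no within-stratum discrimination
  pred_const <- c(0.3, 0.3, 0.3, 0.8, 0.8, 0.8, 0.8)
  expect_equal(adjusted_auc(pred_const, status, strata)$auc, 0.5)
  expect_error(adjusted_auc(c(0.1, 0.2), c(TRUE, FALSE), c("a", "b")),
               "stratum")
})

test_that("quintile RRs reference the lowest group and behave under null
           and informative predictions", {
  co <- simulate_cohort(sim_config(n = 30000, seed = 61))
  # informative predictions from the generating model itself
  pred <- predict_absolute_risk(co, default_model, default_rates,
                                horizon = 10)
  qr <- quintile_rr(pred, co)
  expect_identical(qr$rr[1], 1)
  expect_true(is.na(qr$ci_low[1]))
  expect_equal(sum(qr$cases), sum(co$event == "bc"))
  expect_true(all(diff(qr$rr) > -0.5))   # broadly increasing
  expect_gt(qr$rr[5], qr$rr[2])
  # null predictions: all quintile CIs cover 1
  pred0 <- withr::with_seed(62, runif(nrow(co)))
  qr0 <- quintile_rr(pred0, co)
  expect_true(all(qr0$ci_low[-1] < 1 & qr0$ci_high[-1] > 1))
})

test_that("screening indices satisfy the 2x2 identities at every cutoff", {
  # worked 2x2: TP 8, FP 92, FN 2, TN 898
  pred <- c(rep(0.03, 100), rep(0.001, 900))
  status <- c(rep(TRUE, 8), rep(FALSE, 92), rep(TRUE, 2), rep(FALSE, 898))
  row <- screening_indices(pred, status, cutoffs = 0.02)
  expect_equal(row$sensitivity, 0.8)
  expect_equal(row$specificity, 898 / 990, tolerance = 1e-9)
  expect_equal(row$ppv, 0.08)
  expect_equal(row$nns, 12.5)
  expect_equal(row$pct_high_risk, 0.1)
  # NNS = 1/PPV and bookkeeping identities across the published cutoff grid
  co <- simulate_cohort(sim_config(n = 20000, seed = 71))
  p10 <- predict_absolute_risk(co, default_model, default_rates, horizon = 10)
  st <- ten_year_status(co)
  tab <- screening_indices(p10, st)
  keep <- !is.na(st)
  n_case <- sum(st[keep]); n_ctrl <- sum(!st[keep])
  for (i in seq_len(nrow(tab))) {
    expect_equal(tab$sensitivity[i] * n_case +
                   (1 - tab$sensitivity[i]) * n_case, n_case)
    flagged <- tab$pct_high_risk[i] * (n_case + n_ctrl)
    expect_equal(tab$sensitivity[i] * n_case / flagged, tab$ppv[i],
                 tolerance = 1e-9)
    if (!is.na(tab$ppv[i]) && tab$ppv[i] > 0) {
      expect_equal(tab$nns[i], 1 / tab$ppv[i])
    }
  }
  expect_error(screening_indices(p10, st, cutoffs = c(0, 0.5)), "cutoffs")
})
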