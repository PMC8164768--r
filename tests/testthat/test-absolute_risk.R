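# Competing-risk absolute-risk projection.

flat_table <- function(inc = 100, mort = 500, bcmort = 0) {
  rows <- expand.grid(age_start = seq(30, 80, 5),
                      residence = c("urban", "rural"),
                      stringsAsFactors = FALSE)
  rows$age_width <- 5
  rows$bc_incidence_1e5 <- inc
  rows$all_cause_mortality_1e5 <- mort
  rows$bc_mortality_1e5 <- bcmort
  rate_table(rows)
}

zero_par <- par_set(0, 0, 0, 0)

test_that("zero breast-cancer hazard projects to zero risk", {
  tab <- flat_table(inc = 0, mort = 500)
  for (tau in c(1, 10, 35.5)) {
    pr <- project(profile_reference(), 40, tau, "urban", default_model,
                  tab, zero_par)
    expect_identical(pr$probability, 0)
  }
})

test_that("constant hazards match the closed form and the fine-grid oracle", {
  # h1 = 0.001/PY, h2 = 0.01/PY, tau = 10:
  # P = h1/(h1+h2) * (1 - exp(-(h1+h2)*10))
  tab <- flat_table(inc = 100, mort = 1000, bcmort = 0)
  pr <- project(profile_reference(), 40, 10, "urban", default_model, tab,
                zero_par)
  closed <- 0.001 / 0.011 * (1 - exp(-0.11))
  expect_equal(pr$probability, closed, tolerance = 1e-12)
  expect_equal(closed, 0.009470, tolerance = 1e-4)
  num <- oracle_project(profile_reference(), 40, 10, "urban", default_model,
                        tab, zero_par)
  expect_lt(abs(pr$probability - num), 1e-6)
})

test_that("a query spanning the age split chains the two segments", {
  m <- default_model
  p <- make_profile(bmi_category = ">=28")
  pr <- project(p, 45, 10, "urban", m, default_rates, m$par)
  # manual chaining: 45-50 piece, then 50-55 with survival carried over
  pr1 <- project(p, 45, 5, "urban", m, default_rates, m$par)
  pr2 <- project(p, 50, 5, "urban", m, default_rates, m$par)
  expect_equal(pr$probability,
               pr1$probability + pr1$survival * pr2$probability,
               tolerance = 1e-12)
  num <- oracle_project(p, 45, 10, "urban", m, default_rates, m$par)
  expect_lt(abs(pr$probability - num), 1e-6)
})

test_that("ten-year risk is the 10-year projection, monotone in risk
           factors, and collapses to 1 - exp(-int h1) without competing
           risk", {
  m <- default_model
  p <- make_profile(education = "middle school")
  expect_identical(ten_year_risk(p, 47, "rural", m, default_rates),
                   project(p, 47, 10, "rural", m, default_rates)$probability)
  # raising any single predictor with RR > 1 strictly increases risk
  lv <- rr_levels()
  base <- ten_year_risk(profile_reference(), 52, "urban", m, default_rates)
  for (pred in c("education", "height_category", "family_history")) {
    risks <- vapply(lv[[pred]], function(l) {
      prof <- do.call(make_profile, stats::setNames(list(l), pred))
      ten_year_risk(prof, 52, "urban", m, default_rates)
    }, numeric(1))
    expect_true(all(diff(risks) > 0))
    expect_equal(risks[[1]], base)
  }
  # no competing risk: P = 1 - exp(-cumulative h1)
  tab <- flat_table(inc = 200, mort = 0)
  pr <- project(profile_reference(), 40, 10, "urban", m, tab, zero_par)
  expect_equal(pr$probability, 1 - exp(-0.002 * 10), tolerance = 1e-12)
})

test_that("projection is monotone in horizon and bounded by the
           no-competing-risk limit", {
  m <- default_model
  p <- make_profile(parity = "nulliparous")
  taus <- c(0.5, 1, 2.5, 5, 10, 20, 30)
  risks <- vapply(taus, function(tau) {
    project(p, 42, tau, "rural", m, default_rates)$probability
  }, numeric(1))
  expect_true(all(diff(risks) > 0))
  # competing risk can only reduce risk below 1 - exp(-int h1)
  for (tau in taus) {
    pr <- project(p, 42, tau, "rural", m, default_rates)
    h1_int <- -log(prod(vapply(seq_len(nrow(pr$pieces)), function(i) {
      exp(-pr$pieces$h1[i] * (pr$pieces$end[i] - pr$pieces$start[i]))
    }, numeric(1))))
    expect_lte(pr$probability, 1 - exp(-h1_int))
    expect_lte(1 - exp(-h1_int), h1_int)
  }
})

test_that("chaining identity holds to 1e-12 across random split points", {
  m <- default_model
  set.seed(31)
  for (i in 1:25) {
    p <- make_profile(
      education = sample(rr_levels()$education, 1),
      bmi_category = sample(rr_levels()$bmi_category, 1))
    res <- sample(c("urban", "rural"), 1)
    a <- runif(1, 30, 70)
    tau <- runif(1, 1, 85 - a - 0.1)
    t1 <- runif(1, 0.1, tau - 0.05)
    full <- project(p, a, tau, res, m, default_rates)
    first <- project(p, a, t1, res, m, default_rates)
    second <- project(p, a + t1, tau - t1, res, m, default_rates)
    expect_equal(full$probability,
                 first$probability + first$survival * second$probability,
                 tolerance = 1e-12)
  }
})

test_that("closed-form projection agrees with the fine-grid oracle on random
           queries", {
  m <- default_model
  lv <- rr_levels()
  set.seed(17)
  worst <- 0
  for (i in 1:60) {
    p <- profile_reference()
    for (pred in rr_predictors()) {
      p[[pred]] <- factor(sample(lv[[pred]], 1), lv[[pred]])
    }
    res <- sample(c("urban", "rural"), 1)
    a <- runif(1, 30, 80)
    tau <- runif(1, 0.5, 85 - a)
    got <- project(p, a, tau, res, m, default_rates)$probability
    want <- oracle_project(p, a, tau, res, m, default_rates, m$par)
    worst <- max(worst, abs(got - want))
  }
  expect_lt(worst, 1e-6)
})

test_that("coverage gaps and invalid queries error", {
  m <- default_model
  expect_error(project(profile_reference(), 80, 10, "urban", m,
                       default_rates), "coverage")
  expect_error(project(profile_reference(), 25, 3, "urban", m,
                       default_rates), "coverage")
  expect_error(project(profile_reference(), 40, -1, "urban", m,
                       default_rates), "positive")
  expect_error(project(profile_reference(), 40, 10, model = m,
                       table = default_rates), "residence")
})
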