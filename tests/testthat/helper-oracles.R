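# Independent oracles and small fixture builders shared across tests.
# Everything here recomputes quantities from first principles (direct table
# lookups, hand-written likelihoods, pair enumeration) so the tests never
# check the implementation against itself.

# Build a one-row profile with named overrides of the reference profile.
make_profile <- function(..., n = 1) {
  p <- profile_reference(n)
  lv <- rr_levels()
  over <- list(...)
  for (nm in names(over)) {
    p[[nm]] <- factor(rep(as.character(over[[nm]]), length.out = n),
                      levels = lv[[nm]])
  }
  p
}

# Direct rate lookup from the data frame, written independently of the
# package's band-index machinery.
oracle_rate_row <- function(table, residence, age) {
  df <- as.data.frame(table)
  i <- which(df$residence == residence & df$age_start <= age &
               age < df$age_start + df$age_width)
  stopifnot(length(i) == 1)
  df[i, ]
}

# Manual log-RR sum (no calls into relative_risk) for a one-row profile.
oracle_log_rr <- function(profile, age, model) {
  total <- 0
  for (p in names(model$predictors)) {
    pr <- model$predictors[[p]]
    lev <- as.character(profile[[p]][1])
    lr <- if (p == "bmi_category") {
      if (age < model$age_split) pr$log_rr$lt50 else pr$log_rr$ge50
    } else {
      pr$log_rr
    }
    total <- total + lr[[lev]]
  }
  total
}

# Fine-grid numerical integration of the absolute-risk integral with
# midpoint hazard evaluation (exact within each sub-step for constant
# hazards), default step 1/365 year.
oracle_project <- function(profile, a, tau, residence, model, table, pars,
                           step = 1 / 365) {
  # grid: 1/365-year steps, additionally split at every age where a hazard
  # may jump (band edges, the age split) so each sub-step carries exactly
  # constant hazards and the step-by-step integration of the risk integral
  # is exact
  jumps <- sort(unique(c(as.data.frame(table)$age_start, model$age_split)))
  grid <- sort(unique(c(seq(a, a + tau, by = step), a + tau,
                        jumps[jumps > a & jumps < a + tau])))
  widths <- diff(grid)
  keep <- widths > 1e-12
  widths <- widths[keep]
  mids <- (grid[-length(grid)] + grid[-1])[keep] / 2
  df <- as.data.frame(table)
  df <- df[df$residence == residence, ]
  df <- df[order(df$age_start), ]
  band <- findInterval(mids, df$age_start)
  stopifnot(all(band >= 1),
            all(mids < df$age_start[nrow(df)] + df$age_width[nrow(df)]))
  seg <- ifelse(mids < model$age_split, "lt50", "ge50")
  par_val <- unclass(pars)[paste(residence, seg, sep = "_")]
  rr_lt <- exp(oracle_log_rr(profile, model$age_split - 1, model))
  rr_ge <- exp(oracle_log_rr(profile, model$age_split, model))
  h1 <- df$bc_incidence_1e5[band] / 1e5 * (1 - par_val) *
    ifelse(seg == "lt50", rr_lt, rr_ge)
  h2 <- (df$all_cause_mortality_1e5[band] - df$bc_mortality_1e5[band]) / 1e5
  htot <- h1 + h2
  S_lag <- exp(-c(0, cumsum(htot * widths)[-length(widths)]))
  contrib <- ifelse(htot > 0, h1 / htot * (1 - exp(-htot * widths)), 0)
  sum(S_lag * contrib)
}

# Hand-written Cox partial log-likelihood (no ties expected in the inputs
# used): risk set at an event age t is {j : entry_j < t <= exit_j}.
oracle_partial_loglik <- function(beta, entry, exit, status, z) {
  ll <- 0
  for (i in which(status == 1)) {
    t <- exit[i]
    rs <- entry < t & exit >= t
    ll <- ll + beta * z[i] - log(sum(exp(beta * z[rs])))
  }
  ll
}

# Brute-force AUC by enumerating every case-control pair (ties count half).
oracle_auc <- function(predicted, status) {
  cases <- predicted[status]
  controls <- predicted[!status]
  tot <- 0
  for (x in cases) {
    tot <- tot + sum(x > controls) + 0.5 * sum(x == controls)
  }
  tot / (length(cases) * length(controls))
}

# Minimal single-stratum cohort: exponential event times with relative rate
# exp(beta * z), entry at age `entry`, administrative censoring at `cens`.
# Used by the fitting tests; independent of the package simulator.
sim_simple_cohort <- function(n, beta, base_rate, entry = 40, cens = 20,
                              p_z = 0.5) {
  z <- stats::rbinom(n, 1, p_z)
  t <- stats::rexp(n, rate = base_rate * exp(beta * z))
  exit <- entry + pmin(t, cens)
  data.frame(
    id = seq_len(n), entry_age = entry, exit_age = exit,
    event = ifelse(t < cens, "bc", "censored"),
    z = factor(z, levels = c(0, 1)),
    study_site = "s1", age_stratum = "40-44",
    stringsAsFactors = FALSE)
}

default_model <- rr_model_default()
default_rates <- rate_table_synthetic()
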