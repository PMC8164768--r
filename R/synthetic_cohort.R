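# Piecewise-exponential competing-risk cohort simulator. Covariates follow
# the published per-residence baseline marginals of the derivation cohort;
# event times are drawn by exact inversion from the same hazard definitions
# the projection uses - cause 1 with hazard h10(t) RR(x) (BMI/PAR switch at
# the age split) and cause 2 with hazard h2(t) - so the generator and the
# evaluator share one hazard pathway.

# Published baseline covariate marginals (percent) by residence, derivation
# columns. Normalised on use.
table1_marginals <- function() {
  list(
    rural = list(
      education = c(31.9, 40.3, 21.6, 5.6, 0.6),
      bmi_category = c(5.2, 53.8, 31.2, 9.9),
      height_category = c(29.4, 26.3, 24.1, 20.2),
      family_history = c(85.2, 13.0, 1.8),
      parity = c(0.8, 21.1, 38.6, 39.4),
      menarche_category = c(4.7, 26.3, 38.3, 30.6)
    ),
    urban = list(
      education = c(17.3, 20.4, 29.9, 23.2, 9.2),
      bmi_category = c(3.2, 46.6, 36.1, 14.0),
      height_category = c(19.3, 23.6, 26.1, 31.0),
      family_history = c(80.6, 16.8, 2.6),
      parity = c(1.9, 50.8, 23.6, 23.7),
      menarche_category = c(6.4, 30.3, 36.1, 27.2)
    )
  )
}

# Entry-age band mixture (percent at band starts 30..75) by residence.
table1_entry_age <- function() {
  list(
    rural = c(`30` = 2.4, `35` = 15.8, `40` = 18.3, `45` = 13.2, `50` = 17.6,
              `55` = 13.6, `60` = 8.9, `65` = 6.1, `70` = 3.7, `75` = 0.4),
    urban = c(`30` = 1.7, `35` = 11.6, `40` = 15.9, `45` = 14.2, `50` = 17.1,
              `55` = 13.5, `60` = 9.7, `65` = 9.1, `70` = 6.4, `75` = 0.8)
  )
}

# Null-effect nuisance predictors (considered but not retained in the final
# model), with published prevalences, so variable selection has true
# negatives to discard.
table1_nuisance <- function() {
  list(
    rural = list(
      smoking = c(never = 94.4, ever = 5.6),
      alcohol = c(never = 96.8, ever = 3.2),
      pill_use = c(never = 91.2, ever = 8.8),
      menopause = c(pre = 49.8, post = 50.2),
      breastfeeding = c(`0` = 2.2, `1-23.9` = 36.5, `24-35.9` = 17.4,
                        `36-47.9` = 14.2, `>=48` = 29.6)
    ),
    urban = list(
      smoking = c(never = 95.6, ever = 4.4),
      alcohol = c(never = 97.4, ever = 2.6),
      pill_use = c(never = 88.7, ever = 11.3),
      menopause = c(pre = 45.0, post = 55.0),
      breastfeeding = c(`0` = 6.3, `1-23.9` = 64.1, `24-35.9` = 12.1,
                        `36-47.9` = 7.0, `>=48` = 10.4)
    )
  )
}

#' Simulation configuration
#'
#' Defaults emulate the derivation cohort: the published per-residence
#' covariate marginals and entry-age mixture, a 55.5% rural / 44.5% urban
#' residence mix, five study sites per residence, a 10.2-year administrative
#' censoring horizon (single recruitment wave, so median follow-up equals the
#' horizon), the published relative risks as truth, the synthetic default
#' rate table, and the published PAR set.
#'
#' @param n Number of women.
#' @param seed Integer seed recorded in the output's provenance.
#' @param residence_mix Named probabilities for `rural` and `urban`.
#' @param marginals Per-residence categorical marginals for the six
#'   predictors (lists of probability vectors in level order).
#' @param entry_age_probs Per-residence probabilities over 5-year entry-age
#'   band starts; entry age is uniform within the band.
#' @param model True [rr_model()] generating cause-1 hazards.
#' @param table [rate_table()] supplying incidence and mortality.
#' @param pars [par_set()] used to deflate incidence (defaults to the
#'   model's).
#' @param admin_horizon Administrative censoring horizon in years; follow-up
#'   is also truncated at the rate table's coverage end.
#' @param rank_correlation Optional exchangeable Gaussian-copula correlation
#'   in (0, 1) coupling the six predictors (0 = independent marginals).
#' @param nuisance Generate the null-effect nuisance columns?
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n, seed = 1L,
                       residence_mix = c(rural = 0.555, urban = 0.445),
                       marginals = table1_marginals(),
                       entry_age_probs = table1_entry_age(),
                       model = rr_model_default(),
                       table = rate_table_synthetic(),
                       pars = NULL,
                       admin_horizon = 10.2,
                       rank_correlation = 0,
                       nuisance = TRUE) {
  stopifnot(n >= 1, admin_horizon > 0,
            rank_correlation >= 0, rank_correlation < 1)
  if (is.null(pars)) pars <- model$par
  if (is.null(pars)) stop("no PAR set: supply 'pars' or store one in 'model'")
  residence_mix <- residence_mix / sum(residence_mix)
  for (res in names(marginals)) {
    for (p in names(marginals[[res]])) {
      m <- marginals[[res]][[p]]
      if (any(m < 0) || abs(sum(m / sum(m)) - 1) > 1e-9) {
        stop("invalid marginal for ", res, "/", p)
      }
      if (abs(sum(m) - 1) > 1e-9) marginals[[res]][[p]] <- m / sum(m)
    }
  }
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 residence_mix = residence_mix, marginals = marginals,
                 entry_age_probs = entry_age_probs, model = model,
                 table = table, pars = par_set_validate(pars),
                 admin_horizon = admin_horizon,
                 rank_correlation = rank_correlation, nuisance = nuisance),
            class = "sim_config")
}

# Draw one categorical column from a marginal, optionally through a shared
# Gaussian factor (exchangeable copula) coupling the modelled predictors.
draw_categorical <- function(u, probs, levels) {
  idx <- findInterval(u, cumsum(probs / sum(probs)), left.open = TRUE) + 1L
  factor(levels[pmin(idx, length(levels))], levels = levels)
}

#' Sample covariates, entry ages and study sites
#'
#' Draws residence, study site (five per residence), entry age and the six
#' predictor categories from the configured marginals (independent per
#' predictor unless a copula correlation is set), plus the nuisance columns.
#' Deterministic given the configuration seed via [simulate_cohort()]; called
#' directly it uses the current RNG state.
#'
#' @param config A [sim_config()].
#' @return Data frame of baseline covariates (one row per woman).
#' @export
sample_covariates <- function(config) {
  n <- config$n
  lv <- rr_levels()
  residence <- sample(names(config$residence_mix), n, replace = TRUE,
                      prob = config$residence_mix)
  site <- paste0(residence, "_", sample.int(5, n, replace = TRUE))
  out <- data.frame(residence = residence, study_site = site,
                    stringsAsFactors = FALSE)
  # entry ages: band mixture, uniform within band
  entry <- numeric(n)
  for (res in unique(residence)) {
    sel <- residence == res
    pr <- config$entry_age_probs[[res]]
    starts <- as.numeric(names(pr))
    b <- starts[sample.int(length(starts), sum(sel), replace = TRUE,
                           prob = pr / sum(pr))]
    entry[sel] <- b + stats::runif(sum(sel), 0, 5)
  }
  out$entry_age <- entry
  # six predictors, optionally coupled through a shared Gaussian factor
  rho <- config$rank_correlation
  g <- if (rho > 0) stats::rnorm(n) else NULL
  for (p in rr_predictors()) {
    u <- if (rho > 0) {
      stats::pnorm(sqrt(rho) * g + sqrt(1 - rho) * stats::rnorm(n))
    } else {
      stats::runif(n)
    }
    x <- factor(rep(NA_character_, n), levels = lv[[p]])
    for (res in unique(residence)) {
      sel <- residence == res
      x[sel] <- draw_categorical(u[sel], config$marginals[[res]][[p]],
                                 lv[[p]])
    }
    out[[p]] <- x
  }
  if (isTRUE(config$nuisance)) {
    nuis <- table1_nuisance()
    for (p in names(nuis$rural)) {
      x <- character(n)
      for (res in unique(residence)) {
        sel <- residence == res
        pr <- nuis[[res]][[p]]
        x[sel] <- as.character(draw_categorical(stats::runif(sum(sel)), pr,
                                                names(pr)))
      }
      out[[p]] <- factor(x, levels = names(nuis$rural[[p]]))
    }
  }
  out$age_stratum <- age_band(out$entry_age)
  out
}

# Exact inversion for a piecewise-constant hazard on the global band grid:
# returns the absolute age at which the cumulative hazard from `entry` first
# reaches an Exp(1) draw (Inf if never within coverage).
piecewise_exp_draw <- function(entry, hmat, bounds, E) {
  n <- length(entry)
  Hprev <- numeric(n)
  t_event <- rep(Inf, n)
  done <- logical(n)
  for (k in seq_len(length(bounds) - 1)) {
    lo <- pmax(entry, bounds[k])
    w <- pmax(bounds[k + 1] - lo, 0)
    h <- hmat[, k]
    Hnext <- Hprev + h * w
    hit <- !done & w > 0 & h > 0 & E <= Hnext
    t_event[hit] <- lo[hit] + (E[hit] - Hprev[hit]) / h[hit]
    done <- done | hit
    Hprev <- Hnext
  }
  t_event
}

#' Simulate follow-up and events for sampled covariates
#'
#' Draws, for each woman, a breast-cancer time from the piecewise-exponential
#' distribution with hazard `h10(t) RR(x)` (PAR-deflated incidence times her
#' relative risk, with the BMI/PAR switch at the age split) and an
#' other-cause death time with hazard `h2(t)`; the earliest of the two and
#' administrative censoring (the configured horizon, truncated at rate-table
#' coverage) fixes the exit age and event label.
#'
#' @param covariates Output of [sample_covariates()].
#' @param config The same [sim_config()].
#' @return Cohort records: `id`, `entry_age`, `exit_age`,
#'   `event` (`"bc"`/`"death"`/`"censored"`), covariates and stratum labels.
#' @export
simulate_followup <- function(covariates, config) {
  n <- nrow(covariates)
  model <- config$model
  table <- config$table
  bounds <- sort(unique(c(rate_breakpoints(table), model$age_split)))
  mids <- (utils::head(bounds, -1) + bounds[-1]) / 2
  rr <- profile_rr_segments(covariates, model)
  h1 <- matrix(0, n, length(mids))
  h2 <- matrix(0, n, length(mids))
  for (k in seq_along(mids)) {
    base <- baseline_hazard(table, config$pars, covariates$residence,
                            rep(mids[k], n), age_split = model$age_split)
    h1[, k] <- base * (if (mids[k] < model$age_split) rr$lt50 else rr$ge50)
    h2[, k] <- competing_hazard(table, covariates$residence, rep(mids[k], n))
  }
  entry <- covariates$entry_age
  cov_end <- bounds[length(bounds)]
  t1 <- piecewise_exp_draw(entry, h1, bounds, stats::rexp(n))
  t2 <- piecewise_exp_draw(entry, h2, bounds, stats::rexp(n))
  tc <- entry + pmin(config$admin_horizon, cov_end - entry)
  exit <- pmin(t1, t2, tc)
  event <- ifelse(t1 <= exit & t1 <= t2, "bc",
                  ifelse(t2 <= exit, "death", "censored"))
  event[exit == tc & t1 > tc & t2 > tc] <- "censored"
  out <- cbind(data.frame(id = seq_len(n)), covariates)
  out$exit_age <- exit
  out$event <- event
  out
}

#' Simulate a complete cohort
#'
#' [sample_covariates()] followed by [simulate_followup()], run under the
#' configuration seed (the caller's RNG state is untouched). The seed and the
#' generator settings are attached as a `provenance` attribute.
#'
#' @param config A [sim_config()].
#' @return Cohort records (see [simulate_followup()]).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  out <- withr::with_seed(config$seed, {
    simulate_followup(sample_covariates(config), config)
  })
  attr(out, "provenance") <- list(
    seed = config$seed, n = config$n,
    admin_horizon = config$admin_horizon,
    rank_correlation = config$rank_correlation,
    generated = "synthetic-rates")
  out
}
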