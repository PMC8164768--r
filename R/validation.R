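# Calibration and discrimination machinery: expected case counts, E/O ratios
# with exact Poisson intervals, calibration deciles, 10-year AUC (overall and
# stratum-adjusted), quintile relative risks, and risk-stratified screening
# indices.

#' Expected breast-cancer cases
#'
#' Sums each record's projected probability from the enrollment age, overall
#' and per subgroup; the subgroup totals partition the overall total exactly.
#'
#' Two horizon rules are supported. `"followup"` (default) projects each
#' woman to her observed exit age - the rule used when validating against a
#' real cohort, where the potential censoring date is what it is. Because
#' events and competing deaths truncate observed follow-up, this expectation
#' equals the integral of `h1 * S^2` rather than `h1 * S` and so sits
#' slightly below the expected event count even under a perfectly specified
#' model (by roughly half the cohort's all-cause event fraction). A numeric
#' `horizon` instead projects every woman over her full potential follow-up
#' (clipped at rate-table coverage), which makes `E` the exact expectation of
#' the observed case count when the administrative horizon is known, as in a
#' simulated cohort.
#'
#' @param records Cohort records.
#' @param model An [rr_model()].
#' @param table A [rate_table()].
#' @param pars A [par_set()]; defaults to the model's.
#' @param by Optional name of a grouping column (or a factor of length
#'   `nrow(records)`).
#' @param horizon `"followup"` or a positive number of years of potential
#'   follow-up.
#' @return List with `total` (expected count), `risks` (per-record expected
#'   probabilities) and, when `by` is given, a data frame `by_group` of
#'   per-group expected counts.
#' @export
expected_cases <- function(records, model, table, pars = NULL, by = NULL,
                           horizon = "followup") {
  if (nrow(records) == 0) {
    return(list(total = 0, risks = numeric(0)))
  }
  tau <- records$exit_age - records$entry_age
  if (any(tau <= 0)) stop("each record needs exit_age > entry_age")
  risks <- predict_absolute_risk(records, model, table, pars,
                                 horizon = horizon)
  out <- list(total = sum(risks), risks = risks)
  if (!is.null(by)) {
    g <- if (is.character(by) && length(by) == 1) records[[by]] else by
    agg <- stats::aggregate(list(E = risks), by = list(group = g), FUN = sum)
    out$by_group <- agg
  }
  out
}

#' Expected/observed ratio with exact Poisson interval
#'
#' The calibration measure E/O with a confidence interval obtained by
#' treating the observed count as Poisson and inverting the exact
#' (chi-square-quantile) interval for its mean: the interval for E/O is
#' `(E / O_upper, E / O_lower)`. The exact interval reproduces published
#' subgroup intervals where a normal approximation drifts in the second
#' decimal.
#'
#' @param E Expected number of cases (positive real).
#' @param O Observed number of cases (positive integer).
#' @param level Confidence level (default 0.95).
#' @param label Optional subgroup label.
#' @return A one-row data frame (class `calibration_cell`) with `label`, `E`,
#'   `O`, `ratio`, `ci_low`, `ci_high` at full precision.
#' @examples
#' eo_ratio_ci(760, 751)  # ratio 1.01, CI 0.94-1.09
#' @export
eo_ratio_ci <- function(E, O, level = 0.95, label = "overall") {
  if (!is.finite(E) || E <= 0) stop("E must be positive")
  if (!is.finite(O) || O < 1 || O != round(O)) {
    stop("O must be a positive integer count")
  }
  alpha <- 1 - level
  o_low <- stats::qchisq(alpha / 2, 2 * O) / 2
  o_high <- stats::qchisq(1 - alpha / 2, 2 * (O + 1)) / 2
  structure(data.frame(label = label, E = E, O = O, ratio = E / O,
                       ci_low = E / o_high, ci_high = E / o_low,
                       stringsAsFactors = FALSE),
            class = c("calibration_cell", "data.frame"))
}

#' Calibration table over a cohort partition
#'
#' Expected and observed cases with E/O intervals, overall and per level of a
#' grouping column.
#'
#' @inheritParams expected_cases
#' @param by Grouping column name (or factor); omit for the overall row only.
#' @param level Confidence level.
#' @return Data frame of calibration cells (groups with zero observed cases
#'   are reported with `NA` ratio and interval).
#' @export
eo_table <- function(records, model, table, pars = NULL, by = NULL,
                     level = 0.95) {
  ec <- expected_cases(records, model, table, pars, by = by)
  obs <- records$event == "bc"
  rows <- list(eo_ratio_ci(ec$total, sum(obs), level, label = "overall"))
  if (!is.null(by)) {
    g <- if (is.character(by) && length(by) == 1) records[[by]] else by
    for (lev in levels(factor(g))) {
      sel <- g == lev
      O <- sum(obs[sel])
      E <- sum(ec$risks[sel])
      rows[[length(rows) + 1]] <- if (O >= 1) {
        eo_ratio_ci(E, O, level, label = lev)
      } else {
        data.frame(label = lev, E = E, O = O, ratio = NA_real_,
                   ci_low = NA_real_, ci_high = NA_real_)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Calibration across deciles of predicted risk
#'
#' Sorts subjects by predicted risk (stable order for ties), bins them into
#' near-equal sample deciles (bin sizes differ by at most 1), and reports per
#' bin the expected count (sum of predictions), observed count and E/O with
#' exact Poisson interval.
#'
#' @param predicted Predicted probabilities in \[0, 1\].
#' @param observed Logical or 0/1 outcomes.
#' @param bins Number of bins (default 10).
#' @param level Confidence level.
#' @return Data frame with one row per bin: `bin`, `n`, `mean_predicted`,
#'   `E`, `O`, `ratio`, `ci_low`, `ci_high`.
#' @export
calibration_deciles <- function(predicted, observed, bins = 10,
                                level = 0.95) {
  n <- length(predicted)
  stopifnot(length(observed) == n)
  if (n < bins) stop("need at least as many subjects as bins")
  if (any(predicted < 0 | predicted > 1)) {
    stop("predictions must lie in [0, 1]")
  }
  if (stats::var(predicted) == 0) {
    stop("constant predictions cannot be binned; use fewer bins or check ",
         "the model")
  }
  observed <- as.integer(observed)
  ord <- order(predicted)  # stable ties
  bin_id <- rep(seq_len(bins), times = diff(round(seq(0, n, length.out =
                                                        bins + 1))))
  out <- data.frame(bin = seq_len(bins), n = tabulate(bin_id, bins))
  pred_s <- predicted[ord]
  obs_s <- observed[ord]
  out$mean_predicted <- as.numeric(tapply(pred_s, bin_id, mean))
  out$E <- as.numeric(tapply(pred_s, bin_id, sum))
  out$O <- as.integer(tapply(obs_s, bin_id, sum))
  cells <- lapply(seq_len(bins), function(i) {
    if (out$O[i] >= 1) {
      eo_ratio_ci(out$E[i], out$O[i], level, label = as.character(i))
    } else {
      data.frame(ratio = NA_real_, ci_low = NA_real_, ci_high = NA_real_)
    }
  })
  out$ratio <- vapply(cells, function(c) c$ratio, numeric(1))
  out$ci_low <- vapply(cells, function(c) c$ci_low, numeric(1))
  out$ci_high <- vapply(cells, function(c) c$ci_high, numeric(1))
  out
}

#' Ten-year case/control status
#'
#' Eligibility for the fixed-horizon discrimination analyses: cases are women
#' diagnosed within `horizon` years of entry; controls are women event-free
#' with at least `horizon` years of follow-up (a diagnosis after the horizon
#' counts as control). Women censored - or, by default, dead of other causes -
#' before the horizon are excluded.
#'
#' @param records Cohort records.
#' @param horizon Years (default 10).
#' @param deaths_as_controls Treat other-cause deaths before the horizon as
#'   controls rather than excluding them.
#' @return Logical vector with `TRUE` (case), `FALSE` (control), `NA`
#'   (ineligible), aligned with `records`.
#' @export
ten_year_status <- function(records, horizon = 10,
                            deaths_as_controls = FALSE) {
  fu <- records$exit_age - records$entry_age
  case <- records$event == "bc" & fu <= horizon
  control <- fu >= horizon & !case
  if (deaths_as_controls) {
    control <- control | (records$event == "death" & fu < horizon)
  }
  status <- rep(NA, nrow(records))
  status[case] <- TRUE
  status[control] <- FALSE
  status
}

# Mann-Whitney AUC with ties counted half, via midranks.
auc_mann_whitney <- function(predicted, status) {
  n1 <- sum(status)
  n0 <- sum(!status)
  if (n1 == 0 || n0 == 0) {
    stop("AUC needs at least one case and one control")
  }
  r <- rank(predicted, ties.method = "average")
  (sum(r[status]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Ten-year AUC (c-statistic)
#'
#' Probability that a randomly chosen case carries a higher predicted risk
#' than a randomly chosen control, ties counted one half (Mann-Whitney form);
#' 0.5 is random classification, 1 perfect discrimination. The confidence
#' interval uses the Hanley-McNeil asymptotic variance.
#'
#' @param predicted Predicted 10-year risks.
#' @param status Logical (or 0/1) case status; `NA` entries (ineligible
#'   subjects) are dropped.
#' @param level Confidence level.
#' @return List with `auc`, `ci_low`, `ci_high`, `n_cases`, `n_controls`.
#' @export
auc_10yr <- function(predicted, status, level = 0.95) {
  keep <- !is.na(status)
  predicted <- predicted[keep]
  status <- as.logical(status[keep])
  auc <- auc_mann_whitney(predicted, status)
  n1 <- sum(status); n0 <- sum(!status)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  v <- (auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
          (n0 - 1) * (q2 - auc^2)) / (n1 * n0)
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(max(v, 0))
  list(auc = auc, ci_low = max(0, auc - half), ci_high = min(1, auc + half),
       n_cases = n1, n_controls = n0)
}

#' Stratum-adjusted AUC
#'
#' Discrimination after removing between-stratum separation (e.g. age band x
#' residence): within-stratum Mann-Whitney statistics are pooled with weights
#' proportional to each stratum's case x control pair count; strata lacking a
#' case or a control contribute nothing. With a single stratum this equals
#' [auc_10yr()] exactly.
#'
#' @param predicted Predicted risks.
#' @param status Logical case status (`NA` dropped).
#' @param strata Stratum labels aligned with `predicted`.
#' @return List with `auc`, `n_pairs` and the per-stratum table.
#' @export
adjusted_auc <- function(predicted, status, strata) {
  keep <- !is.na(status)
  predicted <- predicted[keep]
  status <- as.logical(status[keep])
  strata <- factor(strata[keep])
  per <- lapply(levels(strata), function(s) {
    sel <- strata == s
    n1 <- sum(status[sel]); n0 <- sum(!status[sel])
    if (n1 == 0 || n0 == 0) return(NULL)
    data.frame(stratum = s, auc = auc_mann_whitney(predicted[sel],
                                                   status[sel]),
               pairs = n1 * n0)
  })
  per <- do.call(rbind, per)
  if (is.null(per)) stop("no stratum contains both a case and a control")
  list(auc = sum(per$auc * per$pairs) / sum(per$pairs),
       n_pairs = sum(per$pairs), strata = per)
}

#' Relative risks across quintiles of predicted risk
#'
#' Cuts predicted risk at the validation sample's own quintile boundaries
#' (ties to the lower quintile), and estimates the hazard ratio of each upper
#' quintile versus the lowest by the stratified Cox fitter (strata: 5-year
#' entry-age band, and study site when present). The lowest quintile is the
#' reference with RR exactly 1.
#'
#' @param predicted Predicted risks, one per record.
#' @param records Cohort records aligned with `predicted`.
#' @param quantiles Number of groups (default 5).
#' @param level Confidence level.
#' @return Data frame with `quintile`, `cases`, `rr`, `ci_low`, `ci_high`.
#' @export
quintile_rr <- function(predicted, records, quantiles = 5, level = 0.95) {
  stopifnot(length(predicted) == nrow(records))
  br <- stats::quantile(predicted, probs = seq(0, 1, length.out =
                                                 quantiles + 1))
  grp <- findInterval(predicted, unique(br[-c(1, length(br))]),
                      left.open = TRUE) + 1L
  grp <- factor(grp, levels = seq_len(quantiles))
  cases <- tapply(records$event == "bc", grp, sum)
  cases[is.na(cases)] <- 0
  if (cases[1] < 1) stop("no events in the reference (lowest) quintile")
  rec <- records
  rec$.risk_group <- grp
  if (is.null(rec$study_site)) rec$study_site <- "all"
  fit <- fit_stratified_cox(rec, predictors = ".risk_group",
                            bmi_age_split = NULL)
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- stats::setNames(fit$coefficients$estimate, fit$coefficients$term)
  se <- stats::setNames(fit$coefficients$se, fit$coefficients$term)
  out <- data.frame(quintile = seq_len(quantiles),
                    cases = as.integer(cases),
                    rr = 1, ci_low = NA_real_, ci_high = NA_real_)
  for (q in 2:quantiles) {
    nm <- paste0(".risk_group=", q)
    if (nm %in% names(est)) {
      out$rr[q] <- exp(est[[nm]])
      out$ci_low[q] <- exp(est[[nm]] - z * se[[nm]])
      out$ci_high[q] <- exp(est[[nm]] + z * se[[nm]])
    }
  }
  out
}

#' Risk-stratified screening indices
#'
#' For each 10-year-risk cutoff, classifies `predicted >= cutoff` as
#' high-risk and reports the percent flagged, sensitivity, specificity,
#' positive and negative predictive values, and the number needed to screen
#' to find one case (NNS = 1/PPV). Cutoffs flagging nobody yield a row with
#' PPV and NNS marked `NA`.
#'
#' @param predicted Predicted 10-year risks.
#' @param status Logical case status (`NA` dropped).
#' @param cutoffs Risk thresholds in (0, 1); default the published
#'   0.4%-2% grid.
#' @return Data frame with one row per cutoff.
#' @export
screening_indices <- function(predicted, status,
                              cutoffs = seq(0.004, 0.02, by = 0.002)) {
  if (any(cutoffs <= 0 | cutoffs >= 1)) stop("cutoffs must lie in (0, 1)")
  keep <- !is.na(status)
  predicted <- predicted[keep]
  status <- as.logical(status[keep])
  n <- length(status)
  rows <- lapply(cutoffs, function(ct) {
    hi <- predicted >= ct
    tp <- sum(hi & status); fp <- sum(hi & !status)
    fn <- sum(!hi & status); tn <- sum(!hi & !status)
    ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    data.frame(cutoff = ct,
               pct_high_risk = (tp + fp) / n,
               sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               specificity = if (fp + tn > 0) tn / (fp + tn) else NA_real_,
               ppv = ppv,
               npv = if (fn + tn > 0) tn / (fn + tn) else NA_real_,
               nns = if (!is.na(ppv) && ppv > 0) 1 / ppv else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
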