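# Competing-risk absolute risk: the probability that a woman aged a with risk
# factors x develops breast cancer by age a + tau,
#
#   P(a, tau, x) = int_a^{a+tau} h1(t, x) exp[-int_a^t (h1(u, x) + h2(u)) du] dt
#
# with h1(t, x) = h10(t) RR(x) and h2(t) the competing mortality hazard.
# Both hazards are piecewise constant (5-year rate bands; BMI/PAR switch at
# the age split), so the integral is evaluated exactly piece by piece: a piece
# of width d with constant hazards contributes
# S * h1 / (h1 + h2) * (1 - exp(-(h1 + h2) d)), where S is the all-cause
# survival carried in from earlier pieces.

# Vectorised core over subjects: one pass over the global band partition.
# rr_lt50 / rr_ge50 are each subject's relative risks in the two age segments.
risk_piecewise <- function(a, tau, rr_lt50, rr_ge50, residence, table, pars,
                           age_split = 50, keep_pieces = FALSE) {
  n <- max(length(a), length(tau), length(rr_lt50), length(residence))
  a <- rep_len(a, n); tau <- rep_len(tau, n)
  rr_lt50 <- rep_len(rr_lt50, n); rr_ge50 <- rep_len(rr_ge50, n)
  residence <- rep_len(as.character(residence), n)
  if (any(tau <= 0)) stop("projection horizon tau must be positive")
  end <- a + tau
  bounds <- sort(unique(c(rate_breakpoints(table), age_split)))
  if (any(a < bounds[1] - 1e-12) || any(end > bounds[length(bounds)] + 1e-12)) {
    stop("projection interval outside rate-table coverage [", bounds[1], ", ",
         bounds[length(bounds)], ")")
  }
  P <- numeric(n)
  S <- rep(1, n)
  pieces <- if (keep_pieces) vector("list", length(bounds) - 1) else NULL
  for (k in seq_len(length(bounds) - 1)) {
    L <- bounds[k]; U <- bounds[k + 1]
    lo <- pmax(a, L); hi <- pmin(end, U)
    d <- pmax(hi - lo, 0)
    act <- d > 0
    if (!any(act)) next
    mid <- (L + U) / 2
    h1 <- baseline_hazard(table, pars, residence[act], rep(mid, sum(act)),
                          age_split = age_split) *
      (if (mid < age_split) rr_lt50[act] else rr_ge50[act])
    h2 <- competing_hazard(table, residence[act], rep(mid, sum(act)))
    htot <- h1 + h2
    f <- ifelse(htot > 0, h1 / htot * (1 - exp(-htot * d[act])), 0)
    P[act] <- P[act] + S[act] * f
    if (keep_pieces) {
      pieces[[k]] <- data.frame(start = lo[act], end = hi[act], h1 = h1,
                                h2 = h2, surv_in = S[act],
                                contribution = S[act] * f)
    }
    S[act] <- S[act] * exp(-htot * d[act])
  }
  if (keep_pieces) {
    attr(P, "pieces") <- do.call(rbind, pieces)
    attr(P, "survival") <- S
  }
  P
}

profile_rr_segments <- function(profile, model) {
  lp <- log_rr_pair(profile[rr_predictors()], model)
  list(lt50 = exp(lp$lt50), ge50 = exp(lp$ge50))
}

#' Project absolute breast-cancer risk
#'
#' Evaluates the competing-risk absolute risk over \[`a`, `a + tau`) for one
#' risk-factor profile by exact piecewise integration: the interval is
#' partitioned at every rate-band boundary and at the model's age split (where
#' both the BMI relative risk and the PAR segment switch), and each piece's
#' closed-form contribution is accumulated together with the all-cause
#' survival factor.
#'
#' @param profile One-row data frame of categorised risk factors
#'   (see [categorize()]).
#' @param a Starting age in years (within rate-table coverage).
#' @param tau Projection horizon in years (may be fractional);
#'   `a + tau` must stay within coverage.
#' @param residence `"urban"` or `"rural"`; taken from `profile$residence`
#'   when omitted.
#' @param model An [rr_model()].
#' @param table A [rate_table()].
#' @param pars A [par_set()]; defaults to the one stored in `model`.
#' @return Object of class `bc_projection`: list with `probability` and the
#'   `pieces` table (start, end, hazards, incoming survival, contribution).
#' @examples
#' m <- rr_model_default()
#' project(profile_reference(), a = 40, tau = 10, residence = "urban",
#'         model = m, table = rate_table_synthetic())
#' @export
project <- function(profile, a, tau, residence = NULL, model, table,
                    pars = NULL) {
  stopifnot(inherits(model, "rr_model"), nrow(profile) == 1)
  if (is.null(pars)) pars <- model$par
  if (is.null(pars)) stop("no PAR set: supply 'pars' or store one in the model")
  if (is.null(residence)) residence <- profile$residence
  if (is.null(residence)) stop("residence not given and absent from profile")
  rr <- profile_rr_segments(profile, model)
  P <- risk_piecewise(a, tau, rr$lt50, rr$ge50, residence, table, pars,
                      age_split = model$age_split, keep_pieces = TRUE)
  structure(list(probability = as.numeric(P), a = a, tau = tau,
                 residence = as.character(residence),
                 pieces = attr(P, "pieces"),
                 survival = as.numeric(attr(P, "survival"))),
            class = "bc_projection")
}

#' @export
print.bc_projection <- function(x, ...) {
  cat(sprintf("Absolute risk over [%g, %g) (%s): %.4f%%\n", x$a, x$a + x$tau,
              x$residence, 100 * x$probability))
  print(transform(x$pieces, h1 = signif(h1, 4), h2 = signif(h2, 4),
                  surv_in = signif(surv_in, 6),
                  contribution = signif(contribution, 6)), row.names = FALSE)
  invisible(x)
}

#' Ten-year absolute risk
#'
#' [project()] with a fixed 10-year horizon.
#' @inheritParams project
#' @return Numeric probability.
#' @export
ten_year_risk <- function(profile, a, residence = NULL, model, table,
                          pars = NULL) {
  project(profile, a, 10, residence, model, table, pars)$probability
}

#' Predicted absolute risk for every cohort record
#'
#' Vectorised projection across a cohort: for each record the risk is
#' projected from the entry age over either the record's own follow-up
#' (`horizon = "followup"`, i.e. `exit_age - entry_age`, the horizon used for
#' expected-case calibration) or a fixed horizon in years (e.g. `horizon = 10`
#' for the 10-year risk used in discrimination analyses). Horizons running
#' past rate-table coverage are clipped at the coverage end.
#'
#' @param records Cohort records with profile columns, `entry_age`,
#'   `exit_age`, `residence`.
#' @param model An [rr_model()].
#' @param table A [rate_table()].
#' @param pars A [par_set()]; defaults to the model's.
#' @param horizon `"followup"` or a positive number of years.
#' @return Numeric vector of probabilities, one per record.
#' @export
predict_absolute_risk <- function(records, model, table, pars = NULL,
                                  horizon = "followup") {
  if (is.null(pars)) pars <- model$par
  if (is.null(pars)) stop("no PAR set: supply 'pars' or store one in the model")
  rr <- profile_rr_segments(records, model)
  tau <- if (identical(horizon, "followup")) {
    records$exit_age - records$entry_age
  } else {
    stopifnot(is.numeric(horizon), horizon > 0)
    rep(horizon, nrow(records))
  }
  cov_end <- max(rate_breakpoints(table))
  tau <- pmin(tau, cov_end - records$entry_age)
  risk_piecewise(records$entry_age, tau, rr$lt50, rr$ge50, records$residence,
                 table, pars, age_split = model$age_split)
}
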