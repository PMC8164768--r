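# Population attributable risk via Bruzzi's case-distribution formula,
# PAR = 1 - sum_j p_j / RR_j, where p_j is the proportion of cases in joint
# exposure category j and RR_j the category's relative risk. Estimated
# separately in the four attained-age (< / >= 50) x residence groups because
# their risk-factor distributions differ.

#' Bruzzi population attributable risk
#'
#' @param p Proportions of cases per joint exposure category (non-negative,
#'   summing to 1).
#' @param rr Relative risk of each category versus the all-reference category
#'   (positive; the reference category has RR 1).
#' @return The attributable fraction `1 - sum(p / rr)`; 0 when all cases sit
#'   in categories with RR 1, and in \[0, 1) whenever all RR are at least 1.
#' @examples
#' bruzzi_par(c(0.5, 0.5), c(1, 2))  # 0.25
#' @export
bruzzi_par <- function(p, rr) {
  if (length(p) != length(rr)) stop("p and rr must have equal length")
  if (any(!is.finite(p)) || any(p < 0)) stop("case proportions must be >= 0")
  if (abs(sum(p) - 1) > 1e-8) stop("case proportions must sum to 1")
  if (any(!is.finite(rr)) || any(rr <= 0)) {
    stop("relative risks must be positive")
  }
  1 - sum(p / rr)
}

#' Joint case distribution of a cohort subgroup
#'
#' Cross-classifies breast-cancer cases by the full joint level combination of
#' the six predictors (built sparsely from observed cases only) and attaches
#' each combination's joint relative risk, using the BMI mapping of the given
#' age segment.
#'
#' @param cases Data frame of case records (profile columns present).
#' @param model An [rr_model()].
#' @param segment `"lt50"` or `"ge50"`: the attained-age segment whose BMI
#'   mapping applies.
#' @return Data frame with columns `category`, `n`, `p`, `rr`.
#' @export
case_distribution <- function(cases, model, segment = c("lt50", "ge50")) {
  segment <- match.arg(segment)
  if (nrow(cases) == 0) stop("no cases supplied")
  age_probe <- if (segment == "lt50") model$age_split - 1 else model$age_split
  rr <- relative_risk(cases[rr_predictors()], age_probe, model)
  key <- do.call(paste, c(lapply(cases[rr_predictors()], as.character),
                          sep = "|"))
  agg <- stats::aggregate(list(n = rep(1L, length(key))),
                          by = list(category = key), FUN = sum)
  rr_by_key <- tapply(rr, key, function(v) v[1])
  agg$p <- agg$n / sum(agg$n)
  agg$rr <- unname(rr_by_key[agg$category])
  agg
}

#' Estimate the four PARs from cohort cases
#'
#' For each of the four groups defined by residence (urban/rural) and attained
#' age at diagnosis (below / at-or-above the model's age split), builds the
#' joint case distribution of the six predictors and applies [bruzzi_par()]
#' with the segment-appropriate joint relative risks.
#'
#' @param records Cohort records (see [read_cohort()] / [simulate_cohort()]);
#'   cases are rows with `event == "bc"`, their attained age at diagnosis is
#'   `exit_age`.
#' @param model An [rr_model()].
#' @return A [par_set()].
#' @export
par_set_from_cohort <- function(records, model) {
  cases <- records[records$event == "bc", , drop = FALSE]
  seg <- ifelse(cases$exit_age < model$age_split, "lt50", "ge50")
  out <- c(urban_lt50 = NA_real_, urban_ge50 = NA_real_,
           rural_lt50 = NA_real_, rural_ge50 = NA_real_)
  for (res in c("urban", "rural")) {
    for (s in c("lt50", "ge50")) {
      grp <- cases[cases$residence == res & seg == s, , drop = FALSE]
      if (nrow(grp) == 0) {
        stop("no breast-cancer cases in group ", res, "/", s,
             "; cannot estimate its PAR")
      }
      cd <- case_distribution(grp, model, s)
      out[paste(res, s, sep = "_")] <- bruzzi_par(cd$p, cd$rr)
    }
  }
  par_set_validate(out)
}
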