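# Stratified Cox relative-risk fitting on the age timescale, plus the
# model-building steps used around it: follow-up splitting at the BMI age
# split, BIC cutoff selection, backward elimination, likelihood-ratio tests
# and the Schoenfeld proportional-hazards check.
#
# Fitting itself goes through survival::coxph with delayed entry
# (Surv(entry_age, exit_age, event)), so risk sets are formed by attained age
# with left truncation at enrollment, stratified jointly by study site and
# 5-year entry-age band (up to 100 strata). Efron's tie correction is the
# default because ages recorded near-annually produce heavy ties.

#' Five-year age band label
#' @param age Ages in years.
#' @param width Band width in years.
#' @return Character labels like `"50-54"`.
#' @export
age_band <- function(age, width = 5) {
  lo <- floor(age / width) * width
  sprintf("%d-%d", as.integer(lo), as.integer(lo + width - 1))
}

cohort_stratum <- function(records) {
  a <- if (!is.null(records$age_stratum)) records$age_stratum
       else age_band(records$entry_age)
  s <- if (!is.null(records$study_site)) records$study_site else "site"
  interaction(s, a, drop = TRUE, lex.order = TRUE)
}

#' Split follow-up episodes at an age
#'
#' Any record whose follow-up spans `split_age` becomes two contiguous
#' episodes: entry to the split (censored, carrying no event) and split to
#' exit (carrying the original event). Records not spanning the age pass
#' through unchanged; total person-time is conserved exactly. All other
#' columns (including the enrollment-age stratum) are carried along, so the
#' split changes risk-set bookkeeping only.
#'
#' @param records Cohort records.
#' @param split_age Age in years (default 50).
#' @return Records with spanning rows split.
#' @export
split_followup_at_age <- function(records, split_age = 50) {
  span <- records$entry_age < split_age & records$exit_age > split_age
  if (!any(span)) return(records)
  first <- records[span, , drop = FALSE]
  first$exit_age <- split_age
  first$event <- "censored"
  second <- records[span, , drop = FALSE]
  second$entry_age <- split_age
  out <- rbind(records[!span, , drop = FALSE], first, second)
  rownames(out) <- NULL
  out
}

# Design-matrix construction. Categorical predictors contribute reference-
# coded indicators; ordinal predictors a single per-step score. BMI, when an
# age split is in force, contributes two segment-specific blocks (episode
# segment decided by episode entry age); the segment main effect is absorbed
# by the Cox baseline, which matches reporting a separate reference RR of 1
# inside each segment.
build_cox_design <- function(records, predictors, encodings = NULL,
                             bmi_age_split = 50) {
  refs <- rr_references()
  X <- list()
  groups <- list()
  add_col <- function(name, values, predictor) {
    X[[name]] <<- as.numeric(values)
    groups[[predictor]] <<- c(groups[[predictor]], name)
  }
  segment_ge <- records$entry_age >= (bmi_age_split %||% Inf)
  for (p in predictors) {
    x <- records[[p]]
    if (is.null(x)) stop("predictor column '", p, "' not found in records")
    x <- factor(x)
    enc <- if (!is.null(encodings) && p %in% names(encodings)) {
      encodings[[p]]
    } else "categorical"
    if (p == "bmi_category" && !is.null(bmi_age_split)) {
      lev <- levels(x)
      ref <- refs[["bmi_category"]]
      if (enc == "ordinal") {
        score <- as.integer(x) - 1L
        add_col("bmi_lt50.score", score * !segment_ge, p)
        add_col("bmi_ge50.score", score * segment_ge, p)
      } else {
        for (l in setdiff(lev, ref)) {
          add_col(paste0("bmi_lt50=", l), (x == l) & !segment_ge, p)
          add_col(paste0("bmi_ge50=", l), (x == l) & segment_ge, p)
        }
      }
    } else if (enc == "ordinal") {
      add_col(paste0(p, ".score"), as.integer(x) - 1L, p)
    } else {
      ref <- if (p %in% names(refs)) refs[[p]] else levels(x)[1]
      for (l in setdiff(levels(x), ref)) {
        add_col(paste0(p, "=", l), x == l, p)
      }
    }
  }
  list(X = as.data.frame(X, check.names = FALSE, optional = TRUE),
       groups = groups)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the stratified Cox relative-risk model
#'
#' Maximises the stratified partial likelihood on the age timescale: risk sets
#' are formed by attained age within joint study-site x 5-year entry-age-band
#' strata, with left truncation at the entry age. When `bmi_category` is among
#' the predictors and `bmi_age_split` is non-NULL, follow-up is first split at
#' that age and BMI enters with segment-specific effects.
#'
#' @param records Cohort records (`entry_age`, `exit_age`, `event` in
#'   `c("bc", "death", "censored")`, predictor columns, optionally
#'   `study_site` and `age_stratum`).
#' @param predictors Character vector of predictor column names; defaults to
#'   the six model predictors.
#' @param encodings Optional named character vector, `"categorical"`
#'   (default) or `"ordinal"` per predictor.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param bmi_age_split Age for the BMI segment switch, or NULL for an
#'   age-constant BMI effect.
#' @return Object of class `bc_cox_fit`: coefficient table (estimate, SE,
#'   Wald z and p per parameter, tagged by predictor), maximised and null
#'   partial log-likelihoods, event and parameter counts, the underlying
#'   `coxph` fit, and the variance matrix.
#' @export
fit_stratified_cox <- function(records, predictors = rr_predictors(),
                               encodings = NULL,
                               ties = c("efron", "breslow"),
                               bmi_age_split = 50) {
  ties <- match.arg(ties)
  if ("bmi_category" %in% predictors && !is.null(bmi_age_split)) {
    records <- split_followup_at_age(records, bmi_age_split)
  }
  des <- build_cox_design(records, predictors, encodings, bmi_age_split)
  if (ncol(des$X) == 0) stop("empty design: no non-reference parameters")
  const <- vapply(des$X, function(v) stats::var(v) == 0, logical(1))
  if (any(const)) {
    stop("constant design column(s): ",
         paste(names(des$X)[const], collapse = ", "))
  }
  dd <- des$X
  dd$.entry <- records$entry_age
  dd$.exit <- records$exit_age
  dd$.status <- as.integer(records$event == "bc")
  dd$.stratum <- cohort_stratum(records)
  terms <- colnames(des$X)
  # Surv/strata must appear unqualified for coxph's specials detection
  fml <- stats::as.formula(paste(
    "Surv(.entry, .exit, .status) ~",
    paste(sprintf("`%s`", terms), collapse = " + "),
    "+ strata(.stratum)"))
  fit <- survival::coxph(fml, data = dd, ties = ties, x = FALSE, y = TRUE)
  if (!is.null(fit$fail)) stop("coxph failed: ", fit$fail)
  if (anyNA(stats::coef(fit))) {
    stop("non-estimable parameter(s) (separation or aliasing): ",
         paste(terms[is.na(stats::coef(fit))], collapse = ", "))
  }
  beta <- stats::coef(fit)
  se <- sqrt(diag(fit$var))
  pred_of_term <- rep(names(des$groups), lengths(des$groups))
  names(pred_of_term) <- unlist(des$groups)
  coefs <- data.frame(
    term = terms,
    predictor = unname(pred_of_term[terms]),
    estimate = unname(beta),
    se = se,
    z = unname(beta) / se,
    p = 2 * stats::pnorm(-abs(unname(beta) / se)),
    stringsAsFactors = FALSE)
  structure(list(coefficients = coefs,
                 loglik = fit$loglik[2], loglik_null = fit$loglik[1],
                 nevent = fit$nevent, df = length(beta), n = nrow(records),
                 ties = ties, groups = des$groups, vcov = fit$var,
                 predictors = predictors, encodings = encodings,
                 bmi_age_split = bmi_age_split, fit = fit),
            class = "bc_cox_fit")
}

#' @export
print.bc_cox_fit <- function(x, ...) {
  cat(sprintf("Stratified Cox fit: %d records, %d events, %d parameters, ",
              x$n, x$nevent, x$df))
  cat(sprintf("partial loglik %.3f (%s ties)\n", x$loglik, x$ties))
  tab <- x$coefficients
  tab$rr <- exp(tab$estimate)
  print(transform(tab[c("term", "rr", "estimate", "se", "p")],
                  rr = round(rr, 3), estimate = round(estimate, 4),
                  se = round(se, 4), p = signif(p, 3)), row.names = FALSE)
  invisible(x)
}

#' Per-predictor Wald test p-values
#'
#' Joint Wald chi-square test that all of a predictor's parameters are zero;
#' for a single-parameter predictor this reduces to the usual squared z test.
#' @param fit A [fit_stratified_cox()] result.
#' @return Named numeric vector of p-values, one per predictor.
#' @export
wald_group_p <- function(fit) {
  out <- vapply(names(fit$groups), function(g) {
    idx <- match(fit$groups[[g]], fit$coefficients$term)
    b <- fit$coefficients$estimate[idx]
    V <- fit$vcov[idx, idx, drop = FALSE]
    stat <- drop(t(b) %*% solve(V, b))
    stats::pchisq(stat, df = length(idx), lower.tail = FALSE)
  }, numeric(1))
  out
}

#' Likelihood-ratio test of nested Cox fits
#'
#' @param fit_full,fit_reduced Fits from [fit_stratified_cox()] (or any lists
#'   with elements `loglik` and `df`); the reduced model must be nested in the
#'   full one (strictly fewer parameters, same records).
#' @return List with `statistic` (twice the log-likelihood difference), `df`
#'   and `p_value`.
#' @export
likelihood_ratio_test <- function(fit_full, fit_reduced) {
  df <- fit_full$df - fit_reduced$df
  if (is.null(df) || !is.finite(df) || df <= 0) {
    stop("models are not nested: full model must have more parameters")
  }
  stat <- 2 * (fit_full$loglik - fit_reduced$loglik)
  stat <- max(stat, 0)  # guard against convergence-tolerance negatives
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Select category cutoffs by BIC
#'
#' Categorises a raw continuous variable under each candidate cutset, fits
#' the stratified Cox model with the resulting categorical predictor (plus
#' any fixed co-adjusted predictors), and returns the cutset minimising
#' `BIC = -2 loglik + k log(d)` with `k` the parameter count and `d` the
#' number of events (the effective sample size of a partial likelihood).
#' Ties break toward fewer parameters, then lexicographically. Candidates
#' producing an empty category are skipped with a warning.
#'
#' @param records Cohort records containing the raw column `variable`.
#' @param variable Name of the raw numeric column.
#' @param cutsets List of increasing numeric cutoff vectors; each cutset `c`
#'   defines the left-closed categories `(<c1), [c1,c2), ..., (>=ck)`.
#' @param predictors Additional predictor columns kept in every candidate fit.
#' @param ... Passed to [fit_stratified_cox()].
#' @return List with `best` (the chosen cutset), `categorized` (factor under
#'   the chosen cutset) and `table` (per-candidate k, loglik, BIC).
#' @export
select_cutoffs_bic <- function(records, variable, cutsets,
                               predictors = character(), ...) {
  if (length(cutsets) < 1) stop("need at least one candidate cutset")
  x <- records[[variable]]
  if (is.null(x) || !is.numeric(x)) {
    stop("'", variable, "' must be a numeric column of records")
  }
  res <- lapply(cutsets, function(cuts) {
    cuts <- sort(cuts)
    labels <- c(paste0("<", cuts[1]),
                if (length(cuts) > 1)
                  paste0(utils::head(cuts, -1), "-", cuts[-1]),
                paste0(">=", cuts[length(cuts)]))
    labels <- labels[seq_len(length(cuts) + 1)]
    f <- cut_left_closed(x, cuts, labels)
    if (any(table(f) == 0) || nlevels(f) < 2) return(NULL)
    rec <- records
    rec$.candidate <- f
    fit <- fit_stratified_cox(rec, c(".candidate", predictors), ...)
    list(cuts = cuts, fit = fit, k = fit$df,
         bic = -2 * fit$loglik + fit$df * log(fit$nevent))
  })
  skipped <- vapply(res, is.null, logical(1))
  if (any(skipped)) {
    warning("skipped candidate cutset(s) with empty categories: ",
            paste(which(skipped), collapse = ", "))
  }
  if (all(skipped)) stop("every candidate cutset produced an empty category")
  kept <- res[!skipped]
  tab <- data.frame(
    candidate = vapply(kept, function(r) paste(r$cuts, collapse = ","), ""),
    k = vapply(kept, function(r) r$k, numeric(1)),
    loglik = vapply(kept, function(r) r$fit$loglik, numeric(1)),
    bic = vapply(kept, function(r) r$bic, numeric(1)))
  ord <- order(tab$bic, tab$k, tab$candidate)
  best <- kept[[ord[1]]]
  list(best = best$cuts, fit = best$fit, table = tab[ord, ])
}

#' Backward elimination by Wald p-value
#'
#' Iteratively drops the predictor with the largest per-predictor Wald
#' p-value above `alpha` (joint test over all its parameters; optionally a
#' likelihood-ratio test instead) until every remaining predictor is
#' significant at `alpha`.
#'
#' @param records Cohort records.
#' @param predictors Starting predictor set.
#' @param alpha Retention level (default 0.05).
#' @param test `"wald"` (default) or `"lrt"` for the per-step predictor test.
#' @param ... Passed to [fit_stratified_cox()].
#' @return List with `retained`, `trace` (one row per removal with its
#'   p-value) and the final `fit` (NULL if everything was eliminated).
#' @export
backward_eliminate <- function(records, predictors, alpha = 0.05,
                               test = c("wald", "lrt"), ...) {
  test <- match.arg(test)
  trace <- data.frame(step = integer(), predictor = character(),
                      p_value = numeric(), stringsAsFactors = FALSE)
  current <- predictors
  step <- 0L
  fit <- NULL
  while (length(current) > 0) {
    fit <- fit_stratified_cox(records, current, ...)
    p <- if (test == "wald") {
      wald_group_p(fit)
    } else {
      vapply(current, function(g) {
        if (length(current) == 1) {
          stats::pchisq(2 * (fit$loglik - fit$loglik_null), df = fit$df,
                        lower.tail = FALSE)
        } else {
          red <- fit_stratified_cox(records, setdiff(current, g), ...)
          likelihood_ratio_test(fit, red)$p_value
        }
      }, numeric(1))
    }
    worst <- which.max(p)
    if (p[worst] <= alpha) break
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step,
                                     predictor = names(p)[worst],
                                     p_value = unname(p[worst])))
    current <- setdiff(current, names(p)[worst])
    fit <- NULL
  }
  if (length(current) > 0 && is.null(fit)) {
    fit <- fit_stratified_cox(records, current, ...)
  }
  list(retained = current, trace = trace, fit = fit)
}

#' Schoenfeld residual test of proportional hazards
#'
#' Tests, for each covariate, the association of its scaled Schoenfeld
#' residuals with event age (identity time transform, within strata), via
#' `survival::cox.zph`. A small p-value indicates a time-varying effect, as
#' found for BMI around age 50 in this model family.
#'
#' @param fit A [fit_stratified_cox()] result with at least 3 events.
#' @param transform Time transform passed to `cox.zph` (default identity, so
#'   the residuals are regressed on attained age itself).
#' @return Data frame with `term`, `chisq`, `df` and `p` per covariate.
#' @export
schoenfeld_ph_test <- function(fit, transform = "identity") {
  stopifnot(inherits(fit, "bc_cox_fit"))
  if (fit$nevent < 3) stop("need at least 3 events for the Schoenfeld test")
  z <- survival::cox.zph(fit$fit, transform = transform, global = FALSE)
  tab <- as.data.frame(z$table)
  data.frame(term = gsub("`", "", rownames(tab)), chisq = tab$chisq,
             df = tab$df, p = tab$p, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Build a relative-risk model from a categorical Cox fit
#'
#' Maps the fitted segmented-BMI categorical coefficients back onto the
#' [rr_model()] structure (reference levels exactly zero), so a fitted model
#' can be serialised and used in projection.
#'
#' @param fit A [fit_stratified_cox()] over the six standard predictors with
#'   categorical encoding and a BMI age split.
#' @param par Optional [par_set()] to store in the model.
#' @return An [rr_model()].
#' @export
rr_model_from_fit <- function(fit, par = NULL) {
  stopifnot(inherits(fit, "bc_cox_fit"))
  lv <- rr_levels()
  refs <- rr_references()
  beta <- stats::setNames(fit$coefficients$estimate, fit$coefficients$term)
  grab <- function(prefix, levels, ref) {
    out <- stats::setNames(numeric(length(levels)), levels)
    for (l in setdiff(levels, ref)) {
      nm <- paste0(prefix, "=", l)
      if (!nm %in% names(beta)) stop("fit lacks parameter '", nm, "'")
      out[l] <- beta[[nm]]
    }
    out
  }
  lr <- list(
    education = grab("education", lv$education, refs[["education"]]),
    bmi_category = list(
      lt50 = grab("bmi_lt50", lv$bmi_category, refs[["bmi_category"]]),
      ge50 = grab("bmi_ge50", lv$bmi_category, refs[["bmi_category"]])),
    height_category = grab("height_category", lv$height_category,
                           refs[["height_category"]]),
    family_history = grab("family_history", lv$family_history,
                          refs[["family_history"]]),
    parity = grab("parity", lv$parity, refs[["parity"]]),
    menarche_category = grab("menarche_category", lv$menarche_category,
                             refs[["menarche_category"]])
  )
  rr_model(lr, age_split = fit$bmi_age_split %||% 50, par = par)
}
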