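# Relative-risk model: categorisation of raw covariates and evaluation of the
# multiplicative relative risk RR(x) at an attained age.
#
# The model is a per-predictor table of log relative risks over fixed ordered
# categories, with body-mass index carrying two mappings switched at an age
# split (default 50): BMI is inversely (and non-significantly) related to risk
# before the split and positively after it, so a single age-constant RR would
# violate proportional hazards.

#' Predictor names used by the relative-risk model
#'
#' The six modelled risk factors, in canonical order: education, BMI category,
#' height category, number of first-degree relatives with cancer, parity, and
#' age-at-menarche category.
#' @export
rr_predictors <- function() {
  c("education", "bmi_category", "height_category",
    "family_history", "parity", "menarche_category")
}

#' Category levels for each predictor
#'
#' Levels are ordered from the printed lowest category upward; the reference
#' level of each predictor is the lowest-risk category (last level for parity
#' and menarche, first level otherwise).
#' @return Named list of character vectors.
#' @export
rr_levels <- function() {
  list(
    education = c("no formal school", "primary school", "middle school",
                  "high school", "college/university"),
    bmi_category = c("<18.5", "18.5-23.9", "24.0-27.9", ">=28"),
    height_category = c("<150.2", "150.2-154.1", "154.2-158.1", ">=158.2"),
    family_history = c("0", "1", ">=2"),
    parity = c("nulliparous", "1", "2", ">=3"),
    menarche_category = c("<=12", "13-14", "15-16", ">=17")
  )
}

rr_references <- function() {
  c(education = "no formal school", bmi_category = "<18.5",
    height_category = "<150.2", family_history = "0",
    parity = ">=3", menarche_category = ">=17")
}

#' Construct a relative-risk model
#'
#' @param log_rr Named list with one named numeric vector of log relative
#'   risks per predictor (full level set, reference exactly 0). For
#'   `bmi_category` supply a list with elements `lt50` and `ge50`, the
#'   mappings used below and at/above `age_split`.
#' @param encoding Named character vector, `"categorical"` or `"ordinal"` per
#'   predictor (metadata describing how the log-RRs were estimated; evaluation
#'   is always by table lookup).
#' @param age_split Age in years at which the BMI mapping switches.
#' @param par Optional PAR set (see [par_set()]) stored with the model.
#' @param metadata Optional list (e.g. confidence intervals); never used in
#'   projection.
#' @return An object of class `rr_model`.
#' @seealso [rr_model_default()], [relative_risk()], [read_rr_model()]
#' @export
rr_model <- function(log_rr, encoding = NULL, age_split = 50, par = NULL,
                     metadata = list()) {
  levels <- rr_levels()
  refs <- rr_references()
  preds <- rr_predictors()
  if (!setequal(names(log_rr), preds)) {
    stop("log_rr must have exactly the predictors: ",
         paste(preds, collapse = ", "))
  }
  if (is.null(encoding)) {
    encoding <- stats::setNames(rep("categorical", length(preds)), preds)
  }
  predictors <- lapply(preds, function(p) {
    lr <- log_rr[[p]]
    if (p == "bmi_category") {
      if (!is.list(lr) || !all(c("lt50", "ge50") %in% names(lr))) {
        stop("bmi_category log_rr must be a list with elements lt50 and ge50")
      }
      lr <- lapply(lr[c("lt50", "ge50")], check_log_rr_vec,
                   levels = levels[[p]], ref = refs[[p]], predictor = p)
    } else {
      lr <- check_log_rr_vec(lr, levels[[p]], refs[[p]], p)
    }
    list(levels = levels[[p]], log_rr = lr, reference = refs[[p]],
         encoding = match.arg(encoding[[p]], c("categorical", "ordinal")))
  })
  names(predictors) <- preds
  if (!is.null(par)) par <- par_set_validate(par)
  structure(list(predictors = predictors, age_split = age_split, par = par,
                 metadata = metadata),
            class = "rr_model")
}

check_log_rr_vec <- function(lr, levels, ref, predictor) {
  if (is.null(names(lr)) || !setequal(names(lr), levels)) {
    stop("log_rr for '", predictor, "' must be named with levels: ",
         paste(levels, collapse = ", "))
  }
  lr <- lr[levels]
  if (!all(is.finite(lr))) {
    stop("non-finite log relative risk for '", predictor, "'")
  }
  if (lr[[ref]] != 0) {
    stop("reference level '", ref, "' of '", predictor,
         "' must have log relative risk exactly 0")
  }
  lr
}

#' Default relative-risk model
#'
#' The shipped model: published point-estimate hazard ratios for the six
#' predictors from a 300,824-woman prospective Chinese cohort (education,
#' BMI with an age-50 split, height, family history of any cancer, parity,
#' age at menarche), stored as log relative risks with exact-zero references,
#' together with the four published population attributable risks
#' (urban/rural x below/at-or-above age 50). Confidence intervals are carried
#' as metadata only.
#'
#' @return An `rr_model`.
#' @export
rr_model_default <- function() {
  lr <- list(
    education = log(c("no formal school" = 1, "primary school" = 1.17,
                      "middle school" = 1.37, "high school" = 1.60,
                      "college/university" = 1.87)),
    bmi_category = list(
      lt50 = log(c("<18.5" = 1, "18.5-23.9" = 0.95, "24.0-27.9" = 0.90,
                   ">=28" = 0.85)),
      ge50 = log(c("<18.5" = 1, "18.5-23.9" = 1.25, "24.0-27.9" = 1.57,
                   ">=28" = 1.96))
    ),
    height_category = log(c("<150.2" = 1, "150.2-154.1" = 1.13,
                            "154.2-158.1" = 1.28, ">=158.2" = 1.45)),
    family_history = log(c("0" = 1, "1" = 1.10, ">=2" = 1.57)),
    parity = log(c("nulliparous" = 1.78, "1" = 1.66, "2" = 1.41, ">=3" = 1)),
    menarche_category = log(c("<=12" = 1.52, "13-14" = 1.32, "15-16" = 1.15,
                              ">=17" = 1))
  )
  ci <- list(
    education = c("1", "1.11-1.23", "1.24-1.51", "1.39-1.85", "1.54-2.27"),
    bmi_category = list(lt50 = c("1", "0.84-1.07", "0.71-1.14", "0.60-1.21"),
                        ge50 = c("1", "1.17-1.33", "1.38-1.78", "1.62-2.38")),
    height_category = c("1", "1.09-1.18", "1.18-1.39", "1.28-1.65"),
    family_history = c("1", "0.99-1.23", "1.27-1.95"),
    parity = c("1.29-2.45", "1.40-1.96", "1.22-1.62", "1"),
    menarche_category = c("1.31-1.76", "1.20-1.46", "1.09-1.21", "1")
  )
  rr_model(lr, age_split = 50, par = par_set_default(),
           metadata = list(rr_ci_95 = ci))
}

#' @export
print.rr_model <- function(x, ...) {
  cat("Relative-risk model (multiplicative, age split at",
      x$age_split, "years)\n")
  for (p in names(x$predictors)) {
    pr <- x$predictors[[p]]
    if (p == "bmi_category") {
      cat(sprintf("  %-18s RR <%d: %s | RR >=%d: %s\n", p, x$age_split,
                  paste(sprintf("%.2f", exp(pr$log_rr$lt50)), collapse = ", "),
                  x$age_split,
                  paste(sprintf("%.2f", exp(pr$log_rr$ge50)), collapse = ", ")))
    } else {
      cat(sprintf("  %-18s RR: %s\n", p,
                  paste(sprintf("%.2f", exp(pr$log_rr)), collapse = ", ")))
    }
  }
  if (!is.null(x$par)) {
    cat("  PAR:", paste(sprintf("%s=%.2f", names(x$par), x$par),
                        collapse = ", "), "\n")
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# Categorisation of raw covariates

# Left-closed, right-open boundaries on the printed lower bounds. Printed
# integer labels with gaps (e.g. menarche "<=12" then "13-14") close the gap
# downward so the partition over the plausible range is exhaustive.
category_breaks <- function() {
  list(
    bmi = c(18.5, 24.0, 28.0),
    height_cm = c(150.2, 154.2, 158.2),
    menarche_age = c(13, 15, 17),
    parity = c(1, 2, 3),
    family_history = c(1, 2)
  )
}

plausible_ranges <- function() {
  list(bmi = c(10, 60), height_cm = c(100, 200), menarche_age = c(8, 25),
       parity = c(0, 15), family_history = c(0, 15))
}

cut_left_closed <- function(x, breaks, labels) {
  idx <- findInterval(x, breaks, left.open = FALSE) + 1L
  factor(labels[idx], levels = labels)
}

check_plausible <- function(x, field) {
  rng <- plausible_ranges()[[field]]
  bad <- which(!is.finite(x) | x < rng[1] | x > rng[2])
  if (length(bad) > 0) {
    stop("implausible value for '", field, "' (allowed ", rng[1], "-", rng[2],
         ") in row(s): ", paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ..." else "")
  }
  invisible(x)
}

#' Categorise raw covariates into risk-factor profiles
#'
#' Maps raw numeric covariates (BMI in kg/m2, height in cm, age at menarche
#' in years, parity as live births, family history as a count of affected
#' first-degree relatives) onto the model's ordered categories. Boundaries
#' are left-closed / right-open on the printed lower bounds, so BMI 24.0 falls
#' in "24.0-27.9" and height 158.2 in ">=158.2". Already-categorised columns
#' (e.g. a `bmi_category` column with valid levels) pass through unchanged,
#' making the operation idempotent.
#'
#' @param raw Data frame with some of: `education` (level label),
#'   `bmi`/`bmi_category`, `height_cm`/`height_category`,
#'   `menarche_age`/`menarche_category`, `parity`, `family_history`. Other
#'   columns pass through.
#' @return Data frame with the six categorical profile columns as factors,
#'   plus all pass-through columns.
#' @export
categorize <- function(raw) {
  out <- raw
  lv <- rr_levels()
  br <- category_breaks()

  recode_num <- function(col_raw, col_cat, levels, breaks) {
    if (col_cat %in% names(out)) {
      out[[col_cat]] <<- as_profile_factor(out[[col_cat]], levels, col_cat)
    } else if (col_raw %in% names(out)) {
      x <- out[[col_raw]]
      check_plausible(x, col_raw)
      out[[col_cat]] <<- cut_left_closed(x, breaks, levels)
      out[[col_raw]] <<- NULL
    } else {
      stop("missing covariate: need '", col_raw, "' or '", col_cat, "'")
    }
  }

  if ("education" %in% names(out)) {
    out$education <- as_profile_factor(out$education, lv$education, "education")
  } else stop("missing covariate: need 'education'")
  recode_num("bmi", "bmi_category", lv$bmi_category, br$bmi)
  recode_num("height_cm", "height_category", lv$height_category, br$height_cm)
  recode_num("menarche_age", "menarche_category", lv$menarche_category,
             br$menarche_age)

  # parity / family history: counts or already-labelled categories
  recode_count <- function(col, levels, breaks) {
    x <- out[[col]]
    if (is.null(x)) stop("missing covariate: need '", col, "'")
    if (is.numeric(x)) {
      check_plausible(x, col)
      out[[col]] <<- cut_left_closed(x, breaks, levels)
    } else {
      out[[col]] <<- as_profile_factor(x, levels, col)
    }
  }
  recode_count("parity", lv$parity, br$parity)
  recode_count("family_history", lv$family_history, br$family_history)
  out
}

as_profile_factor <- function(x, levels, field) {
  f <- factor(as.character(x), levels = levels)
  if (anyNA(f) && !all(is.na(x) == is.na(f))) {
    bad <- unique(as.character(x)[is.na(f) & !is.na(x)])
    stop("invalid level(s) for '", field, "': ",
         paste(utils::head(bad, 5), collapse = ", "),
         "; expected one of: ", paste(levels, collapse = ", "))
  }
  if (anyNA(f)) stop("missing value in '", field, "'")
  f
}

# ---------------------------------------------------------------------------
# Evaluation

# Per-subject log RR sums for both BMI age segments; the workhorse shared by
# projection, simulation and PAR estimation.
log_rr_pair <- function(profile, model) {
  n <- nrow(profile)
  base <- numeric(n)
  for (p in setdiff(rr_predictors(), "bmi_category")) {
    pr <- model$predictors[[p]]
    base <- base + lookup_log_rr(profile[[p]], pr$log_rr, p)
  }
  bmi <- model$predictors$bmi_category
  list(
    lt50 = base + lookup_log_rr(profile$bmi_category, bmi$log_rr$lt50,
                                "bmi_category"),
    ge50 = base + lookup_log_rr(profile$bmi_category, bmi$log_rr$ge50,
                                "bmi_category")
  )
}

lookup_log_rr <- function(x, table, predictor) {
  if (is.null(x)) stop("profile is missing predictor '", predictor, "'")
  v <- table[as.character(x)]
  if (anyNA(v)) {
    bad <- unique(as.character(x)[is.na(v)])
    stop("level(s) absent from model for '", predictor, "': ",
         paste(utils::head(bad, 3), collapse = ", "))
  }
  unname(v)
}

#' Evaluate the relative risk RR(x) at an attained age
#'
#' Multiplies the per-predictor relative risks of a profile; all predictors
#' are age-constant except BMI, whose mapping switches at the model's age
#' split (attained ages below the split use the early-adult mapping, ages at
#' or above it the later one). An all-reference profile returns exactly 1.
#'
#' @param profile Data frame of categorised profiles (see [categorize()]);
#'   recycled against `attained_age`.
#' @param attained_age Numeric vector of ages in years.
#' @param model An [rr_model()].
#' @return Numeric vector of relative risks (positive).
#' @examples
#' m <- rr_model_default()
#' p <- profile_reference()
#' relative_risk(p, 45, m)  # 1
#' @export
relative_risk <- function(profile, attained_age, model) {
  stopifnot(inherits(model, "rr_model"))
  lp <- log_rr_pair(profile, model)
  n <- max(nrow(profile), length(attained_age))
  lt <- rep_len(lp$lt50, n)
  ge <- rep_len(lp$ge50, n)
  age <- rep_len(attained_age, n)
  exp(ifelse(age < model$age_split, lt, ge))
}

#' All-reference risk-factor profile
#'
#' @param n Number of rows.
#' @return Data frame with every predictor at its reference level.
#' @export
profile_reference <- function(n = 1) {
  refs <- rr_references()
  lv <- rr_levels()
  out <- lapply(rr_predictors(), function(p) {
    factor(rep(refs[[p]], n), levels = lv[[p]])
  })
  names(out) <- rr_predictors()
  as.data.frame(out, stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# Serialization: JSON with explicit references, storing log RRs so the
# reference is exactly zero after a round trip.

#' Write a relative-risk model to JSON
#'
#' @param model An [rr_model()].
#' @param path Output file path.
#' @export
write_rr_model <- function(model, path) {
  preds <- lapply(names(model$predictors), function(p) {
    pr <- model$predictors[[p]]
    list(name = p, encoding = pr$encoding, levels = pr$levels,
         log_rr = pr$log_rr, reference = pr$reference)
  })
  obj <- list(predictors = preds, bmi_age_split = model$age_split)
  if (!is.null(model$par)) obj$par <- as.list(model$par)
  if (length(model$metadata)) obj$metadata <- model$metadata
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a relative-risk model from JSON
#'
#' Applies strict validation: all six predictors present with full level
#' sets, finite log relative risks, exact-zero references, and both BMI age
#' segments.
#'
#' @param path JSON file written by [write_rr_model()] (or hand-authored to
#'   the same schema).
#' @return An [rr_model()].
#' @export
read_rr_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$predictors) || is.null(obj$bmi_age_split)) {
    stop("model JSON must have fields 'predictors' and 'bmi_age_split'")
  }
  log_rr <- list()
  encoding <- character()
  for (pr in obj$predictors) {
    for (f in c("name", "encoding", "levels", "log_rr", "reference")) {
      if (is.null(pr[[f]])) stop("model JSON predictor missing field '", f, "'")
    }
    lvl <- unlist(pr$levels)
    if (pr$name == "bmi_category") {
      log_rr[[pr$name]] <- lapply(pr$log_rr, function(v) {
        stats::setNames(unlist(v), lvl)
      })
    } else {
      log_rr[[pr$name]] <- stats::setNames(unlist(pr$log_rr), lvl)
    }
    encoding[pr$name] <- pr$encoding
  }
  par <- if (!is.null(obj$par)) unlist(obj$par) else NULL
  metadata <- if (!is.null(obj$metadata)) obj$metadata else list()
  rr_model(log_rr, encoding = encoding, age_split = obj$bmi_age_split,
           par = par, metadata = metadata)
}
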