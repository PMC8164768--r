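# Cohort file IO, derivation/test splitting, and the pipeline orchestrator
# tying fitting, PAR estimation, projection and validation together.

cohort_event_codes <- c("bc", "death", "censored")

#' Read a cohort CSV
#'
#' Schema: `id, entry_age, exit_age, event {bc,death,censored}, education,
#' bmi, height_cm, family_history, parity, menarche_age, study_site,
#' residence {urban,rural}` with a header; ages in decimal years. Raw
#' numeric covariate columns may equivalently be supplied already
#' categorised (`bmi_category`, `height_category`, `menarche_category`).
#' Malformed rows (non-numeric or inverted ages, unknown event or residence
#' codes) raise an error naming the row; rows with physiologically
#' implausible covariate values are excluded with a logged count, mirroring
#' the exclusion flow of cohort cleaning.
#'
#' @param path CSV file.
#' @param quiet Suppress the exclusion log message.
#' @return Validated cohort records with categorised profile columns and a
#'   derived `age_stratum` (5-year entry-age band).
#' @export
read_cohort <- function(path, quiet = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need_fixed <- c("id", "entry_age", "exit_age", "event", "education",
                  "study_site", "residence", "parity", "family_history")
  miss <- setdiff(need_fixed, names(df))
  pairs <- list(c("bmi", "bmi_category"), c("height_cm", "height_category"),
                c("menarche_age", "menarche_category"))
  for (pr in pairs) {
    if (!any(pr %in% names(df))) miss <- c(miss, paste(pr, collapse = "|"))
  }
  if (length(miss)) {
    stop("cohort CSV missing column(s): ", paste(miss, collapse = ", "))
  }
  df$.row <- seq_len(nrow(df))
  bad <- !is.finite(df$entry_age) | !is.finite(df$exit_age) |
    df$entry_age >= df$exit_age
  if (any(bad)) {
    stop("malformed entry/exit ages (need entry_age < exit_age) in row(s): ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  }
  if (!all(df$event %in% cohort_event_codes)) {
    bad <- which(!df$event %in% cohort_event_codes)
    stop("unknown event code in row(s): ",
         paste(utils::head(bad, 5), collapse = ", "),
         " (expected bc, death or censored)")
  }
  if (!all(df$residence %in% c("urban", "rural"))) {
    bad <- which(!df$residence %in% c("urban", "rural"))
    stop("unknown residence in row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  # exclude implausible raw covariate values (logged, not fatal)
  rng <- plausible_ranges()
  implausible <- rep(FALSE, nrow(df))
  reasons <- character()
  for (cn in intersect(names(rng), names(df))) {
    x <- df[[cn]]
    if (!is.numeric(x)) next
    bad <- !is.finite(x) | x < rng[[cn]][1] | x > rng[[cn]][2]
    if (any(bad)) reasons <- c(reasons, sprintf("%s: %d", cn, sum(bad)))
    implausible <- implausible | bad
  }
  if (any(implausible) && !quiet) {
    message("read_cohort: excluded ", sum(implausible),
            " record(s) with implausible values (",
            paste(reasons, collapse = "; "), ")")
  }
  df <- df[!implausible, , drop = FALSE]
  out <- categorize(df)
  out$event <- as.character(out$event)
  out$age_stratum <- age_band(out$entry_age)
  out$.row <- NULL
  rownames(out) <- NULL
  out
}

#' Write a cohort CSV
#'
#' Writes the categorised interchange form (category labels in the covariate
#' columns), which [read_cohort()] accepts unchanged; identical records give
#' byte-identical files.
#' @param records Cohort records.
#' @param path Output path.
#' @export
write_cohort <- function(records, path) {
  cols <- c("id", "entry_age", "exit_age", "event", "education",
            "bmi_category", "height_category", "family_history", "parity",
            "menarche_category", "study_site", "residence")
  extra <- setdiff(names(records), c(cols, "age_stratum"))
  df <- as.data.frame(records)[c(cols, extra)]
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Random derivation/test split
#'
#' Disjoint exhaustive partition, reproducible by seed; the derivation part
#' gets `floor(fraction * n)` records.
#'
#' @param records Cohort records.
#' @param fraction Derivation fraction in (0, 1); default two-thirds.
#' @param seed Integer seed.
#' @return List with `derivation` and `test`.
#' @export
split_derivation_test <- function(records, fraction = 2 / 3, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  n <- nrow(records)
  k <- floor(fraction * n)
  idx <- withr::with_seed(seed, sample.int(n, k))
  list(derivation = records[sort(idx), , drop = FALSE],
       test = records[setdiff(seq_len(n), sort(idx)), , drop = FALSE])
}

#' Pipeline configuration
#'
#' @param cohort Cohort records, a cohort CSV path, or NULL to simulate from
#'   `sim`.
#' @param sim A [sim_config()] (used when `cohort` is NULL).
#' @param rates A [rate_table()] or rate CSV path.
#' @param model An [rr_model()], a model JSON path, or NULL to fit the model
#'   on the derivation subcohort.
#' @param split_fraction Derivation fraction (default two-thirds).
#' @param split_seed Seed for the split.
#' @param stages Stages to run, a subset of `c("fit", "par", "validate")`.
#' @param eliminate Run backward elimination in the fit stage?
#' @param cutoffs Screening cutoffs.
#' @param outdir Optional output directory for the JSON report and
#'   calibration CSV.
#' @param rounding Decimals for the rendered text (full precision is kept in
#'   the returned object and JSON).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = NULL, sim = NULL, rates =
                              rate_table_synthetic(), model = NULL,
                            split_fraction = 2 / 3, split_seed = 1L,
                            stages = c("fit", "par", "validate"),
                            eliminate = FALSE,
                            cutoffs = seq(0.004, 0.02, by = 0.002),
                            outdir = NULL, rounding = 2) {
  stopifnot(split_fraction > 0, split_fraction < 1)
  bad <- setdiff(stages, c("fit", "par", "validate"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(list(cohort = cohort, sim = sim, rates = rates, model = model,
                 split_fraction = split_fraction, split_seed = split_seed,
                 stages = stages, eliminate = eliminate, cutoffs = cutoffs,
                 outdir = outdir, rounding = rounding),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields map directly onto [pipeline_config()] arguments; `cohort`,
#' `rates` and `model` are file paths. Requires the `yaml` package.
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading YAML configs requires the 'yaml' package")
  }
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

stage_wrap <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' Orchestrates: read-or-simulate the cohort, derivation/test split, Cox fit
#' on the derivation subcohort (optionally with backward elimination), PAR
#' estimation, and the validation suite (E/O overall and by the standard
#' subgroups, calibration deciles, 10-year and stratum-adjusted AUC, quintile
#' RRs, screening indices) on the test subcohort. Deterministic given the
#' configuration seeds; with `outdir` set, writes `report.json` and
#' `calibration_deciles.csv`.
#'
#' @param config A [pipeline_config()].
#' @return Report list (invisibly when writing to `outdir`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  rates <- if (is.character(config$rates)) {
    stage_wrap("rates", read_rate_table(config$rates))
  } else config$rates
  records <- stage_wrap("cohort", {
    if (is.null(config$cohort)) {
      if (is.null(config$sim)) stop("need a cohort or a sim config")
      simulate_cohort(config$sim)
    } else if (is.character(config$cohort)) {
      read_cohort(config$cohort)
    } else config$cohort
  })
  parts <- split_derivation_test(records, config$split_fraction,
                                 config$split_seed)
  report <- list(
    provenance = list(
      package_version = as.character(utils::packageVersion("bcarisk")),
      n_records = nrow(records),
      n_events = unname(table(factor(records$event,
                                     cohort_event_codes))[["bc"]]),
      split_fraction = config$split_fraction,
      split_seed = config$split_seed,
      sim_seed = if (!is.null(config$sim)) config$sim$seed else NULL,
      n_derivation = nrow(parts$derivation),
      n_test = nrow(parts$test)))

  model <- config$model
  if (is.character(model)) model <- stage_wrap("model", read_rr_model(model))
  if ("fit" %in% config$stages) {
    fitted <- stage_wrap("fit", {
      if (config$eliminate) {
        el <- backward_eliminate(parts$derivation, rr_predictors())
        list(fit = el$fit, trace = el$trace, retained = el$retained)
      } else {
        list(fit = fit_stratified_cox(parts$derivation), trace = NULL,
             retained = rr_predictors())
      }
    })
    report$fit <- list(
      retained = fitted$retained,
      elimination_trace = fitted$trace,
      coefficients = fitted$fit$coefficients,
      loglik = fitted$fit$loglik, nevent = fitted$fit$nevent,
      iterations = fitted$fit$fit$iter)
    if (is.null(model) &&
        setequal(fitted$retained, rr_predictors())) {
      model <- rr_model_from_fit(fitted$fit)
    }
  }
  if (is.null(model)) model <- rr_model_default()

  pars <- model$par
  if ("par" %in% config$stages) {
    pars <- stage_wrap("par", par_set_from_cohort(parts$derivation, model))
    model$par <- pars
    report$par <- as.list(unclass(pars))
  }
  if (is.null(pars)) pars <- par_set_default()

  if ("validate" %in% config$stages) {
    report$validation <- stage_wrap("validate", {
      test <- parts$test
      risks_fu <- predict_absolute_risk(test, model, rates, pars,
                                        horizon = "followup")
      risks_10 <- predict_absolute_risk(test, model, rates, pars,
                                        horizon = 10)
      status <- ten_year_status(test)
      subgroup_cols <- c("age_stratum", "residence", rr_predictors())
      eo_sub <- lapply(subgroup_cols, function(cn) {
        eo_table(test, model, rates, pars, by = cn)
      })
      names(eo_sub) <- subgroup_cols
      strata <- interaction(test$residence, test$age_stratum, drop = TRUE)
      list(
        eo_overall = eo_ratio_ci(sum(risks_fu), sum(test$event == "bc")),
        eo_subgroups = eo_sub,
        deciles = calibration_deciles(risks_fu, test$event == "bc"),
        auc = auc_10yr(risks_10, status),
        adjusted_auc = adjusted_auc(risks_10, status, strata),
        quintile_rr = quintile_rr(risks_10, test),
        screening = screening_indices(risks_10, status, config$cutoffs))
    })
  }

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows", na = "null")
    if (!is.null(report$validation)) {
      utils::write.csv(report$validation$deciles,
                       file.path(config$outdir, "calibration_deciles.csv"),
                       row.names = FALSE, quote = FALSE)
    }
    return(invisible(report))
  }
  report
}
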