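# Piecewise-constant age x residence rate tables and the two hazards of the
# absolute-risk model: the PAR-deflated baseline breast-cancer hazard h10(t)
# and the competing hazard h2(t) of death from other causes.
#
# Rates live on 5-year age bands covering [30, 85) per residence, in units of
# events per 100,000 person-years at the file boundary; everything internal is
# per person-year.

RATE_COVERAGE <- c(30, 85)

#' Construct and validate a rate table
#'
#' @param df Data frame with columns `age_start`, `age_width`, `residence`
#'   (`"urban"`/`"rural"`), `bc_incidence_1e5`, `all_cause_mortality_1e5`,
#'   `bc_mortality_1e5` (rates per 100,000 person-years).
#' @return Object of class `rate_table`. Validation is eager: bands within a
#'   residence must be contiguous, non-overlapping and cover \[30, 85); all
#'   rates must be non-negative, with breast-cancer mortality no larger than
#'   all-cause mortality in every row.
#' @export
rate_table <- function(df) {
  need <- c("age_start", "age_width", "residence", "bc_incidence_1e5",
            "all_cause_mortality_1e5", "bc_mortality_1e5")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("rate table missing column(s): ",
                         paste(miss, collapse = ", "))
  df <- as.data.frame(df)[need]
  if (!all(df$residence %in% c("urban", "rural"))) {
    stop("rate table residence must be 'urban' or 'rural'")
  }
  num <- setdiff(need, "residence")
  for (cn in num) {
    if (!is.numeric(df[[cn]]) || anyNA(df[[cn]])) {
      stop("rate table column '", cn, "' must be numeric without missing values")
    }
  }
  if (any(df$age_width <= 0)) stop("rate table age_width must be positive")
  if (any(df[c("bc_incidence_1e5", "all_cause_mortality_1e5",
               "bc_mortality_1e5")] < 0)) {
    stop("rate table rates must be non-negative")
  }
  bad <- df$bc_mortality_1e5 > df$all_cause_mortality_1e5
  if (any(bad)) {
    stop("breast-cancer mortality exceeds all-cause mortality in row(s): ",
         paste(which(bad), collapse = ", "))
  }
  for (res in unique(df$residence)) {
    b <- df[df$residence == res, ]
    b <- b[order(b$age_start), ]
    ends <- b$age_start + b$age_width
    if (b$age_start[1] != RATE_COVERAGE[1] ||
        ends[nrow(b)] != RATE_COVERAGE[2] ||
        (nrow(b) > 1 && any(abs(b$age_start[-1] - ends[-nrow(b)]) > 1e-9))) {
      stop("rate table bands for residence '", res, "' must be contiguous ",
           "and cover [", RATE_COVERAGE[1], ", ", RATE_COVERAGE[2], ")")
    }
  }
  df <- df[order(df$residence, df$age_start), ]
  rownames(df) <- NULL
  structure(df, class = c("rate_table", "data.frame"))
}

#' Read a rate table CSV
#'
#' Strict header: `age_start, age_width, residence, bc_incidence_1e5,
#' all_cause_mortality_1e5, bc_mortality_1e5`. Validation happens at load.
#' @param path CSV file path.
#' @return A [rate_table()].
#' @export
read_rate_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  rate_table(df)
}

#' Write a rate table CSV
#' @param table A [rate_table()].
#' @param path Output path.
#' @export
write_rate_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# Approximate 2014 China female age structure on 5-year bands 0-84 (fractions
# of the whole female population), used only to calibrate the synthetic
# default table's crude rates. Incidence below 30 is treated as zero.
china_female_age_weights <- function() {
  w <- c(`0` = 0.055, `5` = 0.050, `10` = 0.050, `15` = 0.060, `20` = 0.085,
         `25` = 0.095, `30` = 0.065, `35` = 0.070, `40` = 0.090, `45` = 0.090,
         `50` = 0.060, `55` = 0.060, `60` = 0.055, `65` = 0.040, `70` = 0.030,
         `75` = 0.020, `80` = 0.015)
  w / sum(w)
}

#' Synthetic default rate table
#'
#' The package does not ship the registry's actual 2014 age-specific rates;
#' this clearly synthetic stand-in has a monotone non-decreasing incidence
#' gradient over \[30, 85) whose crude (whole-female-population) rate is
#' calibrated to 54.3 per 100,000 in urban areas and 34.5 per 100,000 in
#' rural areas, with Gompertz-like all-cause mortality and breast-cancer
#' mortality set to a quarter of incidence. Outputs derived from it should be
#' labelled "synthetic-rates"; supply registry rates via [read_rate_table()]
#' for real use.
#'
#' @return A [rate_table()].
#' @export
rate_table_synthetic <- function() {
  starts <- seq(30, 80, by = 5)
  shape <- c(0.15, 0.35, 0.60, 0.85, 1, 1, 1, 1, 1, 1, 1)
  w <- china_female_age_weights()
  wa <- w[as.character(starts)]
  scale_to <- function(target) target / sum(wa * shape)
  inc_urban <- shape * scale_to(54.3)
  inc_rural <- shape * scale_to(34.5)
  mort_urban <- c(40, 55, 85, 130, 200, 330, 600, 1200, 2400, 4800, 9500)
  mort_rural <- mort_urban * 1.15
  build <- function(res, inc, mort) {
    data.frame(age_start = starts, age_width = 5, residence = res,
               bc_incidence_1e5 = inc, all_cause_mortality_1e5 = mort,
               bc_mortality_1e5 = 0.25 * inc)
  }
  rate_table(rbind(build("urban", inc_urban, mort_urban),
                   build("rural", inc_rural, mort_rural)))
}

# Band index lookup; errors on uncovered ages. Right-open bands, so age 85 is
# outside coverage.
rate_band_index <- function(table, residence, age) {
  n <- max(length(residence), length(age))
  residence <- rep_len(as.character(residence), n)
  age <- rep_len(age, n)
  out <- integer(n)
  for (res in unique(residence)) {
    rows <- which(table$residence == res)
    if (!length(rows)) stop("rate table has no rows for residence '", res, "'")
    sel <- residence == res
    starts <- table$age_start[rows]
    ends <- starts + table$age_width[rows]
    k <- findInterval(age[sel], starts)
    bad <- k == 0 | age[sel] >= ends[length(ends)]
    if (any(bad)) {
      stop("age(s) outside rate-table coverage [", starts[1], ", ",
           ends[length(ends)], ") for residence '", res, "': ",
           paste(utils::head(round(age[sel][bad], 2), 5), collapse = ", "))
    }
    out[sel] <- rows[k]
  }
  out
}

#' Band boundaries of a rate table
#' @param table A [rate_table()].
#' @return Sorted vector of ages at which any rate may change (band edges).
#' @export
rate_breakpoints <- function(table) {
  sort(unique(c(table$age_start, table$age_start + table$age_width)))
}

#' Competing hazard of non-breast-cancer death
#'
#' All-cause mortality minus breast-cancer mortality for the band containing
#' `age`, converted to events per person-year; constant within a band.
#'
#' @param table A [rate_table()].
#' @param residence `"urban"` or `"rural"` (vectorised).
#' @param age Attained age(s) in years.
#' @return Hazard(s) per person-year.
#' @export
competing_hazard <- function(table, residence, age) {
  i <- rate_band_index(table, residence, age)
  (table$all_cause_mortality_1e5[i] - table$bc_mortality_1e5[i]) / 1e5
}

#' Composite breast-cancer incidence rate
#'
#' The registry incidence for the band containing `age`, per person-year
#' (the population-average hazard before PAR deflation).
#' @inheritParams competing_hazard
#' @export
composite_incidence <- function(table, residence, age) {
  i <- rate_band_index(table, residence, age)
  table$bc_incidence_1e5[i] / 1e5
}

#' Baseline hazard for an all-reference profile
#'
#' Registry incidence times one minus the population attributable risk of the
#' age segment (below / at-or-above 50) and residence containing the query,
#' per person-year. The PAR switch sits exactly at age 50.
#'
#' @inheritParams competing_hazard
#' @param pars A [par_set()].
#' @param age_split Age of the PAR segment boundary (years).
#' @export
baseline_hazard <- function(table, pars, residence, age, age_split = 50) {
  pars <- par_set_validate(pars)
  inc <- composite_incidence(table, residence, age)
  n <- length(inc)
  inc * (1 - par_lookup(pars, rep_len(as.character(residence), n),
                        rep_len(age, n), age_split))
}

# ---------------------------------------------------------------------------
# PAR sets: the four attributable-risk fractions (age segment x residence)

#' Construct a PAR set
#'
#' Four population attributable risks indexed by residence and age segment,
#' each in \[0, 1).
#' @param urban_lt50,urban_ge50,rural_lt50,rural_ge50 PAR values.
#' @return Named numeric vector of class `par_set`.
#' @export
par_set <- function(urban_lt50, urban_ge50, rural_lt50, rural_ge50) {
  par_set_validate(c(urban_lt50 = urban_lt50, urban_ge50 = urban_ge50,
                     rural_lt50 = rural_lt50, rural_ge50 = rural_ge50))
}

#' Published default PAR set
#'
#' The published attributable-risk fractions for the six modelled predictors:
#' 0.74 / 0.76 in urban areas below / at-or-above age 50, and 0.63 / 0.65 in
#' rural areas.
#' @return A [par_set()].
#' @export
par_set_default <- function() {
  par_set(urban_lt50 = 0.74, urban_ge50 = 0.76,
          rural_lt50 = 0.63, rural_ge50 = 0.65)
}

par_set_validate <- function(pars) {
  need <- c("urban_lt50", "urban_ge50", "rural_lt50", "rural_ge50")
  pars <- unlist(pars)
  if (!all(need %in% names(pars))) {
    stop("PAR set must contain: ", paste(need, collapse = ", "))
  }
  pars <- pars[need]
  if (anyNA(pars) || any(pars < 0) || any(pars >= 1)) {
    stop("each PAR must lie in [0, 1)")
  }
  structure(pars, class = "par_set")
}

par_lookup <- function(pars, residence, age, age_split = 50) {
  seg <- ifelse(age < age_split, "lt50", "ge50")
  unname(unlist(pars)[paste(residence, seg, sep = "_")])
}
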