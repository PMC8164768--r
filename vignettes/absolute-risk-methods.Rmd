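---
title: "Methods: absolute breast-cancer risk with competing mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: absolute breast-cancer risk with competing mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcarisk)
```

## The model

`bcarisk` implements an absolute-risk ("Gail-type") prediction model for
invasive breast cancer in Chinese women aged 30 and over. The probability
that a woman aged $a$ with risk-factor profile $x$ develops breast cancer by
age $a+\tau$, in the presence of competing mortality, is

$$
P(a,\tau,x) \;=\; \int_a^{a+\tau} h_1(t,x)\,
  \exp\!\Big[-\!\int_a^t \big(h_1(u,x)+h_2(u)\big)\,du\Big]\,dt ,
$$

where $h_1(t,x) = h_{10}(t)\,\mathrm{RR}(x)$ is the breast-cancer hazard and
$h_2(t)$ the hazard of death from any other cause. The three ingredients are
held by three objects:

* **Relative risk** (`rr_model`): a multiplicative model over six
  categorical predictors — education (5 levels), body-mass index (4), height
  (4), number of first-degree relatives with any cancer (3), parity (4), and
  age at menarche (4). Log relative risks are stored per category with the
  reference at exactly zero. All effects are age-constant except BMI, which
  carries two mappings switched at age 50: below 50 the association is flat
  to slightly inverse (RR 0.85--1.00), at and above 50 it is strongly
  positive (up to RR 1.96 for BMI $\ge$ 28), a violation of proportional
  hazards handled by splitting follow-up at 50 rather than by a continuous
  time-varying coefficient.
* **Baseline hazard** (`baseline_hazard`): registry age- and
  residence-specific incidence multiplied by one minus the population
  attributable risk (PAR) of the six predictors, so that the baseline refers
  to a woman with every factor at its lowest-risk level. Because risk-factor
  distributions differ by residence and age, four PARs are used
  (urban/rural $\times$ attained age $<50$/$\ge 50$); the shipped values are
  0.74/0.76 (urban) and 0.63/0.65 (rural).
* **Competing hazard** (`competing_hazard`): all-cause mortality minus
  breast-cancer mortality, by the same age bands and residence.

The PAR itself uses the Bruzzi case-distribution estimator
$\mathrm{PAR} = 1 - \sum_j p_j/\mathrm{RR}_j$, with $p_j$ the proportion of
cases in joint exposure category $j$ (built sparsely over the full
cross-classification of the six predictors from observed cases, never from a
marginal-independence product) and $\mathrm{RR}_j$ the joint relative risk
with the segment-appropriate BMI mapping. A case's age segment is decided by
attained age at diagnosis, since the PAR feeds segment-specific baselines.

## Evaluating the integral

All hazards are piecewise constant: rates live on 5-year age bands, and both
the BMI relative risk and the PAR switch exactly at 50. `project()` therefore
partitions $[a, a+\tau)$ at every band edge and at 50, and accumulates the
closed-form contribution of each piece,
$S \cdot \frac{h_1}{h_1+h_2}\big(1-e^{-(h_1+h_2)\Delta}\big)$, carrying the
all-cause survival $S$ forward. No quadrature is involved; the only numerical
error is floating-point rounding, and the test suite checks agreement with a
1/365-year-step grid integration to far better than $10^{-6}$ on 1000 random
queries. The horizon $\tau$ may be fractional; pieces are clipped exactly;
the BMI/PAR segment of a piece is decided by its start age (no piece
straddles 50 by construction). Queries outside the rate table's coverage
([30, 85) by default) raise an error rather than extrapolate.

## Fitting the relative-risk model

`fit_stratified_cox()` maximises the Cox partial likelihood with **age as the
timescale** and delayed entry at enrollment, jointly stratified by study site
(10) and 5-year enrollment-age band (10), up to 100 strata, so that age and
site act through stratum-specific baselines rather than estimated
coefficients. Design choices:

* **Ties** are handled by Efron's method by default (ages reported coarsely
  produce heavy ties); Breslow is available via `ties = "breslow"`.
* **Follow-up splitting**: `split_followup_at_age()` converts a record
  spanning age 50 into two contiguous episodes (the first censored at 50),
  conserving person-time exactly; BMI then enters with segment-specific
  coefficients, and the segment main effect is deliberately absent because it
  is absorbed by the baseline — matching the convention of reporting a
  reference RR of 1.00 inside each BMI age block.
* **Cutoff selection** (`select_cutoffs_bic()`) scores candidate
  categorisations by $\mathrm{BIC} = -2\ell + k\log d$ with $d$ the **number
  of events**, not subjects: the effective information of a partial
  likelihood scales with events. Ties break toward fewer parameters.
* **Backward elimination** (`backward_eliminate()`) drops the predictor with
  the largest per-predictor Wald p-value above 0.05 (joint chi-square over
  all of a predictor's parameters); a likelihood-ratio variant is available
  via `test = "lrt"`. Wald is the default reading of a "P < 0.05" screen.
* **Proportional hazards** are checked by the Schoenfeld-residual score test
  (`schoenfeld_ph_test()`, identity time transform so residuals are related
  to attained age itself).
* Nonlinearity screening is done as an ordinal-versus-categorical
  likelihood-ratio test per predictor (both encodings are supported in the
  design builder) rather than fractional polynomials: the scientific question
  — are the log relative risks proportional to the level index? — is the
  same, with a far smaller surface. Notably, the shipped education, height,
  menarche and late-age BMI log RRs are exactly linear in level index, while
  parity and family history are not.

Convergence and inference come from `survival::coxph` (Newton–Raphson with
step-halving); non-estimable or separated parameters raise errors instead of
returning infinite estimates.

## Validation suite

* **Calibration**: `expected_cases()` sums projected probabilities;
  `eo_ratio_ci()` forms E/O with the **exact** (chi-square-quantile) Poisson
  interval for the observed count. The exact interval matters: for a
  subgroup with E = 111, O = 138 it gives 0.68–0.96 where the normal
  approximation gives 0.69–0.97. `calibration_deciles()` bins by sample
  deciles of predicted risk (stable ties, bin sizes within 1).
* **Two horizon rules**: against a real cohort, each woman is projected to
  her observed exit age. That expectation equals
  $\int h_1 S^2\,dt < \int h_1 S\,dt = \mathbb{E}[O]$, because cases and
  competing deaths truncate observed follow-up; with ~8% ten-year all-cause
  mortality this is a deficit of several percent even for a perfectly
  specified model. When the administrative censoring horizon is known — as
  in a simulated cohort — passing a numeric `horizon` projects everyone over
  their full potential follow-up, making E the exact expectation of O. The
  self-calibration tests use the potential-follow-up rule for this reason.
* **Discrimination**: `auc_10yr()` is the Mann–Whitney probability with ties
  counted one half (midranks), CI by the Hanley–McNeil variance; eligibility
  follows the cumulative/dynamic rule (cases within 10 years; controls
  event-free with $\ge$ 10 years of follow-up; others excluded, with an
  option to count earlier other-cause deaths as controls).
  `adjusted_auc()` removes between-stratum separation by pooling
  within-stratum Mann–Whitney statistics weighted by case $\times$ control
  pair counts — one defensible reading of "adjusting for age and residence";
  regression-based covariate adjustment is a noted alternative, not
  implemented.
* **Risk stratification**: `quintile_rr()` cuts at the validation sample's
  own quintile boundaries (ties to the lower group) and feeds indicator
  variables back through the stratified Cox fitter; `screening_indices()`
  reports percent flagged, sensitivity, specificity, PPV/NPV and the number
  needed to screen (1/PPV) over the 0.4%–2% cutoff grid.

Rounding to two decimals happens only at report boundaries; every internal
comparison uses full precision.

## The synthetic cohort generator

No individual-level data from the source cohorts is public, so
`simulate_cohort()` generates cohorts that emulate the derivation cohort's
structure: a 55.5/44.5 rural/urban mix, five study sites per residence, the
published per-residence entry-age band mixture, and the published
per-residence marginals for the six predictors. Event times are drawn by
exact inversion from piecewise-exponential distributions whose hazards are
the *same* `baseline_hazard`/`competing_hazard`/`relative_risk` pathway the
projector uses — generator and evaluator share one hazard definition, so
closure tests are meaningful. A single recruitment wave with a 10.2-year
administrative horizon reproduces the reported median follow-up; follow-up
is additionally truncated at the rate table's coverage end (85). Seven
considered-but-rejected predictors have no hazard effect; five of them
(smoking, alcohol, oral-contraceptive use, menopausal status, breastfeeding)
are generated at their published prevalences as true negatives for variable
selection.

What the generator does **not** emulate: the joint dependence of risk
factors (defaults are independent marginals, since only marginals are
published — an exchangeable Gaussian-copula option `rank_correlation` exists
for sensitivity analyses), staggered calendar entry, secular rate trends,
covariate measurement error, and informative loss to follow-up. One visible
consequence: the attributable risks induced by independent marginals are
lower in the under-50 urban group (~0.64) than the published 0.74, which
arises from the real joint case distribution; self-consistency tests
therefore compare simulated PARs with their analytically induced values
(product of marginal mean relative risks), not with the published ones.

## Rates

The actual 2014 registry rates are not redistributable here, so the package
ships a clearly synthetic table (`rate_table_synthetic()`, also under
`inst/extdata/rates_synthetic_china2014.csv`): a monotone non-decreasing
incidence gradient over [30, 85) whose whole-population crude rate —
computed against an approximate 2014 female age structure with near-zero
incidence below 30 — is calibrated to 54.3 (urban) and 34.5 (rural) per
100,000, Gompertz-like all-cause mortality, and breast-cancer mortality at a
quarter of incidence. Every output derived from it should be labelled
"synthetic-rates"; real registry tables load through `read_rate_table()`
with eager validation (contiguous bands covering [30, 85), non-negative
rates, cause-specific $\le$ all-cause).

## Numerical and degenerate-input policy

Category boundaries are left-closed/right-open on the printed lower bounds
(BMI 24.0 is "24.0–27.9"; height 158.2 is "$\ge$ 158.2"); printed integer
label gaps close downward (menarche 12 joins "$\le$ 12") so the partition is
exhaustive. Serialisation stores log relative risks with explicit reference
levels, so references survive a JSON round trip at exactly zero. Rate tables
validate eagerly at load; projection errors on coverage gaps; E/O is
undefined at O = 0 and errors rather than returning infinity; AUC requires
both a case and a control; constant predictions cannot be decile-binned and
say so. All simulation randomness flows from explicit seeds
(`withr::with_seed`), leaving the caller's RNG state untouched, and
identical seeds give byte-identical cohort CSVs.

## Problem sizes used by the test suite

The suite exercises the pipeline at the design sizes the validation story
calls for: parameter recovery and variable selection on one simulated cohort
of 100,000 women (~860 cases), self-calibration and discrimination on one of
200,000 (~1650 cases), 1000 random projection queries against the grid
oracle, and 200-replicate null calibration of the Schoenfeld test at small
n. At these sizes a full run of the suite takes on the order of a minute.
One caveat is recorded honestly: with ~54–360 expected events per decile at
n = 200,000, requiring *every* decile ratio within $\pm 10\%$ is a
coin-flip-level check even under the true model (the lowest decile alone
falls outside ~40% of the time by Poisson noise); a decisive version of that
check would need a cohort about six times larger.

## Limitations

The model applies to women 30–85 with the six non-laboratory predictors; it
carries no ER-subtype distinction, no genetic or mammographic-density
information, no confidence intervals on projected risks, and no rate
smoothing or projection to other calendar years. Family history of *any*
cancer is a surrogate for family history of breast cancer and is expected to
overstate inherited risk in the $\ge 2$-relatives category. Validation
against real cohort data requires that the user supply the corresponding
registry rate table and cohort file.
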