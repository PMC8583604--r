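#' Define one monitored outcome
#'
#' An `outcome_spec` describes how one clinical or biochemical variable is
#' generated in a synthetic two-visit cohort: its measurement scale, the
#' location-scale family used to draw values, the target baseline median (or
#' proportion, for binary outcomes) and IQR width, the additive shift in
#' location at follow-up, the within-subject correlation induced by a shared
#' subject effect, and the exact number of missing values planted at each
#' visit.
#'
#' For continuous outcomes the generating family is parameterised so that the
#' population median equals `baseline_location` and the population IQR equals
#' `baseline_spread` exactly (normal and zero-censored-normal families match
#' the quartiles through the normal quantile; the log-normal family matches
#' them through the log-scale quantile). Setting `baseline_spread = 0`
#' degenerates the family to a point mass at `baseline_location` (plus
#' `followup_shift` at follow-up).
#'
#' @param name Variable name (used as the column name in generated cohorts).
#' @param scale One of `"continuous"` or `"binary"`.
#' @param units Free-text measurement units.
#' @param baseline_location Target baseline median (continuous) or event
#'   proportion in `[0, 1]` (binary).
#' @param baseline_spread Target baseline IQR width (continuous; `>= 0`).
#'   Ignored for binary outcomes.
#' @param followup_shift Additive change in the location at follow-up
#'   (median shift for continuous outcomes, proportion shift for binary).
#' @param within_subject_corr Correlation between a subject's two visits on
#'   the latent scale, in `[0, 1]`.
#' @param missing_baseline,missing_followup Exact number of subjects whose
#'   value is set missing at the corresponding visit.
#' @param family Generating family for continuous outcomes: `"normal"`,
#'   `"lognormal"` (for right-skewed lab values; requires a positive
#'   location), or `"censored-normal"` (normal left-censored at zero, for
#'   semicontinuous intake-type variables).
#'
#' @return An object of class `outcome_spec`.
#' @seealso [default_outcome_specs()], [generate_cohort()]
#' @export
outcome_spec <- function(name, scale = c("continuous", "binary"),
                         units = "", baseline_location, baseline_spread = 0,
                         followup_shift = 0, within_subject_corr = 0.7,
                         missing_baseline = 0L, missing_followup = 0L,
                         family = c("normal", "lognormal", "censored-normal")) {
  scale <- match.arg(scale)
  family <- match.arg(family)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(baseline_location) || length(baseline_location) != 1L)
    stop("'baseline_location' must be a single number", call. = FALSE)
  if (baseline_spread < 0)
    stop("'baseline_spread' must be non-negative", call. = FALSE)
  if (within_subject_corr < 0 || within_subject_corr > 1)
    stop("'within_subject_corr' must lie in [0, 1]", call. = FALSE)
  if (missing_baseline < 0 || missing_followup < 0)
    stop("missing counts must be non-negative", call. = FALSE)
  if (scale == "binary") {
    if (baseline_location < 0 || baseline_location > 1)
      stop("binary 'baseline_location' is a proportion in [0, 1]", call. = FALSE)
    p1 <- baseline_location + followup_shift
    if (p1 < 0 || p1 > 1)
      stop("follow-up proportion outside [0, 1]", call. = FALSE)
  }
  if (scale == "continuous" && family == "lognormal" && baseline_location <= 0)
    stop("log-normal family requires a positive baseline median", call. = FALSE)
  structure(
    list(name = name, scale = scale, units = units,
         baseline_location = baseline_location,
         baseline_spread = baseline_spread,
         followup_shift = followup_shift,
         within_subject_corr = within_subject_corr,
         missing_baseline = as.integer(missing_baseline),
         missing_followup = as.integer(missing_followup),
         family = family),
    class = "outcome_spec")
}

#' Default catalogue of the 17 monitored outcomes
#'
#' Returns the built-in list of 17 outcome definitions used by
#' [generate_cohort()] and as the default analysis set of
#' [run_full_analysis()]: 15 continuous variables (glycaemic control, renal
#' function, lipid profile, anthropometry, lifestyle intake, blood pressure
#' and heart rate) and 2 binary indicators (moderate-to-intense physical
#' activity, current smoking). Baseline medians/IQRs, follow-up median
#' shifts and exact per-visit missing-value counts are calibrated to a
#' 124-subject diabetes care-pathway monitoring cohort; right-skewed lab
#' values use a log-normal family, symmetric measurements a normal family,
#' and daily alcohol intake (median zero) a zero-censored normal.
#'
#' @return A named list of [outcome_spec()] objects, in the fixed reporting
#'   order of the longitudinal analysis.
#' @export
default_outcome_specs <- function() {
  s <- list(
    outcome_spec("hba1c", "continuous", "mmol/mol", 52.0, 59.0 - 46.0, -1.0,
                 within_subject_corr = 0.7, missing_baseline = 0, missing_followup = 1,
                 family = "lognormal"),
    outcome_spec("microalbuminuria", "continuous", "mg/die", 8.3, 21.9 - 3.1, -0.4,
                 within_subject_corr = 0.6, missing_baseline = 13, missing_followup = 17,
                 family = "lognormal"),
    outcome_spec("creatinine_clearance", "continuous", "mL/min", 85.7, 102.8 - 68.8, -1.8,
                 within_subject_corr = 0.8, missing_baseline = 4, missing_followup = 5),
    outcome_spec("total_cholesterol", "continuous", "mg/dL", 178, 212 - 152, -6,
                 within_subject_corr = 0.7, missing_baseline = 4, missing_followup = 3),
    outcome_spec("ldl_cholesterol", "continuous", "mg/dL", 96.5, 125.5 - 76.0, -5,
                 within_subject_corr = 0.7, missing_baseline = 0, missing_followup = 4),
    outcome_spec("hdl_cholesterol", "continuous", "mg/dL", 53.5, 63.0 - 43.0, -1,
                 within_subject_corr = 0.7, missing_baseline = 4, missing_followup = 4),
    outcome_spec("triglycerides", "continuous", "mg/dL", 105.5, 151.0 - 78.2, 0.5,
                 within_subject_corr = 0.6, missing_baseline = 6, missing_followup = 6,
                 family = "lognormal"),
    outcome_spec("weight", "continuous", "kg", 80, 90 - 70, 0,
                 within_subject_corr = 0.95),
    outcome_spec("bmi", "continuous", "kg/m^2", 28.7, 31.2 - 25.8, -0.3,
                 within_subject_corr = 0.95),
    outcome_spec("waist_circumference", "continuous", "cm", 106, 112 - 97, -1,
                 within_subject_corr = 0.9, missing_baseline = 13, missing_followup = 7),
    outcome_spec("cigarettes_per_day", "continuous", "n/day", 20.0, 30.0 - 15.0, 0,
                 within_subject_corr = 0.8, missing_baseline = 67, missing_followup = 67,
                 family = "lognormal"),
    outcome_spec("alcohol", "continuous", "g/day", 0, 12, 0,
                 within_subject_corr = 0.8, family = "censored-normal"),
    outcome_spec("sbp", "continuous", "mmHg", 148, 160 - 140, -3,
                 within_subject_corr = 0.4),
    outcome_spec("dbp", "continuous", "mmHg", 80.0, 90.0 - 71.5, -4,
                 within_subject_corr = 0.4),
    outcome_spec("heart_rate", "continuous", "bpm", 73.0, 80.0 - 66.0, 0,
                 within_subject_corr = 0.4, missing_baseline = 5, missing_followup = 0),
    outcome_spec("physical_activity_mod_intense", "binary", "",
                 13 / 124, followup_shift = 12 / 124 - 13 / 124,
                 within_subject_corr = 0.8),
    outcome_spec("smoker", "binary", "", 16 / 122, followup_shift = 14 / 123 - 16 / 122,
                 within_subject_corr = 0.9, missing_baseline = 2, missing_followup = 1)
  )
  names(s) <- vapply(s, `[[`, character(1), "name")
  s
}

#' Configure a synthetic two-visit cohort
#'
#' Bundles everything [generate_cohort()] needs: the two care-group sizes,
#' the follow-up interval distribution, the outcome catalogue, demographic
#' distributions, and a seed. Defaults reproduce the structure of a
#' 124-subject monitoring cohort: 91 subjects followed by the family-physician
#' care pathway alone (group `PDTA`) and 33 also enrolled in the specialised
#' diabetes-centre care plan (group `PDTA_CAD`), re-examined a median 370
#' days after baseline.
#'
#' @param n_group_a Size of the `PDTA` group.
#' @param n_group_b Size of the `PDTA_CAD` group.
#' @param followup_days_median Median follow-up interval, days.
#' @param followup_days_iqr Quartiles (length 2) of the follow-up interval.
#' @param outcome_specs List of [outcome_spec()] objects.
#' @param age_median,age_iqr Median and quartiles of age, years.
#' @param p_male Proportion of male subjects.
#' @param p_treatment Named proportions for pharmacological treatment,
#'   summing to 1.
#' @param seed Integer seed; generation is fully deterministic given the
#'   configuration and seed.
#'
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_group_a = 91L, n_group_b = 33L,
                          followup_days_median = 370,
                          followup_days_iqr = c(315, 403),
                          outcome_specs = default_outcome_specs(),
                          age_median = 71.5, age_iqr = c(66.1, 77.2),
                          p_male = 0.61,
                          p_treatment = c(oral_hypoglycemic = 0.90,
                                          insulin = 0.03, none = 0.07),
                          seed = 1L) {
  n_group_a <- as.integer(n_group_a); n_group_b <- as.integer(n_group_b)
  if (n_group_a < 1L || n_group_b < 1L)
    stop("both group sizes must be positive", call. = FALSE)
  n <- n_group_a + n_group_b
  if (!all(vapply(outcome_specs, inherits, logical(1), "outcome_spec")))
    stop("'outcome_specs' must be a list of outcome_spec objects", call. = FALSE)
  for (sp in outcome_specs) {
    if (sp$missing_baseline > n || sp$missing_followup > n)
      stop(sprintf("outcome '%s': missing count exceeds cohort size %d",
                   sp$name, n), call. = FALSE)
  }
  if (p_male < 0 || p_male > 1) stop("'p_male' must lie in [0, 1]", call. = FALSE)
  if (any(p_treatment < 0) || abs(sum(p_treatment) - 1) > 1e-8)
    stop("'p_treatment' must be non-negative and sum to 1", call. = FALSE)
  if (length(followup_days_iqr) != 2L || diff(followup_days_iqr) < 0)
    stop("'followup_days_iqr' must be (q1, q3) with q1 <= q3", call. = FALSE)
  structure(
    list(n_group_a = n_group_a, n_group_b = n_group_b,
         followup_days_median = followup_days_median,
         followup_days_iqr = followup_days_iqr,
         outcome_specs = outcome_specs,
         age_median = age_median, age_iqr = age_iqr,
         p_male = p_male, p_treatment = p_treatment,
         seed = as.integer(seed)),
    class = "cohort_config")
}

# IQR width -> normal SD (quartiles are +/- qnorm(0.75) SDs around the median)
.iqr_to_sd <- function(iqr) iqr / (2 * stats::qnorm(0.75))
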