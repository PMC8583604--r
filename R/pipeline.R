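#' Full two-model longitudinal analysis of a cohort
#'
#' Runs the complete effectiveness analysis on a two-visit cohort: for each
#' outcome it fits Model 1 (random-intercept LMM with time only) and
#' Model 2 (time + care group + group-by-time interaction) via
#' [fit_random_intercept_lmm()], assembles the estimate / standard error /
#' Wald p-value blocks into a single report, applies Benjamini-Hochberg
#' adjustment within each of the four p-value columns, and builds the
#' per-visit descriptive tables. Binary outcomes are fitted on their 0/1
#' indicators with the same Gaussian model (linear probability scale) —
#' an approximation that keeps every row of the report on the estimate/SE
#' scale of the continuous outcomes.
#'
#' An outcome column that is entirely missing is reported as a row of
#' `NA`s (flagged in `failed`) and the run continues. The analysis is
#' deterministic given the input table and configuration.
#'
#' @param cohort A cohort `data.frame` (see [generate_cohort()]) or the
#'   path to a cohort CSV ([read_cohort()] dialect).
#' @param outcomes Character vector of outcome columns to analyse, in
#'   report order. Defaults to the built-in 17-outcome catalogue.
#' @param time_coding Time coding for the study models; `"days"` uses each
#'   subject's exact follow-up interval.
#' @param estimation `"REML"` or `"ML"`.
#' @param adjust Apply BH adjustment columns (`TRUE`) or report raw
#'   p-values only.
#' @param out_dir Optional directory; when given, writes `table1.csv`,
#'   `table2.csv`, `table3.csv`, `table4.csv` there.
#' @return An object of class `analysis_report`: list with `longitudinal`
#'   (one row per outcome: `m1_est`, `m1_se`, `m1_p`, `m1_p_adj`, and the
#'   three Model-2 blocks `m2_time_*`, `m2_group_*`, `m2_inter_*`),
#'   `baseline_table`, `followup_table`, `subject_table`, `failed`, and a
#'   `meta` block (n, estimation, time coding).
#' @examples
#' coh <- generate_cohort(cohort_config(seed = 1))
#' rep <- run_full_analysis(coh)
#' head(rep$longitudinal[, c("outcome", "m1_est", "m1_p", "m1_p_adj")])
#' @export
run_full_analysis <- function(cohort,
                              outcomes = names(default_outcome_specs()),
                              time_coding = "days", estimation = "REML",
                              adjust = TRUE, out_dir = NULL) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  missing_cols <- setdiff(outcomes, names(cohort))
  if (length(missing_cols))
    stop("cohort lacks outcome columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  blank <- rep(NA_real_, length(outcomes))
  rep4 <- data.frame(
    outcome = outcomes,
    m1_est = blank, m1_se = blank, m1_p = blank,
    m2_time_est = blank, m2_time_se = blank, m2_time_p = blank,
    m2_group_est = blank, m2_group_se = blank, m2_group_p = blank,
    m2_inter_est = blank, m2_inter_se = blank, m2_inter_p = blank,
    stringsAsFactors = FALSE)
  failed <- character(0)
  for (i in seq_along(outcomes)) {
    nm <- outcomes[i]
    f1 <- tryCatch(fit_random_intercept_lmm(cohort, nm, model = 1,
                                            time_coding = time_coding,
                                            estimation = estimation),
                   error = function(e) NULL)
    f2 <- tryCatch(fit_random_intercept_lmm(cohort, nm, model = 2,
                                            time_coding = time_coding,
                                            estimation = estimation),
                   error = function(e) NULL)
    if (is.null(f1) || is.null(f2)) { failed <- c(failed, nm); next }
    rep4[i, c("m1_est", "m1_se", "m1_p")] <-
      c(f1$coefficients["time"], f1$se["time"], f1$p_values["time"])
    rep4[i, c("m2_time_est", "m2_time_se", "m2_time_p")] <-
      c(f2$coefficients["time"], f2$se["time"], f2$p_values["time"])
    rep4[i, c("m2_group_est", "m2_group_se", "m2_group_p")] <-
      c(f2$coefficients["group"], f2$se["group"], f2$p_values["group"])
    rep4[i, c("m2_inter_est", "m2_inter_se", "m2_inter_p")] <-
      c(f2$coefficients["time:group"], f2$se["time:group"],
        f2$p_values["time:group"])
  }
  if (adjust) {
    for (col in c("m1_p", "m2_time_p", "m2_group_p", "m2_inter_p"))
      rep4[[sub("_p$", "_p_adj", col)]] <- bh_adjust(rep4[[col]])
  }

  binary <- outcomes[vapply(outcomes, function(nm) {
    v <- cohort[[nm]]; all(v[!is.na(v)] %in% c(0, 1))
  }, logical(1))]
  scales <- stats::setNames(
    ifelse(outcomes %in% binary, "binary", "continuous"), outcomes)
  tab2 <- descriptive_table(cohort, outcomes, "baseline", scales)
  tab3 <- descriptive_table(cohort, outcomes, "followup", scales)

  base <- cohort[cohort$visit == "baseline", , drop = FALSE]
  fu <- cohort[cohort$visit == "followup", , drop = FALSE]
  tab1 <- data.frame(
    characteristic = c("n_subjects", "n_group_a", "n_group_b",
                       "age_median_iqr", "male_n_pct",
                       "followup_days_median_iqr"),
    value = c(nrow(base),
              sum(base$group == sort(unique(base$group))[1]),
              if (length(unique(base$group)) > 1)
                sum(base$group == sort(unique(base$group))[2]) else 0,
              if ("age" %in% names(base)) {
                q <- summarize_median_iqr(base$age)
                sprintf("%.1f (%.1f, %.1f)", q[2], q[1], q[3])
              } else NA,
              if ("sex" %in% names(base))
                sprintf("%d (%.0f%%)", sum(base$sex == "male"),
                        100 * mean(base$sex == "male")) else NA,
              {
                q <- summarize_median_iqr(fu$days_from_baseline)
                sprintf("%.0f (%.0f, %.0f)", q[2], q[1], q[3])
              }),
    stringsAsFactors = FALSE)

  out <- structure(list(
    longitudinal = rep4, baseline_table = tab2, followup_table = tab3,
    subject_table = tab1, failed = failed,
    meta = list(n_subjects = nrow(base), n_rows = nrow(cohort),
                estimation = estimation, time_coding = time_coding,
                adjusted = adjust)),
    class = "analysis_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(tab1, file.path(out_dir, "table1.csv"), row.names = FALSE)
    utils::write.csv(tab2, file.path(out_dir, "table2.csv"), row.names = FALSE)
    utils::write.csv(tab3, file.path(out_dir, "table3.csv"), row.names = FALSE)
    utils::write.csv(rep4, file.path(out_dir, "table4.csv"), row.names = FALSE)
  }
  out
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("Two-visit longitudinal analysis: %d subjects, %d outcomes (%s, time = %s)\n",
              x$meta$n_subjects, nrow(x$longitudinal), x$meta$estimation,
              x$meta$time_coding))
  if (length(x$failed))
    cat("  failed outcomes:", paste(x$failed, collapse = ", "), "\n")
  print(utils::head(x$longitudinal[, c("outcome", "m1_est", "m1_se", "m1_p",
                                       "m2_group_est", "m2_group_p")], 8))
  invisible(x)
}

#' Validate a cohort table
#'
#' Schema and consistency checks run before analysis: required columns
#' present, no subject with more than two visits or duplicated visit roles,
#' `days_from_baseline` zero exactly at baseline and non-negative, group
#' label constant within subject, and the fraction of missing group labels.
#'
#' @param cohort A cohort `data.frame` or CSV path.
#' @return A `data.frame` of class `cohort_validation` with columns
#'   `check`, `status` (`"pass"`, `"warn"`, `"fail"`) and `detail`.
#' @export
validate_cohort <- function(cohort) {
  if (is.character(cohort)) {
    if (!file.exists(cohort)) stop("file not found: ", cohort, call. = FALSE)
    cohort <- read_cohort(cohort)
  }
  res <- list()
  add <- function(check, status, detail = "")
    res[[length(res) + 1L]] <<- data.frame(check = check, status = status,
                                           detail = detail,
                                           stringsAsFactors = FALSE)
  required <- c("subject_id", "group", "visit", "days_from_baseline")
  miss <- setdiff(required, names(cohort))
  if (length(miss)) {
    add("required_columns", "fail", paste("missing:", paste(miss, collapse = ", ")))
    out <- do.call(rbind, res); class(out) <- c("cohort_validation", "data.frame")
    return(out)
  }
  add("required_columns", "pass")

  nv <- table(cohort$subject_id)
  bad <- names(nv)[nv > 2]
  if (length(bad)) add("max_two_visits", "fail",
                       paste("subjects with >2 visits:",
                             paste(bad, collapse = ", ")))
  else add("max_two_visits", "pass")

  dup <- tapply(cohort$visit, cohort$subject_id,
                function(v) anyDuplicated(v) > 0)
  if (any(dup)) add("distinct_visit_roles", "fail",
                    paste("duplicated visit role:",
                          paste(names(dup)[dup], collapse = ", ")))
  else add("distinct_visit_roles", "pass")

  bad_visit <- !cohort$visit %in% c("baseline", "followup")
  if (any(bad_visit)) add("visit_labels", "fail",
                          sprintf("%d rows with unknown visit label",
                                  sum(bad_visit)))
  else add("visit_labels", "pass")

  is_base <- cohort$visit == "baseline"
  bad_days <- (is_base & cohort$days_from_baseline != 0) |
    (!is_base & cohort$days_from_baseline < 0)
  bad_days[is.na(bad_days)] <- TRUE
  if (any(bad_days)) add("days_from_baseline", "fail",
                         sprintf("%d rows violate the days convention",
                                 sum(bad_days)))
  else add("days_from_baseline", "pass")

  gmiss <- mean(is.na(cohort$group) | cohort$group == "")
  if (gmiss > 0) add("group_labels", "warn",
                     sprintf("%.0f%% of rows have a missing group label",
                             100 * gmiss))
  else add("group_labels", "pass")

  ginc <- tapply(cohort$group, cohort$subject_id,
                 function(g) length(unique(g[!is.na(g)])) > 1)
  ginc[is.na(ginc)] <- FALSE
  if (any(ginc)) add("group_constant_within_subject", "fail",
                     paste(names(ginc)[ginc], collapse = ", "))
  else add("group_constant_within_subject", "pass")

  out <- do.call(rbind, res)
  class(out) <- c("cohort_validation", "data.frame")
  out
}

#' Read a generator or power configuration from YAML
#'
#' Keys mirror the arguments of [cohort_config()] /
#' [power_design_config()]; absent keys keep their defaults.
#'
#' @param path YAML file path.
#' @return A `cohort_config` or `power_design_config`.
#' @export
read_cohort_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$outcome_specs))
    vals$outcome_specs <- lapply(vals$outcome_specs,
                                 function(sp) do.call(outcome_spec, sp))
  do.call(cohort_config, vals[intersect(names(vals),
                                        names(formals(cohort_config)))])
}

#' @rdname read_cohort_config
#' @export
read_power_design_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(power_design_config,
          vals[intersect(names(vals), names(formals(power_design_config)))])
}
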