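#' Pearson chi-square test on a contingency table
#'
#' Uncorrected Pearson test: statistic \eqn{\sum (O - E)^2 / E} with
#' expected counts from the product of marginals, df \eqn{(r-1)(c-1)}, and
#' an upper-tail chi-square p-value. No continuity correction is applied
#' (the 2x2 Yates correction would change the reported p-values and is
#' deliberately off). Small expected counts trigger a warning only — no
#' automatic switch to an exact test — since group-comparison tables in
#' small cohorts routinely contain sparse treatment cells.
#'
#' @param counts A matrix of non-negative integer counts, at least 2x2.
#' @return A list with `statistic`, `df`, `p_value`, and the `expected`
#'   count matrix.
#' @examples
#' pearson_chi_square(matrix(c(82, 29, 1, 3, 8, 1), nrow = 3, byrow = TRUE))
#' @export
pearson_chi_square <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("contingency table must be at least 2x2", call. = FALSE)
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("counts must be finite and non-negative", call. = FALSE)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero marginal total: drop empty rows/columns first", call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  if (any(ct$expected < 1))
    warning("expected count below 1 in at least one cell", call. = FALSE)
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value), expected = ct$expected)
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square reference on
#' \eqn{k - 1} degrees of freedom. For two groups this is the large-sample
#' (squared-z) Wilcoxon rank-sum test, the standard group-comparison test
#' for skewed clinical variables summarised as median/IQR. Degenerate data
#' with all values tied return \eqn{H = 0}, \eqn{p = 1}.
#'
#' @param values Numeric vector (NAs dropped with their labels).
#' @param group_labels Grouping vector, same length as `values`.
#' @return A list with `statistic` (H), `df`, `p_value`.
#' @export
kruskal_wallis <- function(values, group_labels) {
  keep <- !is.na(values) & !is.na(group_labels)
  values <- values[keep]; g <- factor(group_labels[keep])
  if (nlevels(g) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(tabulate(g) == 0L)) stop("empty group", call. = FALSE)
  if (length(unique(values)) == 1L)  # all tied: H = 0 by convention
    return(list(statistic = 0, df = nlevels(g) - 1L, p_value = 1))
  kt <- stats::kruskal.test(values, g)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p_value = unname(kt$p.value))
}

#' Median and interquartile range
#'
#' Quartiles by linear interpolation of order statistics
#' (`stats::quantile` type 7, the R default). The specific interpolation
#' convention is essentially arbitrary for reporting purposes; it is fixed
#' here so summaries are reproducible.
#'
#' @param values Numeric vector; NAs dropped. At least one non-missing
#'   value required.
#' @return Named numeric vector `c(q1, median, q3)`.
#' @examples
#' summarize_median_iqr(c(1, 2, 3, 4, 5))
#' @export
summarize_median_iqr <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("no non-missing values", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  c(q1 = q[1], median = q[2], q3 = q[3])
}

#' Group-comparison descriptive table for one visit
#'
#' Builds a clinical "Table 1"-style summary of a cohort at one visit:
#' for each outcome, the non-missing N, per-group and overall summaries
#' (median (q1, q3) for continuous variables, count (percent) for binary
#' ones) and a two-group comparison p-value (Kruskal-Wallis for continuous,
#' uncorrected Pearson chi-square for binary).
#'
#' @param cohort Long-format cohort `data.frame` (see [generate_cohort()]).
#' @param outcomes Character vector of outcome column names.
#' @param visit Which visit to summarise (`"baseline"` or `"followup"`).
#' @param scales Optional named character vector giving `"continuous"` or
#'   `"binary"` per outcome; outcomes whose observed values are all in
#'   `{0, 1}` default to binary.
#' @return A `data.frame` with one row per outcome: `variable`, `n`,
#'   formatted `group_a`, `group_b`, `all` summaries, and numeric
#'   `p_value`.
#' @export
descriptive_table <- function(cohort, outcomes, visit = "baseline",
                              scales = NULL) {
  stopifnot(visit %in% cohort$visit)
  d <- cohort[cohort$visit == visit, , drop = FALSE]
  glev <- sort(unique(d$group))
  fmt_cont <- function(v) {
    q <- summarize_median_iqr(v)
    sprintf("%.1f (%.1f, %.1f)", q["median"], q["q1"], q["q3"])
  }
  fmt_bin <- function(v) {
    v <- v[!is.na(v)]
    sprintf("%d (%.0f%%)", sum(v == 1), 100 * mean(v == 1))
  }
  rows <- lapply(outcomes, function(nm) {
    v <- d[[nm]]
    scale <- if (!is.null(scales) && nm %in% names(scales)) scales[[nm]]
             else if (all(v[!is.na(v)] %in% c(0, 1))) "binary" else "continuous"
    ok <- !is.na(v)
    p <- tryCatch({
      if (scale == "continuous") kruskal_wallis(v, d$group)$p_value
      else pearson_chi_square(table(factor(v[ok], c(0, 1)),
                                    d$group[ok]))$p_value
    }, error = function(e) NA_real_)
    fmt <- if (scale == "continuous") fmt_cont else fmt_bin
    data.frame(variable = nm, n = sum(ok),
               group_a = fmt(v[d$group == glev[1]]),
               group_b = if (length(glev) > 1) fmt(v[d$group == glev[2]]) else NA,
               all = fmt(v), p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
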