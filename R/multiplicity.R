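#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusts a family of p-values by the Benjamini-Hochberg false-discovery-
#' rate step-up procedure: sort ascending, take
#' \eqn{\tilde p_{(i)} = \min_{j \ge i} p_{(j)} \, m / j} capped at 1, and
#' map back to the original order. Ties are handled stably. In the
#' longitudinal analysis each effect column (Model-1 time, Model-2 time,
#' group, group-by-time) is adjusted as its own family of 17 outcomes.
#'
#' Missing p-values (outcomes that could not be fitted) are passed through
#' as `NA` and excluded from the family size, matching the behaviour of
#' `stats::p.adjust`.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]` (NAs allowed).
#' @return Adjusted p-values, same length and order as `p`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' bh_adjust(c(0.001, 0.5))
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("'p' must be numeric", call. = FALSE)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}
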