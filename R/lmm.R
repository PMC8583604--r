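#' Random-intercept linear mixed model for two repeated measures
#'
#' Fits the Gaussian random-intercept model
#' \deqn{y_{ij} = x_{ij}'\beta + b_i + e_{ij}, \quad
#'   b_i \sim N(0, \sigma_b^2),\; e_{ij} \sim N(0, \sigma_e^2)}
#' to a two-visit cohort by (restricted) maximum likelihood. Estimation
#' profiles the likelihood over the variance ratio
#' \eqn{\lambda = \sigma_b^2/\sigma_e^2}: for fixed \eqn{\lambda} the GLS
#' fixed effects and the residual variance are available in closed form
#' (the per-subject covariance \eqn{I + \lambda J} has an explicit inverse),
#' so the optimisation is a one-dimensional Brent search over
#' \eqn{\log\lambda}. Boundary solutions (\eqn{\sigma_b^2 = 0}, where the
#' model collapses to OLS) are detected and returned, not treated as errors.
#'
#' Inference is by two-sided Wald tests against the standard-normal
#' reference, the conventional default for mixed models without a
#' degrees-of-freedom correction. Subjects observed at only one visit
#' contribute their single observation — no listwise deletion.
#'
#' Two fixed-effect structures are supported, matching a pre-post
#' effectiveness analysis: `model = 1` fits intercept + time only;
#' `model = 2` adds the care-group main effect and the group-by-time
#' interaction (the difference between groups in mean change). Time can be
#' coded as exact days from baseline (`"days"`, for observational follow-up
#' of varying length) or as a 0/1 visit indicator (`"visit"`, the coding of
#' the power-study generative model).
#'
#' @param data A long-format `data.frame` with columns `subject_id`,
#'   `group`, `visit` (`"baseline"`/`"followup"`), `days_from_baseline`,
#'   and the outcome column.
#' @param outcome Name of the outcome column.
#' @param model `1` (time only) or `2` (time + group + group-by-time).
#' @param time_coding `"days"` or `"visit"`.
#' @param estimation `"REML"` (default) or `"ML"`.
#' @param group_ref Reference level of `group`; the other observed level is
#'   coded 1.
#' @return An object of class `lmm_fit`: a list with elements
#'   `coefficients`, `se`, `z`, `p_values` (named per term), `sigma_b2`,
#'   `sigma_e2`, `icc`, `loglik`, `estimation`, `n_subjects`,
#'   `n_observations`, `converged`, `boundary`.
#' @examples
#' d <- generate_power_dataset(power_design_config(seed = 3))
#' fit <- fit_random_intercept_lmm(d, "y", model = 2, time_coding = "visit")
#' fit
#' @export
fit_random_intercept_lmm <- function(data, outcome, model = 2,
                                     time_coding = c("days", "visit"),
                                     estimation = c("REML", "ML"),
                                     group_ref = "PDTA") {
  time_coding <- match.arg(time_coding)
  estimation <- match.arg(estimation)
  stopifnot(is.data.frame(data), outcome %in% names(data))
  if (!model %in% c(1, 2)) stop("'model' must be 1 or 2", call. = FALSE)

  y <- data[[outcome]]
  keep <- !is.na(y)
  if (!any(keep)) stop(sprintf("outcome '%s' is entirely missing", outcome),
                       call. = FALSE)
  tt <- if (time_coding == "days") data$days_from_baseline else
    as.numeric(data$visit == "followup")
  terms <- c("(Intercept)", "time")
  X <- cbind(1, tt)
  if (model == 2) {
    lev <- unique(data$group)
    if (!group_ref %in% lev)
      stop(sprintf("reference group '%s' not present", group_ref), call. = FALSE)
    g <- as.numeric(data$group != group_ref)
    X <- cbind(X, g, tt * g)
    terms <- c(terms, "group", "time:group")
  }
  keep <- keep & stats::complete.cases(X)
  X <- X[keep, , drop = FALSE]
  colnames(X) <- terms
  fit <- .ri_lmm_engine(y[keep], X, data$subject_id[keep],
                        reml = estimation == "REML")
  fit$outcome <- outcome
  fit$estimation <- estimation
  fit$time_coding <- time_coding
  fit$model <- model
  fit
}

# Core profile-likelihood engine. Sufficient statistics are per-subject
# column sums, so each objective evaluation is O(n_subjects * p):
#   (I + lam J)^-1 = I - lam/(1 + n_i lam) J
#   X'WX = X'X - sum_i c_i s_i s_i',  c_i = lam/(1 + n_i lam)
.ri_lmm_engine <- function(y, X, subject, reml = TRUE) {
  sf <- factor(subject)
  ni <- tabulate(sf)
  N <- length(y); p <- ncol(X)
  if (N <= p) stop("too few observations for the fixed-effect structure",
                   call. = FALSE)
  # standardize the outcome internally so the profiled objective is
  # invariant (to rounding) under location and scale changes of y; all
  # results are transformed back to the original scale below
  y_loc <- mean(y)
  y_scl <- stats::sd(y)
  if (!is.finite(y_scl) || y_scl == 0) y_scl <- 1
  y <- (y - y_loc) / y_scl
  Sx <- rowsum(X, sf); Sy <- rowsum(y, sf)[, 1]
  si <- as.integer(sf)
  yty <- sum(y * y)

  # half-weighting: (I + lam J)^{-1/2} = I - (theta/n_i) J with
  # theta = 1 - 1/sqrt(1 + n_i lam); GLS becomes ordinary least squares on
  # the transformed data, solved by QR for numerical stability
  gls <- function(lam) {
    th <- 1 - 1 / sqrt(1 + ni * lam)
    f <- (th / ni)[si]
    Xt <- X - f * Sx[si, , drop = FALSE]
    yt <- y - f * Sy[si]
    dec <- qr(Xt)
    beta <- qr.coef(dec, yt)
    rss <- sum(qr.resid(dec, yt)^2)
    list(beta = beta, XtWX = crossprod(Xt), rss = rss,
         logdet_v = sum(log1p(ni * lam)))
  }
  dfree <- if (reml) N - p else N
  objective <- function(loglam) {
    f <- gls(exp(loglam))
    if (f$rss <= 0) return(Inf)
    val <- dfree * log(f$rss / dfree) + f$logdet_v
    if (reml) val <- val + determinant(f$XtWX, logarithm = TRUE)$modulus
    as.numeric(val)
  }

  lo <- log(1e-8); hi <- log(1e8)
  opt <- stats::optimize(objective, c(lo, hi), tol = 1e-9)
  converged <- is.finite(opt$objective)
  # boundary check: sigma_b^2 = 0 when the profile keeps decreasing toward
  # lambda -> 0 (objective is flat below lam ~ 1e-8 in double precision)
  boundary <- FALSE
  lam <- exp(opt$minimum)
  if (opt$minimum <= lo + 1e-6 || objective(lo) <= opt$objective + 1e-10) {
    lam <- 0; boundary <- TRUE
  }
  f <- gls(lam)
  sigma_e2 <- f$rss / dfree
  if (f$rss <= .Machine$double.eps * yty) {
    boundary <- TRUE
    warning("zero residual variation: degenerate fit", call. = FALSE)
  }
  vcov_beta <- solve(f$XtWX) * sigma_e2
  se <- sqrt(pmax(diag(vcov_beta), 0))
  beta <- drop(f$beta)
  # back to the original outcome scale
  intercept <- which(colnames(X) == "(Intercept)")
  beta <- beta * y_scl
  if (length(intercept)) beta[intercept] <- beta[intercept] + y_loc
  se <- se * y_scl
  vcov_beta <- vcov_beta * y_scl^2
  sigma_e2 <- sigma_e2 * y_scl^2
  z <- ifelse(se > 0, beta / se, sign(beta) * Inf)
  pv <- 2 * stats::pnorm(-abs(z))
  # full log-likelihood at the optimum (lme4's REML constant convention:
  # the log|X'WX| term enters unscaled by sigma_e^2)
  ll <- -0.5 * (dfree * log(2 * pi * sigma_e2) + f$logdet_v + dfree)
  if (reml) ll <- ll - 0.5 * as.numeric(
    determinant(f$XtWX, logarithm = TRUE)$modulus)
  structure(
    list(coefficients = stats::setNames(beta, colnames(X)),
         se = stats::setNames(se, colnames(X)),
         z = stats::setNames(z, colnames(X)),
         p_values = stats::setNames(pv, colnames(X)),
         vcov = vcov_beta,
         sigma_b2 = lam * sigma_e2, sigma_e2 = sigma_e2,
         icc = lam / (1 + lam),
         loglik = ll, n_subjects = nlevels(sf), n_observations = N,
         converged = converged, boundary = boundary),
    class = "lmm_fit")
}

#' Two-sided Wald p-value for one fitted term
#'
#' @param fit An `lmm_fit`.
#' @param term Term name, e.g. `"time"`, `"group"`, `"time:group"`.
#' @return The two-sided p-value \eqn{2(1 - \Phi(|\hat\beta|/SE))}. A zero
#'   standard error yields `p = 0` with a warning (degenerate fit).
#' @export
wald_p <- function(fit, term) {
  stopifnot(inherits(fit, "lmm_fit"))
  if (!term %in% names(fit$coefficients))
    stop(sprintf("term '%s' not in fit", term), call. = FALSE)
  if (fit$se[[term]] == 0) {
    warning("zero standard error: degenerate fit", call. = FALSE)
    return(0)
  }
  unname(2 * stats::pnorm(-abs(fit$coefficients[[term]] / fit$se[[term]])))
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("Random-intercept LMM (%s), outcome '%s'\n",
              x$estimation, x$outcome %||% "?"))
  cat(sprintf("  %d subjects, %d observations%s\n", x$n_subjects,
              x$n_observations,
              if (isTRUE(x$boundary)) "  [boundary: sigma_b^2 = 0]" else ""))
  tab <- data.frame(Estimate = x$coefficients, `Std.Error` = x$se,
                    z = x$z, `p` = x$p_values, check.names = FALSE)
  print(round(tab, 4))
  cat(sprintf("  sigma_b^2 = %.4f  sigma_e^2 = %.4f  ICC = %.3f  logLik = %.2f\n",
              x$sigma_b2, x$sigma_e2, x$icc, x$loglik))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
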