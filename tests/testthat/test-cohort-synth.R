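test_that("cohort generation is deterministic and has the configured shape", {
  cfg <- cohort_config(seed = 99)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)

  expect_equal(nrow(c1), 248)
  expect_equal(unname(table(c1$group) / 2), c(91, 33), ignore_attr = TRUE)
  expect_true(all(table(c1$subject_id) == 2))
  expect_true(all(c1$days_from_baseline[c1$visit == "baseline"] == 0))
  expect_true(all(c1$days_from_baseline[c1$visit == "followup"] > 0))

  c3 <- generate_cohort(cohort_config(seed = 100))
  expect_false(identical(c1$hba1c, c3$hba1c))
})

test_that("per-outcome non-missing counts are exact, not expected values", {
  coh <- generate_cohort(cohort_config(seed = 7))
  specs <- default_outcome_specs()
  n <- 124
  for (sp in specs) {
    nb <- sum(!is.na(coh[[sp$name]][coh$visit == "baseline"]))
    nf <- sum(!is.na(coh[[sp$name]][coh$visit == "followup"]))
    expect_equal(nb, n - sp$missing_baseline, info = sp$name)
    expect_equal(nf, n - sp$missing_followup, info = sp$name)
  }
  # the sparse renal marker in particular
  expect_equal(sum(!is.na(coh$microalbuminuria[coh$visit == "baseline"])), 111)
  expect_equal(sum(!is.na(coh$microalbuminuria[coh$visit == "followup"])), 107)
})

test_that("zero spread degenerates to a point mass shifted at follow-up", {
  specs <- list(
    outcome_spec("flat", "continuous", "u", baseline_location = 5,
                 baseline_spread = 0, followup_shift = 2),
    outcome_spec("flatlog", "continuous", "u", baseline_location = 5,
                 baseline_spread = 0, followup_shift = 2, family = "lognormal"))
  coh <- generate_cohort(cohort_config(n_group_a = 10, n_group_b = 5,
                                       outcome_specs = specs, seed = 3))
  for (nm in c("flat", "flatlog")) {
    expect_true(all(coh[[nm]][coh$visit == "baseline"] == 5))
    expect_true(all(abs(coh[[nm]][coh$visit == "followup"] - 7) < 1e-12))
  }
})

test_that("invalid configurations are rejected", {
  bad <- default_outcome_specs()
  bad$hba1c$missing_baseline <- 200L
  expect_error(cohort_config(outcome_specs = bad), "missing count")
  expect_error(outcome_spec("x", "continuous", baseline_location = 1,
                            baseline_spread = -1), "non-negative")
  expect_error(outcome_spec("x", "binary", baseline_location = 1.2),
               "proportion")
  expect_error(power_design_config(icc = 1), "icc")
  expect_error(power_design_config(icc = 0.9999999), NA)
  expect_error(power_design_config(sd_total = 0), "positive")
  expect_error(power_design_config(allocation = c(10, 10), n_total = 30),
               "sum")
})

test_that("large-cohort medians and IQRs converge to their targets", {
  specs <- default_outcome_specs()
  cfg <- cohort_config(n_group_a = 7000, n_group_b = 3000,
                       outcome_specs = specs, seed = 12)
  coh <- generate_cohort(cfg)
  base <- coh[coh$visit == "baseline", ]
  # asymptotic SE of an empirical p-quantile: sqrt(p(1-p)/n) / f(q_p);
  # heavy-tailed families need this on top of the 2% convergence band
  q_se <- function(sp, p, n) {
    q <- stats::qnorm(p)
    a <- stats::qnorm(0.75)
    dens <- switch(sp$family,
      lognormal = {
        s <- asinh(sp$baseline_spread / (2 * sp$baseline_location)) / a
        stats::dlnorm(sp$baseline_location * exp(s * q),
                      log(sp$baseline_location), s)
      },
      stats::dnorm(sp$baseline_location + .iqr_to_sd(sp$baseline_spread) * q,
                   sp$baseline_location, .iqr_to_sd(sp$baseline_spread)))
    sqrt(p * (1 - p) / n) / dens
  }
  for (sp in specs) {
    if (sp$scale != "continuous" || sp$family == "censored-normal") next
    n_obs <- 10000 - sp$missing_baseline
    q <- summarize_median_iqr(base[[sp$name]])
    tol_med <- 0.02 * sp$baseline_location + 3 * q_se(sp, 0.5, n_obs)
    expect_lt(abs(q[["median"]] - sp$baseline_location), tol_med,
              label = paste(sp$name, "median err"))
    tol_iqr <- 0.02 * sp$baseline_spread +
      3 * sqrt(q_se(sp, 0.25, n_obs)^2 + q_se(sp, 0.75, n_obs)^2)
    expect_lt(abs((q[["q3"]] - q[["q1"]]) - sp$baseline_spread), tol_iqr,
              label = paste(sp$name, "IQR err"))
  }
  # the zero-censored intake variable: median 0, censored IQR = target
  alc <- base$alcohol
  expect_lt(abs(median(alc)), 0.5)
  expect_lt(abs(unname(diff(quantile(alc, c(0.25, 0.75)))) - 12), 1.0)
  # binary outcomes hit their proportions
  pa <- mean(base$physical_activity_mod_intense, na.rm = TRUE)
  expect_lt(abs(pa - 13 / 124), 0.02)
})

test_that("power-design data follow the stated generative model", {
  des <- power_design_config(n_total = 10000, allocation = c(5000, 5000),
                             icc = 0.5, seed = 21)
  d <- generate_power_dataset(des)
  expect_equal(nrow(d), 20000)

  # cell mean: treated arm at follow-up = 51 + 2.6 * 3
  m <- mean(d$y[d$group == "PDTA_CAD" & d$time == 1])
  expect_lt(abs(m - 58.7), 3 * 3.3 / sqrt(5000) * 3)

  # within-arm correlation between visits equals the configured ICC
  # (within one arm the two visits differ only by a constant shift)
  y0 <- d$y[d$time == 0]; y1 <- d$y[d$time == 1]
  ctrl <- d$group[d$time == 0] == "PDTA"
  expect_lt(abs(cor(y0[ctrl], y1[ctrl]) - 0.5), 0.02)
  expect_lt(abs(cor(y0[!ctrl], y1[!ctrl]) - 0.5), 0.02)

  # change-score variance in the control arm: subject effect cancels
  v <- var(y1[ctrl] - y0[ctrl])
  expect_lt(abs(v / (2 * des$sigma_e2) - 1), 0.05)

  # icc = 0 with only an intercept: visits uncorrelated within subject
  d0 <- generate_power_dataset(power_design_config(
    n_total = 4000, allocation = c(2000, 2000), beta_time = 0,
    beta_group = 0, beta_interaction = 0, icc = 0, seed = 4))
  expect_lt(abs(cor(d0$y[d0$time == 0], d0$y[d0$time == 1])), 0.05)
})

test_that("cohort CSV round-trips with empty-field missing values", {
  coh <- generate_cohort(cohort_config(seed = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(back$hba1c, coh$hba1c)
  expect_equal(sum(is.na(back$microalbuminuria)),
               sum(is.na(coh$microalbuminuria)))
  expect_equal(back$subject_id, coh$subject_id)
})
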