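test_that("closed-form identities hold on complete balanced data", {
  fit <- fit_random_intercept_lmm(hand_fixture(), "y", model = 2,
                                  time_coding = "visit")
  # interaction = difference of group mean changes: (5 + 2 = deliberately
  # unequal changes) -> (26 - 21) - (15 - 12) ... hand: changes 2,2,5,5
  expect_equal(unname(fit$coefficients["time:group"]), 3, tolerance = 1e-10)
  expect_equal(unname(fit$coefficients["time"]), 2, tolerance = 1e-10)
  expect_equal(unname(fit$coefficients["group"]), 9, tolerance = 1e-10)
  expect_equal(unname(fit$coefficients["(Intercept)"]), 12, tolerance = 1e-10)

  # on larger random balanced data the identity still holds exactly
  set.seed(31)
  d <- sim_prepost(n_per_group = 25)
  f <- fit_random_intercept_lmm(d, "y", model = 2, time_coding = "visit")
  ch <- with(d, tapply(y, list(subject_id, visit), mean))
  change <- ch[, "followup"] - ch[, "baseline"]
  grp <- d$group[match(rownames(ch), d$subject_id)]
  expect_equal(unname(f$coefficients["time:group"]),
               mean(change[grp == "PDTA_CAD"]) - mean(change[grp == "PDTA"]),
               tolerance = 1e-10)
  expect_equal(unname(f$coefficients["time"]),
               mean(change[grp == "PDTA"]), tolerance = 1e-10)
})

test_that("no between-subject variance collapses the model to OLS", {
  set.seed(8)
  d <- sim_prepost(n_per_group = 40, icc = 0)
  fit <- fit_random_intercept_lmm(d, "y", model = 2, time_coding = "visit",
                                  estimation = "ML")
  g <- as.numeric(d$group == "PDTA_CAD")
  t <- as.numeric(d$visit == "followup")
  ols <- lm(d$y ~ t * g)
  # on complete balanced data the GLS fixed effects equal OLS for any
  # variance ratio, and the fitted subject variance sits near its boundary
  expect_lt(fit$sigma_b2, fit$sigma_e2)
  expect_equal(unname(fit$coefficients), unname(coef(ols)), tolerance = 1e-8)
})

test_that("estimates match the reference mixed-model implementation", {
  skip_if_not_installed("lme4")
  set.seed(14)
  for (rep in 1:5) {
    d <- sim_prepost(n_per_group = 60, icc = runif(1, 0.2, 0.8))
    # make it unbalanced: drop one visit for ~10% of subjects
    drop_ids <- sample(unique(d$subject_id), 12)
    drop_rows <- d$subject_id %in% drop_ids &
      d$visit == sample(c("baseline", "followup"), 1)
    d$y[drop_rows] <- NA
    for (est in c("REML", "ML")) {
      fit <- fit_random_intercept_lmm(d, "y", model = 2,
                                      time_coding = "visit", estimation = est)
      dd <- d[!is.na(d$y), ]
      dd$t <- as.numeric(dd$visit == "followup")
      dd$g <- as.numeric(dd$group == "PDTA_CAD")
      ref <- lme4::lmer(y ~ t * g + (1 | subject_id), dd, REML = est == "REML")
      expect_equal(unname(fit$coefficients), unname(lme4::fixef(ref)),
                   tolerance = 1e-6)
      expect_equal(unname(fit$se), unname(sqrt(diag(as.matrix(vcov(ref))))),
                   tolerance = 1e-6)
      vc <- as.data.frame(lme4::VarCorr(ref))
      expect_equal(fit$sigma_b2, vc$vcov[1], tolerance = 1e-4)
      expect_equal(fit$sigma_e2, vc$vcov[2], tolerance = 1e-4)
      expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-6)
    }
  }
})

test_that("single-visit subjects are retained, not listwise deleted", {
  set.seed(5)
  d <- sim_prepost(n_per_group = 30)
  d$y[d$subject_id == "P0001" & d$visit == "followup"] <- NA
  fit <- fit_random_intercept_lmm(d, "y", model = 2, time_coding = "visit")
  expect_equal(fit$n_observations, 119)
  expect_equal(fit$n_subjects, 60)
})

test_that("location invariance and scale equivariance", {
  set.seed(77)
  d <- sim_prepost(n_per_group = 40)
  f0 <- fit_random_intercept_lmm(d, "y", model = 2, time_coding = "visit")

  d$y <- d$y + 100
  f1 <- fit_random_intercept_lmm(d, "y", model = 2, time_coding = "visit")
  expect_equal(unname(f1$coefficients["(Intercept)"]),
               unname(f0$coefficients["(Intercept)"]) + 100, tolerance = 1e-9)
  expect_equal(f1$coefficients[-1], f0$coefficients[-1], tolerance = 1e-9)
  expect_equal(f1$se, f0$se, tolerance = 1e-9)
  expect_equal(f1$sigma_b2, f0$sigma_b2, tolerance = 1e-7)

  d$y <- (d$y - 100) * 3
  f3 <- fit_random_intercept_lmm(d, "y", model = 2, time_coding = "visit")
  expect_equal(unname(f3$coefficients), unname(f0$coefficients) * 3,
               tolerance = 1e-7)
  expect_equal(unname(f3$se), unname(f0$se) * 3, tolerance = 1e-7)
  expect_equal(f3$sigma_e2, f0$sigma_e2 * 9, tolerance = 1e-6)
  expect_equal(f3$sigma_b2, f0$sigma_b2 * 9, tolerance = 1e-5)
})

test_that("ML and REML agree on fixed effects; REML variances are larger", {
  set.seed(50)
  d <- sim_prepost(n_per_group = 50)
  fr <- fit_random_intercept_lmm(d, "y", model = 2, time_coding = "visit",
                                 estimation = "REML")
  fm <- fit_random_intercept_lmm(d, "y", model = 2, time_coding = "visit",
                                 estimation = "ML")
  expect_equal(fr$coefficients, fm$coefficients, tolerance = 1e-6)
  expect_gte(fr$sigma_e2, fm$sigma_e2 - 1e-10)
  expect_gte(fr$sigma_b2 + fr$sigma_e2, fm$sigma_b2 + fm$sigma_e2 - 1e-10)
})

test_that("Wald p-values follow the normal-reference identities", {
  fit <- structure(list(coefficients = c(x = 1.959964), se = c(x = 1)),
                   class = "lmm_fit")
  expect_equal(wald_p(fit, "x"), 0.05, tolerance = 1e-6)

  fit$coefficients <- c(x = 0)
  expect_equal(wald_p(fit, "x"), 1)

  fit$coefficients <- c(x = 2.6); fit$se <- c(x = 0.5927)
  expect_equal(wald_p(fit, "x"), 2 * pnorm(-2.6 / 0.5927), tolerance = 1e-12)
  expect_equal(wald_p(fit, "x"), 1.15e-5, tolerance = 0.01)

  fit$se <- c(x = 0)
  expect_warning(p0 <- wald_p(fit, "x"), "degenerate")
  expect_equal(p0, 0)
  expect_error(wald_p(fit, "nope"), "not in fit")
})

test_that("degenerate inputs raise informative errors", {
  d <- sim_prepost(n_per_group = 5)
  d$y <- NA_real_
  expect_error(fit_random_intercept_lmm(d, "y"), "entirely missing")
  expect_error(fit_random_intercept_lmm(hand_fixture(), "y", model = 2,
                                        group_ref = "XX"), "not present")
})
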