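zero_re_truth <- function(seed = 2) {
  eps <- default_endpoints()
  eps$BEI$sd_patient <- 0; eps$BEI$sd_region <- 0; eps$BEI$sd_resid <- 0.1
  cohort_truth(n_subjects = 12, endpoints = eps, seed = seed)
}

test_that("with zero random-effect variance the LMM reduces to OLS", {
  coh <- simulate_cohort(zero_re_truth())
  fm <- crosssectional_model(coh, "BEI", robust = FALSE)
  ols <- stats::lm(BEI ~ age_years + A3 + factor(timepoint_months),
                   data = coh)
  expect_lt(max(abs(fm$coefs$estimate - stats::coef(ols))), 1e-6)
  expect_true(fm$singular)
})

test_that("reported fixed effects equal the GLS solution at the fitted variance components", {
  coh <- simulate_cohort(cohort_truth(n_subjects = 10, seed = 4))
  fm <- crosssectional_model(coh, "BEI", robust = FALSE)
  # rebuild V = Zp Zp' sd_p^2 + Zc Zc' sd_c^2 + sigma^2 I from the fit's
  # variance components and solve GLS directly
  vc <- fm$varcomp
  sd_p <- vc$sdcor[vc$grp == "subject"]
  sd_c <- vc$sdcor[vc$grp == "subject:region"]
  sig <- vc$sdcor[vc$grp == "Residual"]
  X <- stats::model.matrix(~ age_years + A3 + factor(timepoint_months), coh)
  Zp <- stats::model.matrix(~ 0 + subject, coh)
  Zc <- stats::model.matrix(~ 0 + interaction(subject, region), coh)
  V <- sd_p^2 * tcrossprod(Zp) + sd_c^2 * tcrossprod(Zc) +
    sig^2 * diag(nrow(coh))
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% coh$BEI)
  expect_lt(max(abs(fm$coefs$estimate - as.numeric(beta))), 1e-4)
})

test_that("beta mixed model with tiny dispersion agrees with a logit LMM", {
  eps <- list(WP = list(
    family = "beta", intercept = 0.4, beta_age = -0.04, beta_A3 = 0.01,
    beta_tp = c("3" = 0, "12" = 0, "24" = 0),
    sd_patient = 0.1, sd_region = 0.05, phi = 4000
  ))
  coh <- simulate_cohort(cohort_truth(n_subjects = 25, endpoints = eps,
                                      seed = 6))
  coh$WP01 <- coh$WP / 100
  spec_b <- qct_model_spec("WP01", family = "beta",
                           fixed = c("age_years", "A3"),
                           random = c("subject", "subject:region"),
                           robust = FALSE)
  fb <- fit_mixed(coh, spec_b)
  coh$logit_wp <- stats::qlogis(coh$WP01)
  spec_l <- qct_model_spec("logit_wp", family = "linear",
                           fixed = c("age_years", "A3"),
                           random = c("subject", "subject:region"),
                           robust = FALSE)
  fl <- fit_mixed(coh, spec_l)
  for (term in c("age_years", "A3")) {
    b <- fb$coefs$estimate[fb$coefs$term == term]
    l <- fl$coefs$estimate[fl$coefs$term == term]
    expect_lt(abs(b - l) / max(abs(l), 1e-6), 0.05)
  }
})

test_that("robust fits downweight planted outliers more than plain REML", {
  coh <- simulate_cohort(cohort_truth(n_subjects = 15, seed = 8))
  contaminated <- coh
  idx <- seq(1, nrow(coh), by = 37)
  contaminated$BEI[idx] <- contaminated$BEI[idx] + 15
  plain <- crosssectional_model(contaminated, "BEI", robust = FALSE)
  rob <- crosssectional_model(contaminated, "BEI", robust = TRUE)
  clean <- crosssectional_model(coh, "BEI", robust = FALSE)
  err <- function(f) {
    abs(f$coefs$estimate[f$coefs$term == "age_years"] -
          clean$coefs$estimate[clean$coefs$term == "age_years"])
  }
  expect_lt(err(rob), err(plain))
})

test_that("a constant endpoint is rejected", {
  coh <- simulate_cohort(cohort_truth(n_subjects = 4, seed = 1))
  coh$BEI <- 1
  expect_error(crosssectional_model(coh, "BEI"), "zero variance")
})

test_that("model reports echo formula, scale and flags", {
  coh <- simulate_cohort(cohort_truth(n_subjects = 6, seed = 3))
  fm <- crosssectional_model(coh, "WP_5_10", robust = FALSE)
  expect_match(fm$formula, "WP_5_10 ~ age_years \\+ A3")
  expect_match(fm$scale, "logit")
  td <- tidy(fm)
  expect_true(all(c("estimate", "std_error", "ci_lo", "ci_hi", "p_value")
                  %in% names(td)))
  expect_true(all(td$ci_lo <= td$estimate & td$estimate <= td$ci_hi))
  expect_true(all(td$std_error > 0))
  g <- glance(fm)
  expect_identical(g$family, "beta")
  expect_output(print(fm), "descriptive")
})

test_that("pure tracking yields baseline coefficient 1 and null covariates", {
  coh <- simulate_cohort(cohort_truth(n_subjects = 20, seed = 5))
  key <- paste(coh$subject, coh$region)
  base <- coh[coh$timepoint_months == 0, ]
  coh$BEI <- base$BEI[match(key, paste(base$subject, base$region))]
  ft <- suppressWarnings(longitudinal_model(coh, "BEI", c(0, 24),
                                            robust = FALSE))
  cf <- ft$coefs
  expect_lt(abs(cf$estimate[cf$term == "baseline_endpoint"] - 1), 1e-6)
  expect_lt(abs(cf$estimate[cf$term == "age_years"]), 1e-6)
  expect_lt(abs(cf$estimate[cf$term == "A3"]), 1e-6)
})

test_that("an interval with no overlapping subjects is a validation error", {
  coh <- simulate_cohort(cohort_truth(n_subjects = 6, seed = 7))
  half <- coh[!(coh$timepoint_months == 24 & coh$subject <= "S003") &
                !(coh$timepoint_months == 0 & coh$subject > "S003"), ]
  expect_error(longitudinal_model(half, "BEI", c(0, 99)), "not present|no subject|missing")
  none <- coh[coh$timepoint_months != 24, ]
  expect_error(longitudinal_model(none, "BEI", c(0, 24)), "both visits|no subject")
})

test_that("autoplot produces a forest plot without evaluation errors", {
  coh <- simulate_cohort(cohort_truth(n_subjects = 6, seed = 3))
  fm <- crosssectional_model(coh, "BEI", robust = FALSE)
  p <- autoplot(fm)
  expect_s3_class(p, "ggplot")
  built <- ggplot2::ggplot_build(p)
  expect_gt(nrow(built$data[[2]]), 0)
})
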