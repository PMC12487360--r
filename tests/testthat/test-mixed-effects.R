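test_that("without replication the LMM reduces exactly to OLS", {
  set.seed(1)
  d <- data.frame(subject = 1:24,
                  age_days = rep(c(90, 110, 130, 150), 6),
                  sex = rep(c("F", "M"), each = 12))
  d$resid <- rnorm(24)
  f <- fit_random_intercept_lmm(d)
  ols <- lm(resid ~ age_days * factor(sex, levels = c("F", "M")), d)
  expect_equal(f$coefficients$estimate, unname(coef(ols)), tolerance = 1e-8)
  expect_equal(f$coefficients$se,
               unname(summary(ols)$coefficients[, 2]), tolerance = 1e-8)
  expect_identical(f$var_subject, 0)
  expect_true(f$boundary)
  # classical residual df: n_subjects minus the rank of the between design
  expect_equal(unique(f$coefficients$df), 24 - 4)
})

test_that("REML recovers the generating variance components on average", {
  vs <- vapply(1:100, function(s) {
    fit_random_intercept_lmm(balanced_lmm_data(var_s = 4, var_e = 1,
                                               seed = s))$var_subject
  }, numeric(1))
  expect_equal(mean(vs), 4, tolerance = 0.1)
})

test_that("REML solution matches a brute-force grid oracle", {
  d <- balanced_lmm_data(seed = 7)
  f <- fit_random_intercept_lmm(d)
  X <- model.matrix(~ age_days * factor(sex, levels = c("F", "M")), d)
  g <- reml_grid_betas(d$resid, X, d$subject,
                       vs_grid = seq(0.5, 8, by = 0.05),
                       ve_grid = seq(0.3, 3, by = 0.02))
  expect_equal(f$coefficients$estimate, g$beta, tolerance = 1e-4)
  expect_equal(f$var_subject, g$var_s, tolerance = 0.1)
})

test_that("a zero subject variance reproduces the OLS likelihood", {
  d <- balanced_lmm_data(var_s = 0, var_e = 1, seed = 3)
  X <- model.matrix(~ age_days * factor(sex, levels = c("F", "M")), d)
  ols <- lm(resid ~ age_days * factor(sex, levels = c("F", "M")), d)
  # REML criterion at var_s = 0 equals the restricted Gaussian likelihood
  # of the OLS model; its optimum in var_e is rss / (n - p)
  n <- nrow(d); p <- ncol(X)
  s2 <- sum(residuals(ols)^2) / (n - p)
  ll0 <- reml_loglik(d$resid, X, d$subject, 0 + 1e-12, s2)
  ll_near <- reml_loglik(d$resid, X, d$subject, 0 + 1e-12, s2 * 1.2)
  expect_gt(ll0, ll_near)
  Z <- model.matrix(~ 0 + factor(subject), d)
  beta_gls <- solve(crossprod(X), crossprod(X, d$resid))
  expect_equal(as.numeric(beta_gls), unname(coef(ols)), tolerance = 1e-10)
})

test_that("Bonferroni adjustment clips at 1 and scales by m", {
  expect_equal(bonferroni_adjust(0.01, 6), 0.06)
  expect_equal(bonferroni_adjust(0.5, 6), 1.0)
  # a cortical-plate-sized interaction p survives correction across 6 regions
  expect_equal(bonferroni_adjust(0.0048, 6), 0.0288)
  expect_lt(bonferroni_adjust(0.0048, 6), 0.05)
  expect_error(bonferroni_adjust(1.2, 3))
})

test_that("residual analysis recovers an injected male age-slope excess", {
  models <- atlas_growth_parameters()
  pooled <- models[!(models$region == "whole_brain" & models$sex == "M"), ]
  pooled$sex[pooled$region == "whole_brain"] <- "both"
  pooled <- pooled[pooled$region == "whole_brain", ]
  est <- vapply(1:30, function(s) {
    tab <- simulate_cohort(models = pooled,
                           sex_effect = c(whole_brain = 0.014), seed = s)
    r <- residual_effect_analysis(tab, "whole_brain")
    r$coefficients$estimate[4]
  }, numeric(1))
  expect_gt(median(est), 0)
  expect_lt(abs(median(est) - 0.014), 0.5 * 0.014)
})

test_that("degenerate covariates are rejected", {
  tab <- simulate_cohort(seed = 2)
  tab$flat <- "x"
  expect_error(residual_effect_analysis(tab, "whole_brain",
                                        covariate = "flat"), "vary")
  expect_error(residual_effect_analysis(tab, "no_such_region"),
               "not present")
})

test_that("a confound aliasing sex reproduces the sex analysis", {
  tab <- simulate_cohort(seed = 4)
  tab$scanner <- tab$sex  # perfect alias
  sex_res <- residual_effect_analysis(tab, "whole_brain", m = 5)
  scr <- confound_screen(tab, "whole_brain",
                         confounds = c("scanner", "scan_number"), m = 5)
  expect_equal(scr$scanner$coefficients$estimate,
               sex_res$coefficients$estimate, tolerance = 1e-10)
  expect_equal(scr$scanner$coefficients$p, sex_res$coefficients$p,
               tolerance = 1e-10)
  # ordinal scan number yields the standard 4 coefficient rows
  expect_equal(nrow(scr$scan_number$coefficients), 4)
})

test_that("single-level confounds are skipped with a warning", {
  tab <- simulate_cohort(seed = 5)
  tab$sequence <- "TSE"
  expect_warning(
    scr <- confound_screen(tab, "whole_brain",
                           confounds = c("sequence", "scanner")),
    "single level")
  expect_named(scr, "scanner")
  expect_error(confound_screen(tab, "whole_brain", confounds = "absent"),
               "absent")
})

test_that("an independent confound rarely reaches significance", {
  hits <- vapply(1:40, function(s) {
    tab <- simulate_cohort(models = atlas_growth_parameters()[
      atlas_growth_parameters()$region == "whole_brain", ], seed = s)
    scr <- confound_screen(tab, "whole_brain", confounds = "sequence", m = 1)
    any(scr$sequence$coefficients$p[3:4] < 0.05)
  }, logical(1))
  expect_lte(mean(hits), 0.2)
})
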