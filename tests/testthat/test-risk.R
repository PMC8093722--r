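# small synthetic analysis table with the questionnaire covariates
toy_table <- function(n = 40, n_sites = 4, seed = 1) {
  with_seed <- freeroam:::with_seed
  with_seed(seed, {
    data.frame(
      dog_id = sprintf("d%02d", 1:n),
      site = paste0("site", rep_len(1:n_sites, n)),
      age_class = sample(c("<1 yr", "1-5 yr", ">5 yr"), n, TRUE,
                         prob = c(0.1, 0.7, 0.2)),
      sex_status = sample(c("intact male", "castrated male",
                            "intact female", "spayed female"), n, TRUE),
      reported_time_outside = sample(c("<2 h", "2-6 h", ">6 h"), n, TRUE),
      fixes_per_hour = runif(n, 5, 30),
      recording_hours = runif(n, 30, 150),
      daily_distance_km = rlnorm(n, 2.5, 0.3),
      core_hr_ha = rlnorm(n, -1, 0.5),
      extended_hr_ha = rlnorm(n, 2.2, 0.6),
      pct_time_household = runif(n, 5, 75))
  })
}

test_that("outcome preparation transforms, dichotomizes and screens", {
  tab <- toy_table()
  tab$core_hr_ha[1] <- 0.25
  prep <- prepare_outcomes(tab)
  expect_equal(prep$sqrt_core_hr[1], 0.5)
  expect_equal(prep$log_extended_hr, log(tab$extended_hr_ha))
  expect_equal(levels(prep$age_dichot), c("<1 yr", ">=1 yr"))
  expect_equal(levels(prep$sex_status)[1], "intact male")
  # independent outcomes: nothing flagged
  expect_equal(nrow(attr(prep, "collinear_pairs")), 0)
  expect_true(all(abs(attr(prep, "outcome_cor")[upper.tri(diag(4))]) < 0.7))
  # a duplicated outcome is flagged at r = 1
  dup <- tab
  dup$pct_time_household <- dup$daily_distance_km
  flagged <- attr(prepare_outcomes(dup), "collinear_pairs")
  expect_equal(nrow(flagged), 1)
  expect_equal(flagged$r, 1)
  # log transform refuses non-positive areas
  bad <- tab
  bad$extended_hr_ha[3] <- 0
  expect_error(prepare_outcomes(bad), "non-positive")
})

test_that("mixed fits report coefficients, variance components and ICC", {
  tab <- prepare_outcomes(toy_table(n = 60, n_sites = 6, seed = 3))
  fit <- fit_mixed_model(tab, "daily_distance_km",
                         c("age_dichot", "sex_status", "fixes_per_hour"))
  expect_s3_class(fit, "mixed_fit")
  expect_equal(nrow(fit$coefficients), 6)  # intercept + 1 + 3 + 1
  expect_true(all(c("age_dichot", "sex_status", "fixes_per_hour") %in%
                  fit$term_tests$term))
  expect_gte(fit$var_between, 0)
  expect_gt(fit$var_within, 0)
  expect_true(fit$icc >= 0 && fit$icc <= 1)
  expect_equal(compute_icc(fit), fit$icc)
})

test_that("the ICC is the between-share of total variance", {
  fake <- structure(list(var_between = 2, var_within = 2), class = "mixed_fit")
  expect_equal(compute_icc(fake), 0.5)
  fake$var_between <- 0
  expect_equal(compute_icc(fake), 0)
  fake$var_within <- 0
  expect_warning(expect_true(is.na(compute_icc(fake))), "undefined")
})

test_that("a boundary fit with no site variance matches ordinary regression", {
  # seed chosen so REML lands exactly on the zero-variance boundary
  tab <- simulate_analysis_table(n = 73, n_sites = 8, beta = 2,
                                 sigma_site = 0, sigma_resid = 1, seed = 1)
  fit <- suppressMessages(fit_mixed_model(tab, "y", "x"))
  expect_true(fit$singular)
  expect_equal(fit$var_between, 0, tolerance = 1e-8)
  expect_equal(fit$icc, 0, tolerance = 1e-6)
  ols <- lm(y ~ x, data = tab)
  expect_equal(fit$coefficients$estimate, unname(coef(ols)),
               tolerance = 1e-6)
})

test_that("a single-site table falls back to least squares with a warning", {
  tab <- simulate_analysis_table(n = 20, n_sites = 1, beta = 1, seed = 2)
  expect_warning(fit <- fit_mixed_model(tab, "y", "x"), "one site")
  expect_equal(fit$n_sites, 1)
  expect_equal(fit$var_between, 0)
})

test_that("null effects are covered by their confidence intervals", {
  # zero site effect, zero covariate effect: the 95% CI of the covariate
  # coefficient should contain 0 in at least ~90% of replicates
  covered <- vapply(1:100, function(s) {
    tab <- simulate_analysis_table(n = 73, n_sites = 8, beta = 0,
                                   sigma_site = 0.01, sigma_resid = 2,
                                   seed = s)
    cf <- fit_mixed_model(tab, "y", "x")$coefficients
    abs(cf$estimate[2]) <= 1.96 * cf$se[2]
  }, TRUE)
  expect_gte(mean(covered), 0.90)
})

test_that("single-covariate screens drop constants and find real effects", {
  tab <- prepare_outcomes(toy_table(n = 60, n_sites = 6, seed = 8))
  tab$purpose <- "security"   # no variation, like the field questionnaire
  expect_warning(
    res <- unconditional_tests(tab, covariates = c("age_class", "sex_status",
                                                   "purpose",
                                                   "fixes_per_hour")),
    "lack of variation")
  expect_equal(res$excluded, "purpose")
  expect_equal(sort(unique(res$p_values$covariate)),
               c("age_class", "fixes_per_hour", "sex_status"))
  expect_true(all(res$p_values$p >= 0 & res$p_values$p <= 1))
  # descriptives cover every level of the categorical covariates
  expect_equal(sum(res$descriptives$covariate == "age_class"), 3 * 4)
  # a strong planted effect is detected
  strong <- tab
  strong$daily_distance_km <- strong$daily_distance_km +
    10 * strong$fixes_per_hour
  res2 <- unconditional_tests(strong, covariates = "fixes_per_hour")
  p <- res2$p_values$p[res2$p_values$outcome == "daily_distance"]
  expect_lt(p, 0.001)
})

test_that("null p-values are close to uniform", {
  pvals <- vapply(1:150, function(s) {
    tab <- simulate_analysis_table(n = 73, n_sites = 8, beta = 0,
                                   sigma_site = 0.5, sigma_resid = 2,
                                   seed = 1000 + s)
    fit_mixed_model(tab, "y", "x")$coefficients$p[2]
  }, 0)
  expect_gt(suppressWarnings(ks.test(pvals, "punif")$p.value), 0.01)
})

test_that("leave-one-site-out influence reports sign stability", {
  tab <- simulate_analysis_table(n = 73, n_sites = 8, beta = 3,
                                 sigma_site = 1, sigma_resid = 1, seed = 9)
  infl <- site_influence(tab, "y", "x")
  expect_equal(nrow(infl$site_refits), 8 * 2)
  expect_true(infl$sign_stable[["x"]])
  expect_true(all(infl$outlier_rows %in% seq_len(nrow(tab))))
})
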