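# BIC backward elimination, LRT, parametric bootstrap, 1:1 test.

glm_spec <- function(fixed) {
  mixed_model_spec("preference", fixed = fixed, random = character(0))
}

sim_null_data <- function(n = 160, seed = 1) {
  set.seed(seed)
  d <- expand.grid(i = seq_len(n / 8), Td = c("27", "19"), Ta = c("27", "19"),
                   Sex = c("M", "F"))
  d$Td <- factor(d$Td, levels = c("27", "19"))
  d$Ta <- factor(d$Ta, levels = c("27", "19"))
  d$Sex <- factor(d$Sex, levels = c("M", "F"))
  trials <- rpois(nrow(d), 4) + 1L
  d$successes <- rbinom(nrow(d), trials, 0.5)
  d$failures <- trials - d$successes
  d$cohort <- factor(rep(1:8, length.out = nrow(d)))
  d$timepoint <- factor(rep(1:10, length.out = nrow(d)))
  d
}

test_that("BIC elimination strips null covariates and keeps real ones", {
  null_keep <- 0L
  for (r in 1:20) {
    d <- sim_null_data(n = 240, seed = 400 + r)
    sel <- backward_select_bic(d, glm_spec(c("Td", "Ta", "Sex", "Ta:Sex")))
    if (length(sel$spec$fixed) == 0) null_keep <- null_keep + 1L
    expect_true(all(diff(sel$trace$bic) < 0)) # strictly decreasing trace
  }
  expect_gte(null_keep / 20, 0.9)

  # strong Ta:Sex interaction is retained
  keep <- 0L
  for (r in 1:20) {
    d <- sim_null_data(n = 240, seed = 500 + r)
    trials <- d$successes + d$failures
    eta <- 0 + 1.2 * (d$Ta == "19") * (d$Sex == "F")
    d$successes <- rbinom(nrow(d), trials, plogis(eta))
    d$failures <- trials - d$successes
    sel <- backward_select_bic(d, glm_spec(c("Td", "Ta", "Sex", "Ta:Sex")))
    if (all(c("Ta", "Sex", "Ta:Sex") %in% sel$spec$fixed)) keep <- keep + 1L
  }
  expect_gte(keep / 20, 0.9)
})

test_that("elimination respects marginality and stops at a BIC minimum", {
  d <- sim_null_data(n = 240, seed = 77)
  trials <- d$successes + d$failures
  d$successes <- rbinom(nrow(d), trials, plogis(1.0 * (d$Td == "19")))
  d$failures <- trials - d$successes
  sel <- backward_select_bic(d, glm_spec("Td"))
  expect_equal(sel$spec$fixed, "Td") # removal would raise BIC: unchanged
  expect_equal(nrow(sel$trace), 1L)
  # interactions leave before their main effects along any trace
  sel2 <- backward_select_bic(d, glm_spec(c("Td", "Ta", "Sex", "Ta:Sex")))
  removed <- sel2$trace$removed[-1]
  if ("Ta:Sex" %in% removed) {
    expect_lt(match("Ta:Sex", removed),
              min(match(c("Ta", "Sex"), removed), Inf))
  }
})

test_that("LRT follows the chi-squared tail and nesting rules", {
  d <- sim_null_data(n = 160, seed = 9)
  f_full <- fit_glmm(d, glm_spec(c("Td", "Ta")))
  f_red <- fit_glmm(d, glm_spec("Td"))
  tst <- lrt(f_full, f_red)
  expect_equal(tst$statistic, 2 * (f_full$logLik - f_red$logLik))
  expect_equal(tst$df, 1L)
  expect_equal(tst$p_lrt, pchisq(tst$statistic, 1, lower.tail = FALSE))
  # identical specs: statistic 0, p 1
  same <- lrt(f_full, f_full)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_lrt, 1)
  # non-nested comparison is an error
  f_other <- fit_glmm(d, glm_spec("Sex"))
  expect_error(lrt(f_full, f_other), "not nested")
})

test_that("the chi-squared upper tail at 20.66 on 1 df is below 0.001", {
  expect_lt(pchisq(20.66, df = 1, lower.tail = FALSE), 0.001)
})

test_that("bootstrap p follows the add-one formula and the seed", {
  d <- sim_null_data(n = 120, seed = 10)
  f_full <- fit_glmm(d, glm_spec("Td"))
  f_red <- fit_glmm(d, glm_spec(character(0)))
  b1 <- parametric_bootstrap_p(f_full, f_red, nsim = 49, seed = 7)
  b2 <- parametric_bootstrap_p(f_full, f_red, nsim = 49, seed = 7)
  expect_equal(b1$p_bootstrap, b2$p_bootstrap) # seed-deterministic
  expect_gte(b1$p_bootstrap, 1 / 50)
  expect_lte(b1$p_bootstrap, 1)
  # observed statistic 0 (identical models) -> p = 1 exactly
  b0 <- parametric_bootstrap_p(f_full, f_full, nsim = 19, seed = 3)
  expect_equal(b0$p_bootstrap, 1)
  # a huge observed statistic no simulation reaches -> p = 1/(nsim+1)
  f_fake <- f_full
  f_fake$logLik <- f_red$logLik + 500
  b3 <- parametric_bootstrap_p(f_fake, f_red, nsim = 19, seed = 3)
  expect_equal(b3$p_bootstrap, 1 / 20)
})

test_that("bootstrap simulates from mixed null models too", {
  p <- cohort_sim_params(n_cohorts_per_cell = 3L, seed = 19L)
  obs <- generate_cohort_series(p)
  pref <- suppressMessages(build_preference_response(obs))
  f_full <- fit_glmm(pref, mixed_model_spec("preference", "Td",
                                            random = "cohort"))
  f_red <- fit_glmm(pref, mixed_model_spec("preference", character(0),
                                           random = "cohort"))
  b <- parametric_bootstrap_p(f_full, f_red, nsim = 9, seed = 11)
  expect_true(b$p_bootstrap >= 0.1 && b$p_bootstrap <= 1)
  expect_equal(b$n_failed, 0L)
})

test_that("test_vs_even is the exact two-sided binomial test", {
  expect_equal(test_vs_even(5, 5), 1)
  expect_equal(test_vs_even(10, 0), 2 * 0.5^10, tolerance = 1e-12)
  expect_equal(test_vs_even(0, 10), 2 * 0.5^10, tolerance = 1e-12)
  expect_error(test_vs_even(0, 0), "one trial")
  expect_error(test_vs_even(-1, 3), "counts")
})
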