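# Mixed-model fitting: GLM degeneracy, recovery, degenerate inputs.

test_that("spec validation enforces marginality and known terms", {
  expect_error(mixed_model_spec(fixed = c("Td", "Ta:Sex")), "marginality")
  expect_error(mixed_model_spec(fixed = "Weight"), "unknown")
  sp <- mixed_model_spec("preference", c("Td", "Ta", "Sex", "Ta:Sex"))
  expect_equal(sp$family, "binomial")
  f <- spec_formula(sp)
  expect_true(grepl("cbind\\(successes, failures\\)", deparse(f)[1]))
})

test_that("GLMM with no random terms matches a hand-rolled IRLS fit", {
  d <- make_glm_response(n = 150, beta = c(0.2, 0.7), seed = 21)
  sp <- mixed_model_spec("preference", fixed = c("Td", "Sex"),
                         random = character(0))
  fit <- fit_glmm(d, sp)
  X <- model.matrix(~ Td + Sex, d)
  oracle <- irls_binomial(X, d$successes, d$failures)
  expect_equal(unname(coef(fit)), oracle, tolerance = 1e-6)
  # BIC bookkeeping: -2 logLik + k log(n)
  expect_equal(fit$BIC, -2 * fit$logLik + fit$k * log(nrow(d)))
  expect_equal(fit$k, 3L)
})

test_that("GLMM recovers an injected cohort variance and fixed effect", {
  p <- cohort_sim_params(
    n_cohorts_per_cell = 38L, # ~300 cohorts in total
    fixed_effects_logit = list(preference = c(intercept = 0, Td19 = 0.8),
                               activity = numeric(0)),
    sigma_cohort = 0.8, sigma_timepoint = 0, seed = 14L
  )
  obs <- generate_cohort_series(p)
  pref <- suppressMessages(build_preference_response(obs))
  fit <- fit_glmm(pref, mixed_model_spec("preference", fixed = "Td",
                                         random = "cohort"), nAGQ = 0L)
  expect_equal(unname(fit$ranef_sd[["cohort"]]), 0.8, tolerance = 0.15)
  expect_equal(unname(coef(fit)[["Td19"]]), 0.8, tolerance = 0.2)
  expect_true(fit$converged)
})

test_that("complete separation is flagged as divergent", {
  d <- data.frame(
    successes = c(rep(5, 6), rep(0, 6)),
    failures = c(rep(0, 6), rep(5, 6)),
    Td = factor(rep(c("19", "27"), each = 6), levels = c("27", "19")),
    cohort = factor(rep(1:4, 3)), timepoint = factor(rep(1:3, 4))
  )
  sp <- mixed_model_spec("preference", fixed = "Td", random = character(0))
  fit <- fit_glmm(d, sp)
  expect_true(fit$divergent)
  expect_false(fit$converged)
})

test_that("rank-deficient designs are rejected with the aliased term named", {
  d <- make_glm_response(n = 60, seed = 2)
  d$Ta <- d$Td # aliased
  sp <- mixed_model_spec("preference", fixed = c("Td", "Ta"),
                         random = character(0))
  expect_error(fit_glmm(d, sp), "rank deficient")
})

test_that("LMM without random term reproduces classical one-way ANOVA F", {
  set.seed(31)
  d <- data.frame(
    score = c(rnorm(12, 0.05, 0.01), rnorm(12, 0.08, 0.01)),
    Td = factor(rep(c("27", "19"), each = 12), levels = c("27", "19"))
  )
  fit <- fit_lmm(d, mixed_model_spec("score", fixed = "Td",
                                     random = character(0),
                                     family = "gaussian"))
  ft <- f_tests(fit)
  # oracle: closed-form one-way ANOVA from group summaries; the ML fit has
  # residual df n - p, matching the classical denominator here
  expect_equal(ft$F, oneway_anova_F(d$score, d$Td), tolerance = 1e-10)
  expect_equal(ft$df1, 1L)
  expect_equal(ft$df2, 22L)
})

test_that("constant responses yield flagged, not bogus, F statistics", {
  d <- data.frame(score = rep(0.5, 20),
                  Td = factor(rep(c("27", "19"), 10), levels = c("27", "19")))
  fit <- suppressWarnings(
    fit_lmm(d, mixed_model_spec("score", fixed = "Td",
                                random = character(0),
                                family = "gaussian"))
  )
  ft <- f_tests(fit)
  expect_true(is.na(ft$F) || ft$F < 1e-10)
})

test_that("a small injected Td shift in scores is reliably detected", {
  # power check, scaled: Td shift 0.05, sd 0.01, 16 wings per cell
  hits <- 0L
  for (r in 1:25) {
    set.seed(100 + r)
    d <- expand.grid(rep_i = 1:16, Td = c("27", "19"), Ta = c("27", "19"),
                     Sex = c("M", "F"))
    d$Td <- factor(d$Td, levels = c("27", "19"))
    d$score <- 0.1 + 0.05 * (d$Td == "19") + rnorm(nrow(d), 0, 0.01)
    fit <- fit_lmm(d, mixed_model_spec("score", fixed = c("Td"),
                                       random = character(0),
                                       family = "gaussian"))
    ft <- f_tests(fit)
    if (ft$p[ft$term == "Td"] < 0.001) hits <- hits + 1L
  }
  expect_gte(hits / 25, 0.95)
})

test_that("random factors need at least two levels", {
  d <- make_glm_response(n = 40, seed = 5)
  d$cohort <- factor("only")
  sp <- mixed_model_spec("preference", fixed = "Td", random = "cohort")
  expect_error(fit_glmm(d, sp), "2 levels")
})
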