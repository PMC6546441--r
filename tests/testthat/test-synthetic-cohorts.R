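# Synthetic cohort series: null symmetry, injected effects, conservation.

null_params <- function(..., seed = 5L) {
  cohort_sim_params(
    fixed_effects_logit = list(preference = c(intercept = 0),
                               activity = numeric(0)),
    sigma_cohort = 0, sigma_timepoint = 0, seed = seed, ...
  )
}

test_that("with no effects arrivals split evenly between brown and green", {
  # enough cohorts that pooled arrivals exceed 10,000
  p <- null_params(n_cohorts_per_cell = 16L)
  obs <- generate_cohort_series(p)
  later <- obs[obs$timepoint > 1, ]
  nb <- sum(later$arrivals_brown); ng <- sum(later$arrivals_green)
  expect_gt(nb + ng, 10000)
  expect_equal(nb / (nb + ng), 0.5, tolerance = 0.02)
})

test_that("a +1 logit preference intercept gives arrival proportion 0.731", {
  p <- cohort_sim_params(
    fixed_effects_logit = list(preference = c(intercept = 1),
                               activity = numeric(0)),
    sigma_cohort = 0, sigma_timepoint = 0,
    n_cohorts_per_cell = 16L, seed = 6L
  )
  obs <- generate_cohort_series(p)
  later <- obs[obs$timepoint > 1, ]
  prop <- sum(later$arrivals_brown) /
    sum(later$arrivals_brown + later$arrivals_green)
  expect_equal(prop, plogis(1), tolerance = 0.02) # 0.7311 analytically
})

test_that("cohort-level variance responds to sigma_cohort", {
  emp_logit_var <- function(sigma, seed) {
    p <- cohort_sim_params(
      fixed_effects_logit = list(preference = c(intercept = 0),
                                 activity = numeric(0)),
      sigma_cohort = sigma, sigma_timepoint = 0,
      n_cohorts_per_cell = 63L, seed = seed
    )
    obs <- generate_cohort_series(p)
    later <- obs[obs$timepoint > 1, ]
    agg <- aggregate(cbind(arrivals_brown, arrivals_green) ~ cohort_id,
                     later, sum)
    el <- qlogis((agg$arrivals_brown + 0.5) /
                   (agg$arrivals_brown + agg$arrivals_green + 1))
    var(el)
  }
  # paired comparison: same seed, only sigma differs (~500 cohorts)
  expect_gt(emp_logit_var(1.0, seed = 9L), emp_logit_var(0, seed = 9L))
})

test_that("occupancy and movement bookkeeping is conserved", {
  p <- cohort_sim_params(seed = 12L)
  obs <- generate_cohort_series(p)
  K <- p$cohort_size
  expect_true(all(obs$on_brown + obs$on_green == K))
  later <- obs[obs$timepoint > 1, ]
  expect_true(all(later$stationary + later$relocated == K))
  expect_true(all(later$arrivals_brown + later$arrivals_green ==
                    later$relocated))
  expect_true(all(obs[obs$timepoint == 1,
                      c("arrivals_brown", "relocated")] |> is.na()))
  # occupancy change bounded by movement: |delta on_brown| <= relocated,
  # and no photo counts more individuals than the cohort holds
  for (cid in unique(obs$cohort_id)[1:5]) {
    c1 <- obs[obs$cohort_id == cid, ]
    expect_true(all(abs(diff(c1$on_brown)) <= c1$relocated[-1]))
    expect_true(all(c1$on_brown >= 0 & c1$on_brown <= K))
  }
})

test_that("the series is reproducible under its seed", {
  p <- cohort_sim_params(seed = 33L)
  expect_identical(generate_cohort_series(p), generate_cohort_series(p))
  p2 <- cohort_sim_params(seed = 34L)
  expect_false(identical(generate_cohort_series(p), generate_cohort_series(p2)))
})

test_that("parameter validation catches bad inputs", {
  expect_error(cohort_sim_params(sigma_cohort = -1), "sds")
  expect_error(cohort_sim_params(n_timepoints = 1L), "n_timepoints")
  expect_error(cohort_sim_params(
    fixed_effects_logit = list(preference = c(bogus = 1))), "unknown")
  expect_error(cohort_sim_params(mean_relocations_per_photo = 25),
               "mean_relocations")
})

test_that("calibration standards follow the stated gamma law", {
  std <- generate_calibration_standards(true_gamma = 1, n_levels = 6,
                                        noise_sd = 0)
  expect_equal(std$raw, std$reflectance)
  std22 <- generate_calibration_standards(true_gamma = 2.2, n_levels = 11,
                                          noise_sd = 0)
  half <- std22[std22$channel == "R" & std22$reflectance == 0.5, ]
  expect_equal(half$raw, 0.5^(1 / 2.2), tolerance = 1e-12) # ~0.7297
  ends <- std22[std22$reflectance %in% c(0, 1), ]
  expect_equal(ends$raw, ends$reflectance)
  expect_identical(generate_calibration_standards(2.2, 8, 0.01, seed = 2),
                   generate_calibration_standards(2.2, 8, 0.01, seed = 2))
  expect_error(generate_calibration_standards(true_gamma = -1), "true_gamma")
  expect_error(generate_calibration_standards(n_levels = 2), "levels")
})
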