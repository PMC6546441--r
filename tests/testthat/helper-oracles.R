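# Independent oracles and small fixtures used across the suite.

# Binomial-logit regression by hand-written IRLS: the independent check for
# the no-random-term GLMM path.  Deliberately does not call glm().
irls_binomial <- function(X, successes, failures, tol = 1e-12,
                          maxit = 100L) {
  n <- successes + failures
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- as.numeric(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- n * mu * (1 - mu)
    z <- eta + (successes - n * mu) / pmax(W, 1e-12)
    XtW <- t(X * W)
    beta_new <- solve(XtW %*% X, XtW %*% z)
    if (max(abs(beta_new - beta)) < tol) {
      return(as.numeric(beta_new))
    }
    beta <- as.numeric(beta_new)
  }
  as.numeric(beta)
}

# Classical one-way ANOVA F from group summaries (closed form).
oneway_anova_F <- function(y, g) {
  g <- as.factor(g)
  k <- nlevels(g)
  n <- length(y)
  gm <- tapply(y, g, mean)
  ng <- tapply(y, g, length)
  ssb <- sum(ng * (gm - mean(y))^2)
  ssw <- sum((y - gm[g])^2)
  (ssb / (k - 1)) / (ssw / (n - k))
}

# Small noise-free wing pair (one per Td level) reused by several tests.
make_test_wings <- function(noise_sd = 0, seed = 42L) {
  p <- wing_sim_params(pixel_noise_sd = noise_sd, seed = seed)
  list(
    params = p,
    td19 = generate_wing_image(p, 19, "F"),
    td27 = generate_wing_image(p, 27, "F")
  )
}

# Minimal two-vector response table with independent rows (no clustering),
# for GLM-level checks.
make_glm_response <- function(n = 120L, beta = c(0.3, 0.8), seed = 1L) {
  set.seed(seed)
  Td <- factor(sample(c("27", "19"), n, TRUE), levels = c("27", "19"))
  eta <- beta[1] + beta[2] * (Td == "19")
  trials <- rpois(n, 5) + 1L
  successes <- rbinom(n, trials, plogis(eta))
  data.frame(
    successes = successes, failures = trials - successes, Td = Td,
    Ta = factor(sample(c("27", "19"), n, TRUE), levels = c("27", "19")),
    Sex = factor(sample(c("M", "F"), n, TRUE), levels = c("M", "F")),
    cohort = factor(rep(1:10, length.out = n)),
    timepoint = factor(rep(1:12, length.out = n))
  )
}
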