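# Likelihood-ratio tests, parametric bootstrap, and the 1:1 preference test.

#' Likelihood-ratio test between nested model fits
#'
#' `statistic = 2 * (logLik_full - logLik_reduced)`, df the difference in
#' free parameter counts, p from the chi-squared upper tail.  The reduced
#' spec must be nested in the full one (fixed and random terms subsets) and
#' fitted to the same rows.
#'
#' @param fit_full,fit_reduced `crypsis_fit` objects.
#' @return object of class `crypsis_test`: `statistic`, `df`, `p_lrt`.
#' @export
lrt <- function(fit_full, fit_reduced) {
  .check_nested(fit_full, fit_reduced)
  stat <- 2 * (fit_full$logLik - fit_reduced$logLik)
  # tiny negative values are optimizer noise on truly nested fits
  if (stat < 0 && stat > -1e-6) stat <- 0
  if (stat < 0) {
    warning("full model has lower likelihood than reduced model; ",
            "check convergence", call. = FALSE)
    stat <- 0
  }
  df <- fit_full$k - fit_reduced$k
  p <- if (df == 0L || stat == 0) 1 else
    stats::pchisq(stat, df, lower.tail = FALSE)
  structure(list(statistic = stat, df = df, p_lrt = p,
                 p_bootstrap = NULL, nsim = NULL, n_failed = NULL),
            class = "crypsis_test")
}

.check_nested <- function(full, reduced) {
  if (!all(reduced$spec$fixed %in% full$spec$fixed) ||
      !all(reduced$spec$random %in% full$spec$random) ||
      reduced$spec$family != full$spec$family) {
    stop_wc("models are not nested")
  }
  if (full$n_obs != reduced$n_obs) {
    stop_wc("models were fitted to different numbers of rows")
  }
  invisible(TRUE)
}

#' @export
print.crypsis_test <- function(x, ...) {
  cat(sprintf("LRT: chisq = %.3f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_lrt))
  if (!is.null(x$p_bootstrap)) {
    cat(sprintf("Parametric bootstrap (nsim = %d%s): p = %.4g\n",
                x$nsim,
                if (x$n_failed > 0) paste0(", ", x$n_failed, " refits failed")
                else "", x$p_bootstrap))
  }
  invisible(x)
}

# refit a crypsis_fit to a new response (vector for gaussian, 2-col matrix
# for binomial); returns the refitted logLik or an error
.refit_loglik <- function(fit, newresp) {
  if (inherits(fit$fit, "merMod")) {
    as.numeric(stats::logLik(lme4::refit(fit$fit, newresp = newresp)))
  } else {
    d <- fit$data
    if (fit$spec$family == "binomial") {
      d$successes <- newresp[, 1]
      d$failures <- newresp[, 2]
      m <- suppressWarnings(
        stats::glm(spec_formula(fit$spec), data = d,
                   family = stats::binomial())
      )
    } else {
      d[[fit$spec$response]] <- newresp
      m <- stats::lm(spec_formula(fit$spec), data = d)
    }
    as.numeric(stats::logLik(m))
  }
}

#' Parametric-bootstrap p-value for a nested model comparison
#'
#' Simulates `nsim` response tables from the fitted reduced (null) model —
#' for mixed models including fresh random-effect draws — refits both
#' models on each, and compares the simulated LRT statistics with the
#' observed one: `p = (1 + #\{sim >= observed\}) / (nsim_ok + 1)`.  Refits
#' that fail are dropped and counted; more than 10% failures is an error.
#' Reproducible under `seed`.
#'
#' @inheritParams lrt
#' @param nsim number of bootstrap simulations (>= 1; 999 in routine use).
#' @param seed integer seed for the bootstrap sub-stream.
#' @return `crypsis_test` with `p_bootstrap`, `nsim`, `n_failed` filled in.
#' @export
parametric_bootstrap_p <- function(fit_full, fit_reduced, nsim = 999L,
                                   seed = 1L) {
  if (nsim < 1L) stop_wc("nsim must be >= 1")
  obs <- lrt(fit_full, fit_reduced)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, "bootstrap"))
  sims <- stats::simulate(fit_reduced$fit, nsim = nsim)
  stat_sim <- rep(NA_real_, nsim)
  for (i in seq_len(nsim)) {
    newresp <- sims[[i]]
    s <- tryCatch({
      ll_r <- .refit_loglik(fit_reduced, newresp)
      ll_f <- .refit_loglik(fit_full, newresp)
      max(0, 2 * (ll_f - ll_r))
    }, error = function(e) NA_real_)
    stat_sim[i] <- s
  }
  n_failed <- sum(is.na(stat_sim))
  if (n_failed > 0.10 * nsim) {
    stop_wc(n_failed, " of ", nsim, " bootstrap refits failed (> 10%)")
  }
  ok <- stat_sim[!is.na(stat_sim)]
  obs$p_bootstrap <- (1 + sum(ok >= obs$statistic - 1e-12)) / (length(ok) + 1)
  obs$nsim <- as.integer(nsim)
  obs$n_failed <- as.integer(n_failed)
  obs
}

#' Exact binomial test against a 1:1 ratio
#'
#' Two-sided exact binomial test of proportion 0.5 on aggregated
#' (successes, failures) counts — e.g. total relocations to brown vs green
#' within a treatment cell.
#'
#' @param successes,failures non-negative counts, summing to >= 1.
#' @return the two-sided p-value.
#' @export
test_vs_even <- function(successes, failures) {
  if (!is_count(successes) || !is_count(failures)) {
    stop_wc("successes and failures must be non-negative counts")
  }
  n <- successes + failures
  if (n < 1) stop_wc("need at least one trial")
  stats::binom.test(successes, n, p = 0.5)$p.value
}
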