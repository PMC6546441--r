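# Mixed-model fitting: binomial GLMMs (logit link) and Gaussian LMMs with
# crossed random intercepts for cohort and time point.  Estimation is ML
# throughout (Laplace approximation for the binomial integrals, via lme4)
# so that likelihood-ratio tests and BIC comparisons across fixed-effect
# structures are valid.  With no random terms the fit degenerates to an
# ordinary GLM/LM.

.FIXED_MAIN <- c("Td", "Ta", "Sex")
.FIXED_INT <- c("Td:Ta", "Td:Sex", "Ta:Sex")

#' Specify a mixed model over the treatment factors
#'
#' @param response `"preference"`, `"activity"` (binomial-logit on
#'   `cbind(successes, failures)`) or the name of a numeric score column
#'   (Gaussian).
#' @param fixed character vector of fixed terms from
#'   `Td, Ta, Sex, Td:Ta, Td:Sex, Ta:Sex` (marginality enforced: an
#'   interaction requires both its main effects).  Empty = intercept only.
#' @param random character subset of `c("cohort", "timepoint")` (crossed
#'   random intercepts).
#' @param family `"binomial"` or `"gaussian"`; defaults by response.
#' @return object of class `mixed_model_spec`.
#' @export
mixed_model_spec <- function(response = "preference",
                             fixed = c("Td", "Ta", "Sex",
                                       "Td:Ta", "Td:Sex", "Ta:Sex"),
                             random = c("cohort", "timepoint"),
                             family = NULL) {
  fixed <- unique(fixed)
  bad <- setdiff(fixed, c(.FIXED_MAIN, .FIXED_INT))
  if (length(bad)) stop_wc("unknown fixed terms: ", paste(bad, collapse = ", "))
  for (tm in intersect(fixed, .FIXED_INT)) {
    mains <- strsplit(tm, ":")[[1]]
    if (!all(mains %in% fixed)) {
      stop_wc("marginality violated: '", tm, "' requires main effects ",
              paste(mains, collapse = " and "))
    }
  }
  random <- unique(random)
  bad <- setdiff(random, c("cohort", "timepoint"))
  if (length(bad)) stop_wc("unknown random terms: ", paste(bad, collapse = ", "))
  if (is.null(family)) {
    family <- if (response %in% c("preference", "activity")) "binomial"
    else "gaussian"
  }
  family <- match.arg(family, c("binomial", "gaussian"))
  structure(list(response = response, fixed = fixed, random = random,
                 family = family),
            class = "mixed_model_spec")
}

#' @export
print.mixed_model_spec <- function(x, ...) {
  cat("Mixed model spec [", x$family, "]: ", deparse(spec_formula(x)), "\n",
      sep = "")
  invisible(x)
}

#' Model formula implied by a spec
#' @param spec a `mixed_model_spec`.
#' @return a formula.
#' @export
spec_formula <- function(spec) {
  lhs <- if (spec$family == "binomial") "cbind(successes, failures)"
  else spec$response
  rhs <- if (length(spec$fixed)) paste(spec$fixed, collapse = " + ") else "1"
  if (length(spec$random)) {
    rhs <- paste(rhs, paste(sprintf("(1 | %s)", spec$random), collapse = " + "),
                 sep = " + ")
  }
  stats::as.formula(paste(lhs, "~", rhs))
}

# number of free parameters: fixed coefficients + RE variances (+ residual
# variance for gaussian)
.n_params <- function(fit, spec) {
  p <- length(fit$coefficients)
  p + length(spec$random) + (spec$family == "gaussian")
}

.collect_warnings <- function(expr) {
  msgs <- character(0)
  val <- withCallingHandlers(
    expr,
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    }
  )
  list(value = val, messages = msgs)
}

.make_crypsis_fit <- function(model, spec, data, messages, nAGQ = NA_integer_) {
  is_mer <- inherits(model, "merMod")
  beta <- if (is_mer) lme4::fixef(model) else stats::coef(model)
  V <- as.matrix(stats::vcov(model))
  ll <- as.numeric(stats::logLik(model))
  n_obs <- nrow(data)
  ranef_sd <- if (is_mer) {
    vc <- lme4::VarCorr(model)
    stats::setNames(vapply(vc, function(v) sqrt(v[1, 1]), numeric(1)),
                    names(vc))
  } else stats::setNames(numeric(0), character(0))
  fit <- list(coefficients = beta, se = sqrt(diag(V)), vcov = V,
              ranef_sd = ranef_sd, logLik = ll, spec = spec, data = data,
              fit = model, n_obs = n_obs, messages = messages,
              nAGQ = nAGQ)
  fit$k <- .n_params(fit, spec)
  fit$BIC <- -2 * ll + fit$k * log(n_obs)
  fit$boundary <- is_mer && any(ranef_sd < 1e-6)
  conv_bad <- any(grepl("converge|Hessian|unable to evaluate|degenerate",
                        messages, ignore.case = TRUE))
  sep_bad <- spec$family == "binomial" &&
    (any(abs(beta) > 10) ||
       any(grepl("fitted probabilities numerically 0 or 1", messages)))
  fit$converged <- !conv_bad && !sep_bad
  fit$divergent <- sep_bad
  class(fit) <- "crypsis_fit"
  fit
}

#' Fit a binomial-logit mixed model
#'
#' Maximum-likelihood fit (Laplace approximation) of a binomial GLMM with
#' the spec's fixed terms and crossed random intercepts, via `lme4::glmer`.
#' With no random terms the model is fitted as an ordinary binomial GLM.
#' Non-convergence and boundary (zero) variance estimates are reported in
#' the returned object, never silently; quasi-complete separation is
#' flagged as `divergent`.
#'
#' @param data response table from [build_preference_response()] /
#'   [build_activity_response()] (columns `successes`, `failures` and the
#'   spec's covariates).
#' @param spec a [mixed_model_spec()] with `family = "binomial"`.
#' @param nAGQ integer passed to `lme4::glmer`: 1 (default) is the Laplace
#'   approximation; 0 uses the faster penalized-least-squares step only,
#'   appropriate for very large designs.
#' @return object of class `crypsis_fit`.
#' @export
fit_glmm <- function(data, spec, nAGQ = 1L) {
  if (spec$family != "binomial") stop_wc("fit_glmm needs a binomial spec")
  if (!all(c("successes", "failures") %in% names(data))) {
    stop_wc("data must have successes and failures columns")
  }
  for (rt in spec$random) {
    if (length(unique(data[[rt]])) < 2L) {
      stop_wc("random factor '", rt, "' needs >= 2 levels")
    }
  }
  .check_rank(data, spec)
  f <- spec_formula(spec)
  res <- if (length(spec$random)) {
    .collect_warnings(lme4::glmer(
      f, data = data, family = stats::binomial(), nAGQ = nAGQ,
      control = lme4::glmerControl(optimizer = "bobyqa")
    ))
  } else {
    .collect_warnings(stats::glm(f, data = data, family = stats::binomial()))
  }
  .make_crypsis_fit(res$value, spec, data, res$messages, nAGQ)
}

#' Fit a Gaussian (linear) mixed model for pigmentation scores
#'
#' ML fit (`lme4::lmer` with `REML = FALSE`) of the spec's fixed terms and
#' random intercepts on a numeric score; with no random term this is an
#' ordinary least-squares linear model, so a single-factor spec reproduces
#' classical one-way ANOVA.
#'
#' @param data data.frame containing the score column named by
#'   `spec$response` and the covariates.
#' @param spec a [mixed_model_spec()] with `family = "gaussian"`.
#' @return object of class `crypsis_fit`.
#' @export
fit_lmm <- function(data, spec) {
  if (spec$family != "gaussian") stop_wc("fit_lmm needs a gaussian spec")
  if (!spec$response %in% names(data)) {
    stop_wc("data has no column '", spec$response, "'")
  }
  .check_rank(data, spec)
  f <- spec_formula(spec)
  res <- if (length(spec$random)) {
    .collect_warnings(lme4::lmer(f, data = data, REML = FALSE))
  } else {
    .collect_warnings(stats::lm(f, data = data))
  }
  .make_crypsis_fit(res$value, spec, data, res$messages)
}

# reject rank-deficient fixed designs, naming the aliased columns
.check_rank <- function(data, spec) {
  rhs <- if (length(spec$fixed)) paste(spec$fixed, collapse = "+") else "1"
  X <- stats::model.matrix(stats::as.formula(paste("~", rhs)), data = data)
  qr_ <- qr(X)
  if (qr_$rank < ncol(X)) {
    aliased <- colnames(X)[qr_$pivot[(qr_$rank + 1):ncol(X)]]
    stop_wc("fixed-effect design is rank deficient; aliased terms: ",
            paste(aliased, collapse = ", "))
  }
  invisible(TRUE)
}

#' @export
print.crypsis_fit <- function(x, ...) {
  cat("Mixed-model fit [", x$spec$family, "]: ",
      deparse(spec_formula(x$spec)), "\n", sep = "")
  cat(sprintf("  n = %d, logLik = %.3f, BIC = %.2f (k = %d)\n",
              x$n_obs, x$logLik, x$BIC, x$k))
  tab <- cbind(Estimate = x$coefficients, `Std. Error` = x$se)
  print(round(tab, 4))
  if (length(x$ranef_sd)) {
    cat("  Random-intercept sd:",
        paste(sprintf("%s = %.3f", names(x$ranef_sd), x$ranef_sd),
              collapse = ", "), "\n")
  }
  if (!x$converged) cat("  WARNING: fit did not converge cleanly\n")
  if (x$divergent) cat("  WARNING: separation/divergence suspected\n")
  if (x$boundary) cat("  NOTE: variance estimate at boundary (0)\n")
  invisible(x)
}

#' @export
coef.crypsis_fit <- function(object, ...) object$coefficients

#' @export
vcov.crypsis_fit <- function(object, ...) object$vcov

#' @export
logLik.crypsis_fit <- function(object, ...) {
  structure(object$logLik, df = object$k, nobs = object$n_obs,
            class = "logLik")
}

#' @export
BIC.crypsis_fit <- function(object, ...) object$BIC

#' @export
summary.crypsis_fit <- function(object, ...) {
  z <- object$coefficients / object$se
  tab <- data.frame(
    estimate = object$coefficients, se = object$se, z = z,
    p = 2 * stats::pnorm(-abs(z))
  )
  out <- list(fit = object, coef_table = tab)
  class(out) <- "summary.crypsis_fit"
  out
}

#' @export
print.summary.crypsis_fit <- function(x, ...) {
  print(x$fit)
  cat("\nWald tests:\n")
  print(round(x$coef_table, 5))
  invisible(x)
}

#' Per-term Wald F tests for a fitted model
#'
#' For each fixed term, the Wald F statistic on its coefficient block, with
#' denominator degrees of freedom `n - p` (residual df).  For an ordinary
#' linear model with a single factor this equals the classical one-way
#' ANOVA F exactly; for mixed models it is the Wald approximation (the df
#' method is isolated here so an alternative can be substituted).
#'
#' @param fit a `crypsis_fit`.
#' @return data.frame `term`, `F`, `df1`, `df2`, `p`.
#' @export
f_tests <- function(fit) {
  X <- if (inherits(fit$fit, "merMod")) lme4::getME(fit$fit, "X")
  else stats::model.matrix(fit$fit)
  asgn <- attr(X, "assign")
  labels <- attr(stats::terms(
    stats::as.formula(paste("~", if (length(fit$spec$fixed))
      paste(fit$spec$fixed, collapse = "+") else "1"))), "term.labels")
  df2 <- fit$n_obs - length(fit$coefficients)
  rows <- lapply(seq_along(labels), function(i) {
    idx <- which(asgn == i)
    b <- fit$coefficients[idx]
    Vi <- fit$vcov[idx, idx, drop = FALSE]
    Fstat <- if (all(diag(Vi) < 1e-20)) {
      NA_real_ # degenerate (constant response): no usable error variance
    } else {
      tryCatch(
        as.numeric(t(b) %*% solve(Vi, b)) / length(idx),
        error = function(e) NA_real_
      )
    }
    data.frame(term = labels[i], F = Fstat, df1 = length(idx), df2 = df2,
               p = stats::pf(Fstat, length(idx), df2, lower.tail = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
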