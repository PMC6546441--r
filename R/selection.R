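# Backward model selection on BIC.

#' Backward elimination of fixed-effect terms by BIC
#'
#' Starting from the full spec, repeatedly refits the model with each
#' currently removable fixed term deleted (marginality respected: an
#' interaction must leave before its main effects become removable) and
#' removes the term whose deletion lowers BIC the most; stops when no
#' deletion lowers BIC.  Ties are broken deterministically: the
#' higher-order term first, then alphabetically.  The random structure is
#' kept fixed throughout.
#'
#' @param data model data (see [fit_glmm()] / [fit_lmm()]).
#' @param full the full [mixed_model_spec()] to start from.
#' @param fitter fitting function, [fit_glmm()] or [fit_lmm()]; chosen from
#'   the spec family by default.
#' @param ... passed to the fitter (e.g. `nAGQ`).
#' @return list with `spec` (selected), `fit` (its fit), and `trace`
#'   (data.frame `step`, `removed`, `bic`): `trace$bic` strictly decreases.
#' @export
backward_select_bic <- function(data, full, fitter = NULL, ...) {
  if (is.null(fitter)) {
    fitter <- if (full$family == "binomial") fit_glmm else fit_lmm
  }
  spec <- full
  fit <- fitter(data, spec, ...)
  trace <- data.frame(step = 0L, removed = "<full>", bic = fit$BIC,
                      stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    cand <- .removable_terms(spec$fixed)
    if (!length(cand)) break
    # deterministic candidate order: interactions first, then alphabetical
    ord <- order(-vapply(cand, .term_order, numeric(1)), cand)
    cand <- cand[ord]
    best <- NULL
    for (tm in cand) {
      sp2 <- spec
      sp2$fixed <- setdiff(spec$fixed, tm)
      f2 <- tryCatch(fitter(data, sp2, ...), error = function(e) e)
      if (inherits(f2, "error")) {
        stop_wc("backward elimination aborted at term '", tm, "': ",
                conditionMessage(f2))
      }
      if (f2$BIC < fit$BIC - 1e-9 &&
          (is.null(best) || f2$BIC < best$fit$BIC - 1e-9)) {
        best <- list(term = tm, spec = sp2, fit = f2)
      }
    }
    if (is.null(best)) break
    step <- step + 1L
    spec <- best$spec
    fit <- best$fit
    trace <- rbind(trace, data.frame(step = step, removed = best$term,
                                     bic = fit$BIC))
  }
  list(spec = spec, fit = fit, trace = trace)
}

.term_order <- function(tm) length(strsplit(tm, ":")[[1]])

# terms removable under marginality: every interaction; a main effect only
# if it appears in no retained interaction
.removable_terms <- function(fixed) {
  ints <- fixed[vapply(fixed, .term_order, numeric(1)) > 1]
  mains <- setdiff(fixed, ints)
  in_int <- unique(unlist(strsplit(ints, ":")))
  c(ints, setdiff(mains, in_int))
}
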