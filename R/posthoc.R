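# Tukey-adjusted post hoc contrasts and compact letter display.

#' Post hoc pairwise comparisons with Tukey adjustment
#'
#' Estimated marginal means on the link scale for every combination of the
#' grouping factors (via emmeans), all pairwise differences with
#' familywise adjustment from the multivariate-t (Tukey-style) reference,
#' and a compact letter display at the chosen alpha: groups sharing a
#' letter are not significantly different.
#'
#' @param fit a `crypsis_fit` containing the grouping factors.
#' @param factors character vector of factor names in the model (e.g.
#'   `c("Td", "Ta", "Sex")`).
#' @param alpha familywise significance level for the letter display.
#' @return list of class `crypsis_posthoc`: `emmeans` (data.frame of group
#'   means with a `letters` column), `contrasts` (data.frame of pairwise
#'   comparisons with adjusted p), `alpha`.
#' @export
posthoc_pairwise <- function(fit, factors, alpha = 0.05) {
  miss <- setdiff(factors, unique(unlist(strsplit(fit$spec$fixed, ":"))))
  if (length(miss)) {
    stop_wc("factor(s) not in the fitted model: ", paste(miss, collapse = ", "))
  }
  spec_f <- stats::as.formula(paste("~", paste(factors, collapse = " * ")))
  emm <- emmeans::emmeans(fit$fit, specs = spec_f, data = fit$data)
  means <- as.data.frame(emm)
  pw <- emmeans::contrast(emm, method = "pairwise")
  prs <- as.data.frame(summary(pw, adjust = "tukey"))
  unadj <- as.data.frame(summary(pw, adjust = "none"))
  contrasts <- data.frame(
    contrast = as.character(prs$contrast),
    estimate = prs$estimate, se = prs$SE,
    p_adj = prs$p.value, p_unadj = unadj$p.value
  )
  means$group <- apply(means[, factors, drop = FALSE], 1, paste,
                       collapse = " ")
  est_col <- intersect(c("emmean", "response", "prob"), names(means))[1]
  # pairwise contrasts are emitted in combn order over the grid rows
  pair_idx <- t(utils::combn(nrow(means), 2))
  stopifnot(nrow(pair_idx) == nrow(contrasts))
  means$letters <- compact_letters(
    pair_idx, contrasts$p_adj, n_groups = nrow(means),
    means = means[[est_col]], alpha = alpha
  )
  structure(list(emmeans = means, contrasts = contrasts, alpha = alpha),
            class = "crypsis_posthoc")
}

#' @export
print.crypsis_posthoc <- function(x, ...) {
  cat("Estimated marginal means (link scale), Tukey letters at alpha =",
      x$alpha, "\n")
  print(x$emmeans)
  cat("\nPairwise contrasts (Tukey-adjusted):\n")
  print(x$contrasts)
  invisible(x)
}

#' Compact letter display from pairwise p-values
#'
#' Standard insert-and-absorb algorithm: start from one letter covering all
#' groups; for each significant pair split every letter containing both
#' members; absorb letter sets that are subsets of others; label letters in
#' order of the group means.
#'
#' @param pairs two-column integer matrix: the group indices compared in
#'   each pairwise contrast.
#' @param p_adj adjusted p-value per contrast (parallel to `pairs` rows).
#' @param n_groups number of groups.
#' @param means group means (controls letter ordering only).
#' @param alpha significance threshold.
#' @return character vector of letter strings, one per group.
#' @export
compact_letters <- function(pairs, p_adj, n_groups, means = NULL,
                            alpha = 0.05) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  k <- as.integer(n_groups)
  cols <- list(rep(TRUE, k)) # letter "columns": logical membership vectors
  for (ci in seq_len(nrow(pairs))) {
    if (is.na(p_adj[ci]) || p_adj[ci] >= alpha) next
    a <- pairs[ci, 1]
    b <- pairs[ci, 2]
    new_cols <- list()
    for (col in cols) {
      if (col[a] && col[b]) {
        c1 <- col; c1[a] <- FALSE
        c2 <- col; c2[b] <- FALSE
        new_cols <- c(new_cols, list(c1, c2))
      } else {
        new_cols <- c(new_cols, list(col))
      }
    }
    # absorb: drop any column that is a subset of another
    keep <- rep(TRUE, length(new_cols))
    for (i in seq_along(new_cols)) {
      for (j in seq_along(new_cols)) {
        if (i != j && keep[j] &&
            all(new_cols[[i]] <= new_cols[[j]]) &&
            !identical(new_cols[[i]], new_cols[[j]])) {
          keep[i] <- FALSE
          break
        }
      }
    }
    cols <- new_cols[keep]
    cols <- cols[!duplicated(vapply(cols, paste, character(1),
                                    collapse = ""))]
  }
  # order letters by the smallest-mean group they contain
  if (is.null(means)) means <- seq_len(k)
  first_mean <- vapply(cols, function(col) min(means[col]), numeric(1))
  cols <- cols[order(first_mean)]
  out <- character(k)
  for (i in seq_along(cols)) {
    out[cols[[i]]] <- paste0(out[cols[[i]]], letters[i])
  }
  out
}
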