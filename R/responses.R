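# Two-vector (successes, failures) responses from cohort observations.

#' @noRd
.validate_cohort_obs <- function(obs) {
  req <- c("cohort_id", "sex", "Td", "Ta", "timepoint", "on_brown",
           "on_green", "arrivals_brown", "arrivals_green", "stationary",
           "relocated")
  miss <- setdiff(req, names(obs))
  if (length(miss)) stop_wc("missing columns: ", paste(miss, collapse = ", "))
  later <- obs$timepoint > 1
  cnt <- obs[later, c("on_brown", "on_green", "arrivals_brown",
                      "arrivals_green", "stationary", "relocated")]
  bad <- which(later)[rowSums(cnt < 0, na.rm = TRUE) > 0 |
                        (cnt$arrivals_brown + cnt$arrivals_green >
                           cnt$relocated)]
  if (length(bad)) {
    stop_wc("invalid cohort observations (negative counts or arrivals ",
            "exceeding relocations) in rows: ",
            paste(utils::head(bad, 10), collapse = ", "))
  }
  invisible(obs)
}

.build_response <- function(obs, succ_col, fail_col, role) {
  .validate_cohort_obs(obs)
  d <- obs[obs$timepoint > 1, , drop = FALSE] # photo 1 has no previous photo
  out <- data.frame(
    successes = d[[succ_col]],
    failures = d[[fail_col]],
    Td = factor(d$Td, levels = c(27, 19), labels = c("27", "19")),
    Ta = factor(d$Ta, levels = c(27, 19), labels = c("27", "19")),
    Sex = factor(d$sex, levels = c("M", "F")),
    cohort = factor(d$cohort_id),
    timepoint = factor(d$timepoint)
  )
  zero <- out$successes + out$failures == 0
  n_dropped <- sum(zero)
  if (n_dropped > 0) {
    message("dropping ", n_dropped, " zero-trial ", role, " rows")
    out <- out[!zero, , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "role") <- role
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Build the perching-preference response table
#'
#' One row per cohort x photo (photos 2..T; the first photo has no previous
#' photo so arrivals are undefined there): successes are new arrivals to
#' brown patches, failures new arrivals to green.  Rows with zero trials
#' (no arrivals at all) are dropped with a logged count.  Factors are coded
#' with baselines `Td = 27`, `Ta = 27`, `Sex = M`, so coefficients read as
#' `Td19`, `Ta19`, `SexF` effects.
#'
#' @param obs cohort observation table (schema of
#'   [generate_cohort_series()]).
#' @return data.frame `successes`, `failures`, `Td`, `Ta`, `Sex`, `cohort`,
#'   `timepoint`, with attributes `role` and `n_dropped`.
#' @export
build_preference_response <- function(obs) {
  .build_response(obs, "arrivals_brown", "arrivals_green", "preference")
}

#' Build the activity response table
#'
#' As [build_preference_response()], with successes = relocated individuals
#' and failures = stationary individuals.
#'
#' @inheritParams build_preference_response
#' @return see [build_preference_response()].
#' @export
build_activity_response <- function(obs) {
  .build_response(obs, "relocated", "stationary", "activity")
}
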