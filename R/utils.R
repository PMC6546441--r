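#' @keywords internal
"_PACKAGE"

#' Derive a reproducible sub-stream seed from a master seed
#'
#' One master seed drives the whole pipeline; each stage (wing images,
#' cohort series, calibration standards, bootstrap) draws from its own
#' sub-stream so stages stay independently reproducible.  The derivation
#' is a small deterministic integer hash, kept below 2^31 - 1.
#'
#' @param master integer master seed.
#' @param purpose character tag naming the sub-stream (e.g. "wings").
#' @param index optional integer distinguishing repeated uses of the same
#'   purpose (e.g. individual wings).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, purpose, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(master) %% m
  for (ch in utf8ToInt(paste0(purpose, ":", index))) {
    h <- (h * 131 + ch) %% m
  }
  as.integer(h)
}

clip01 <- function(x) {
  # keeps dim attributes (pmin/pmax with a scalar first would drop them)
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

inv_logit <- function(x) stats::plogis(x)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_wc <- function(..., call. = FALSE) stop(..., call. = call.)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 0 && x == round(x)
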