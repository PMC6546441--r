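# Scanner linearization: gray-standard calibration.
#
# Downstream colorimetry assumes linear-reflectance RGB.  A set of gray
# standards of known reflectance is scanned; per channel a monotone
# polynomial mapping raw scanner value -> linear reflectance is fitted by
# least squares.  Degree 1 is the default (a well-behaved scanner is already
# linear); higher degrees handle gamma-encoded devices.

#' Simulate gray-standard scans for a gamma-type device response
#'
#' The device is modelled as `raw = reflectance^(1/true_gamma) + noise`,
#' clipped to `[0, 1]` — the usual power-law (gamma) encoding.  Reflectance
#' levels are evenly spaced over `[0, 1]`.
#'
#' @param true_gamma device gamma, > 0 (1 = already linear).
#' @param n_levels number of distinct reflectance levels, >= 3.
#' @param noise_sd Gaussian sd added to the raw values.
#' @param seed integer seed.
#' @return data.frame `channel`, `reflectance`, `raw` (all three channels
#'   share the response).
#' @export
generate_calibration_standards <- function(true_gamma = 2.2, n_levels = 11L,
                                           noise_sd = 0, seed = 1L) {
  if (!is.numeric(true_gamma) || true_gamma <= 0) stop_wc("true_gamma must be > 0")
  if (n_levels < 3L) stop_wc("need at least 3 reflectance levels")
  refl <- seq(0, 1, length.out = n_levels)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, "calibration"))
  out <- do.call(rbind, lapply(c("R", "G", "B"), function(ch) {
    raw <- clip01(refl^(1 / true_gamma) + stats::rnorm(n_levels, 0, noise_sd))
    data.frame(channel = ch, reflectance = refl, raw = raw)
  }))
  rownames(out) <- NULL
  out
}

#' Fit a per-channel linearization curve to gray standards
#'
#' Least-squares polynomial (default degree 1) per channel mapping raw
#' scanner values to known linear reflectances.  Fits whose mapping is not
#' non-decreasing on a 256-point grid over `[0, 1]` are rejected, as are
#' degenerate standards (fewer than `degree + 2` distinct levels, or
#' constant raw values).
#'
#' @param standards data.frame with columns `channel` (`R`/`G`/`B`),
#'   `reflectance`, `raw`, all values in `[0, 1]`.
#' @param degree polynomial degree, >= 1.
#' @return object of class `calibration_curve`: per-channel coefficients
#'   (intercept first) plus fit diagnostics (`r_squared`, `max_residual`).
#' @export
fit_calibration <- function(standards, degree = 1L) {
  req <- c("channel", "reflectance", "raw")
  if (!all(req %in% names(standards))) {
    stop_wc("standards must have columns channel, reflectance, raw")
  }
  if (any(standards$reflectance < 0 | standards$reflectance > 1) ||
      any(standards$raw < 0 | standards$raw > 1)) {
    stop_wc("reflectance and raw values must lie in [0, 1]")
  }
  degree <- as.integer(degree)
  if (degree < 1L) stop_wc("degree must be >= 1")
  channels <- c("R", "G", "B")
  coefs <- list(); diag <- list()
  for (ch in channels) {
    d <- standards[standards$channel == ch, ]
    if (length(unique(d$reflectance)) < degree + 2L) {
      stop_wc("channel ", ch, ": need at least degree + 2 distinct ",
              "reflectance levels")
    }
    if (length(unique(d$raw)) < 2L) {
      stop_wc("channel ", ch, ": raw values are constant; cannot fit a ",
              "monotone response")
    }
    fit <- stats::lm(reflectance ~ stats::poly(raw, degree, raw = TRUE),
                     data = d)
    beta <- unname(stats::coef(fit))
    grid <- seq(0, 1, length.out = 256L)
    mapped <- .poly_eval(beta, grid)
    # cumulative dip > 0.5% of full scale = genuinely non-monotone; smaller
    # dips are least-squares wiggle at the ends of the range
    if (max(cummax(mapped) - mapped) > 5e-3) {
      stop_wc("channel ", ch, ": fitted mapping is non-monotone on [0, 1]; ",
              "lower the degree or supply better standards")
    }
    res <- d$reflectance - .poly_eval(beta, d$raw)
    tss <- sum((d$reflectance - mean(d$reflectance))^2)
    coefs[[ch]] <- beta
    diag[[ch]] <- c(
      r_squared = if (tss > 0) 1 - sum(res^2) / tss else NA_real_,
      max_residual = max(abs(res))
    )
  }
  structure(list(coefficients = coefs, degree = degree, diagnostics = diag),
            class = "calibration_curve")
}

.poly_eval <- function(beta, x) {
  out <- numeric(length(x))
  for (k in rev(seq_along(beta))) out <- out * x + beta[k]
  out
}

#' Identity calibration curve (no-op linearization)
#' @return a degree-1 `calibration_curve` with slope 1, intercept 0.
#' @export
identity_calibration <- function() {
  structure(list(
    coefficients = list(R = c(0, 1), G = c(0, 1), B = c(0, 1)),
    degree = 1L,
    diagnostics = list(R = c(r_squared = 1, max_residual = 0),
                       G = c(r_squared = 1, max_residual = 0),
                       B = c(r_squared = 1, max_residual = 0))
  ), class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("Calibration curve (degree", x$degree, "):\n")
  for (ch in names(x$coefficients)) {
    cat(sprintf("  %s: coef = [%s]  R^2 = %.5f  max|res| = %.2e\n", ch,
                paste(signif(x$coefficients[[ch]], 6), collapse = ", "),
                x$diagnostics[[ch]][["r_squared"]],
                x$diagnostics[[ch]][["max_residual"]]))
  }
  invisible(x)
}

#' Apply a calibration curve to an image
#'
#' Maps each channel of an image through its fitted curve and clips to
#' `[0, 1]`.  Integer images are normalized first (8-bit by 255, 16-bit by
#' 65535).
#'
#' @param image rows x cols x 3 numeric array in `[0, 1]`, or an integer
#'   array (raw 8/16-bit values).
#' @param curve a `calibration_curve`.
#' @return linearized image, same dimensions, values in `[0, 1]`.
#' @export
apply_calibration <- function(image, curve) {
  if (!inherits(curve, "calibration_curve")) stop_wc("curve must be a calibration_curve")
  if (length(dim(image)) != 3L) stop_wc("image must be a 3-d array")
  if (dim(image)[3] != length(curve$coefficients)) {
    stop_wc("image has ", dim(image)[3], " channels but curve has ",
            length(curve$coefficients))
  }
  if (is.integer(image) || max(image) > 1) {
    div <- if (max(image) > 255) 65535 else 255
    image <- image / div
  }
  out <- image
  for (ch in seq_along(curve$coefficients)) {
    out[, , ch] <- clip01(.poly_eval(curve$coefficients[[ch]], image[, , ch]))
  }
  out
}

#' Read gray standards from CSV (`channel,reflectance,raw`)
#' @param path CSV file path.
#' @return standards data.frame.
#' @export
read_standards_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("channel", "reflectance", "raw") %in% names(d))) {
    stop_wc("standards CSV needs columns channel,reflectance,raw")
  }
  d
}

#' Serialize a calibration curve to JSON
#' @param curve a `calibration_curve`.
#' @param path output path.
#' @export
write_calibration_json <- function(curve, path) {
  jsonlite::write_json(unclass(curve), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a calibration curve from JSON
#' @param path JSON path written by [write_calibration_json()].
#' @return a `calibration_curve`.
#' @export
read_calibration_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    coefficients = lapply(x$coefficients, as.numeric),
    degree = as.integer(x$degree),
    diagnostics = lapply(x$diagnostics, unlist)
  ), class = "calibration_curve")
}
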