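# Colour conversion and chromaticity distances.
#
# All scores operate in the CIE 1931 (x, y) chromaticity plane: linear RGB is
# taken to sRGB/Rec.709 primaries with D65 white (2 degree observer), mapped
# to XYZ, then normalized to (x, y) with relative luminance Y kept alongside
# but excluded from distances.

# linear sRGB -> XYZ (D65, 2 deg); rows X, Y, Z
.SRGB_TO_XYZ <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041
), nrow = 3, byrow = TRUE)

# D65 white chromaticity: the convention target for degenerate black pixels
.WHITE_XY <- c(x = 0.31271, y = 0.32902)

#' Convert linear RGB to CIE xyY chromaticity
#'
#' Linear RGB (sRGB primaries, D65 white point, 2 degree observer) is mapped
#' to CIE XYZ and normalized to chromaticity coordinates
#' `x = X/(X+Y+Z)`, `y = Y/(X+Y+Z)`; `Y` is the relative luminance.
#' Pure black (`X+Y+Z = 0`) has no defined chromaticity and is mapped, by
#' convention, to the white-point chromaticity with `Y = 0`; such samples are
#' flagged via the `degenerate` column so callers can exclude them from
#' averages.
#'
#' @param rgb numeric vector of length 3, or an n x 3 matrix, of linear RGB
#'   values in `[0, 1]`.
#' @return a data.frame with columns `x`, `y`, `Y`, `degenerate` (one row per
#'   input colour).
#' @examples
#' rgb_to_xyY(c(1, 1, 1)) # D65 white: x ~ 0.3127, y ~ 0.3290, Y ~ 1
#' @export
rgb_to_xyY <- function(rgb) {
  if (is.null(dim(rgb))) rgb <- matrix(rgb, ncol = 3, byrow = FALSE)
  rgb <- as.matrix(rgb)
  if (ncol(rgb) != 3L) stop_wc("rgb must have 3 components (R, G, B)")
  if (anyNA(rgb) || any(rgb < 0) || any(rgb > 1)) {
    stop_wc("RGB components must lie in [0, 1]")
  }
  xyz <- rgb %*% t(.SRGB_TO_XYZ)
  s <- rowSums(xyz)
  degen <- s <= 0
  x <- ifelse(degen, .WHITE_XY[["x"]], xyz[, 1] / ifelse(degen, 1, s))
  y <- ifelse(degen, .WHITE_XY[["y"]], xyz[, 2] / ifelse(degen, 1, s))
  data.frame(x = x, y = y, Y = xyz[, 2], degenerate = degen)
}

#' Euclidean distance in the CIE xy chromaticity plane
#'
#' The distance underlying both the internal-contrast and the crypsis scores:
#' `sqrt((x_a - x_b)^2 + (y_a - y_b)^2)`.  Luminance `Y` is deliberately
#' excluded; the scores live in the chromaticity diagram only.
#'
#' @param a,b chromaticity points: anything with `x` and `y` components
#'   (a named vector, list, or single-row data.frame as from [rgb_to_xyY()]).
#' @return non-negative numeric distance.
#' @export
chromatic_distance <- function(a, b) {
  ax <- as.numeric(a[["x"]]); ay <- as.numeric(a[["y"]])
  bx <- as.numeric(b[["x"]]); by <- as.numeric(b[["y"]])
  if (anyNA(c(ax, ay, bx, by))) stop_wc("chromaticity points need x and y")
  .validate_xy(ax, ay); .validate_xy(bx, by)
  sqrt((ax - bx)^2 + (ay - by)^2)
}

.validate_xy <- function(x, y) {
  if (any(x < 0) || any(y < 0) || any(x + y > 1 + 1e-9)) {
    stop_wc("invalid chromaticity: need x >= 0, y >= 0, x + y <= 1")
  }
  invisible(TRUE)
}

#' Convert HSB (hue-saturation-brightness) to RGB
#'
#' Standard HSB/HSV to RGB conversion.  Used for the behavioural-assay
#' reference patches: brown HSB(25, 0.60, 0.50) -> RGB (0.500, 0.325, 0.200)
#' and green HSB(130, 0.60, 0.50) -> RGB (0.200, 0.500, 0.250).  The result
#' is treated as a linear-scale RGB triple.
#'
#' @param h hue in degrees, `[0, 360)`.
#' @param s saturation as a fraction in `[0, 1]`.
#' @param b brightness (value) as a fraction in `[0, 1]`.
#' @return numeric RGB triple in `[0, 1]`.
#' @export
hsb_to_rgb <- function(h, s, b) {
  if (!is.numeric(h) || h < 0 || h >= 360) stop_wc("hue must be in [0, 360)")
  if (!is.numeric(s) || s < 0 || s > 1) stop_wc("saturation must be in [0, 1]")
  if (!is.numeric(b) || b < 0 || b > 1) stop_wc("brightness must be in [0, 1]")
  C <- b * s
  X <- C * (1 - abs((h / 60) %% 2 - 1))
  m <- b - C
  rgb1 <- switch(1L + (h %/% 60) %% 6,
    c(C, X, 0), c(X, C, 0), c(0, C, X),
    c(0, X, C), c(X, 0, C), c(C, 0, X)
  )
  out <- rgb1 + m
  names(out) <- c("R", "G", "B")
  out
}

#' Reference patch chromaticities used in the behavioural assay
#'
#' @param patch `"brown"` (HSB 25, 60%, 50%) or `"green"` (HSB 130, 60%, 50%),
#'   or a numeric HSB triple `c(h, s, b)` for a custom patch.
#' @return single-row data.frame of chromaticity (as [rgb_to_xyY()]).
#' @export
reference_patch <- function(patch = c("brown", "green")) {
  if (is.numeric(patch) && length(patch) == 3L) {
    rgb <- hsb_to_rgb(patch[1], patch[2], patch[3])
  } else {
    patch <- match.arg(patch)
    rgb <- switch(patch,
      brown = hsb_to_rgb(25, 0.60, 0.50),
      green = hsb_to_rgb(130, 0.60, 0.50)
    )
  }
  rgb_to_xyY(rgb)
}
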