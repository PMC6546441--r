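# Synthetic wing images with known ground truth.
#
# The geometry is deliberately stylized: a flat brown background field, a
# pale transverse band, and a concentric eyespot (outer ring / dark disc /
# pale focus).  The downstream pipeline only ever reads colours along a
# landmark transect, so morphological realism beyond landmark and boundary
# placement would buy nothing.  What matters is that element colours, sizes
# and landmark positions are known exactly, and that the developmental
# temperature (Td) covariate shifts them the way the seasonal forms do:
# Td = 19 wings are browner (element colours closer to the wing background
# and to the brown assay patch) with smaller pattern elements; Td = 27 wings
# have larger, more contrasting elements.

#' Parameters for the synthetic wing-image generator
#'
#' Defaults encode the two seasonal forms keyed by developmental temperature:
#' at `Td = 19` (dry-season-like) the eyespot rings and band sit close to the
#' wing background colour and the element radii are small; at `Td = 27`
#' (wet-season-like) they are larger and more contrasting.  Colours are
#' linear RGB in `[0, 1]`.
#'
#' @param image_size_px integer `c(rows, cols)` of the generated image.
#' @param colors named list with one entry per Td level (`"19"`, `"27"`),
#'   each a named list of RGB triples: `background`, `band`, `outer_ring`,
#'   `dark_disc`, `focus`.
#' @param radii_px named list per Td level of `c(focus, disc, ring)` pixel
#'   radii, strictly increasing, Td 19 strictly smaller than Td 27.
#' @param band_cols integer `c(first, last)` 0-based column span of the band.
#' @param center 0-based `c(row, col)` of the eyespot centre.
#' @param pixel_noise_sd per-channel Gaussian noise sd in linear RGB.
#' @param seed integer master seed for the image sub-streams.
#' @return object of class `wing_sim_params`.
#' @export
wing_sim_params <- function(image_size_px = c(120L, 180L),
                            colors = NULL,
                            radii_px = list(
                              "19" = c(focus = 3, disc = 7, ring = 11),
                              "27" = c(focus = 5, disc = 11, ring = 17)
                            ),
                            band_cols = c(40L, 52L),
                            center = c(60L, 120L),
                            pixel_noise_sd = 0.01,
                            seed = 1L) {
  if (is.null(colors)) {
    colors <- list(
      "19" = list(
        background = c(0.42, 0.295, 0.185),
        band       = c(0.55, 0.44, 0.30),
        outer_ring = c(0.50, 0.36, 0.22),
        dark_disc  = c(0.20, 0.135, 0.085),
        focus      = c(0.55, 0.43, 0.30)
      ),
      "27" = list(
        background = c(0.36, 0.235, 0.135),
        band       = c(0.72, 0.62, 0.45),
        outer_ring = c(0.76, 0.60, 0.22),
        dark_disc  = c(0.07, 0.05, 0.04),
        focus      = c(0.88, 0.84, 0.80)
      )
    )
  }
  p <- structure(list(
    image_size_px = as.integer(image_size_px), colors = colors,
    radii_px = radii_px, band_cols = as.integer(band_cols),
    center = as.integer(center), pixel_noise_sd = pixel_noise_sd,
    seed = as.integer(seed)
  ), class = "wing_sim_params")
  validate_wing_sim_params(p)
  p
}

#' @noRd
validate_wing_sim_params <- function(p) {
  stopifnot(length(p$image_size_px) == 2L, all(p$image_size_px > 0))
  for (lev in c("19", "27")) {
    cl <- p$colors[[lev]]
    if (is.null(cl)) stop_wc("colors must cover Td levels 19 and 27")
    for (el in c("background", "band", "outer_ring", "dark_disc", "focus")) {
      rgb <- cl[[el]]
      if (is.null(rgb) || length(rgb) != 3L || any(rgb < 0) || any(rgb > 1)) {
        stop_wc("colour '", el, "' at Td ", lev, " must be an RGB triple in [0,1]")
      }
      xy <- rgb_to_xyY(rgb)
      .validate_xy(xy$x, xy$y)
    }
    r <- p$radii_px[[lev]]
    if (is.null(r) || length(r) != 3L || any(r <= 0)) {
      stop_wc("radii at Td ", lev, " must be three positive values")
    }
    if (!(r[1] < r[2] && r[2] < r[3])) {
      stop_wc("radii must be ordered focus < disc < ring at Td ", lev)
    }
  }
  if (!all(p$radii_px[["19"]] < p$radii_px[["27"]])) {
    stop_wc("Td 19 radii must be strictly smaller than Td 27 radii")
  }
  if (p$pixel_noise_sd < 0) stop_wc("pixel_noise_sd must be >= 0")
  invisible(p)
}

#' Generate one annotated synthetic wing image
#'
#' Produces a linear-RGB pixel array plus full ground-truth annotation: five
#' landmarks defining two contiguous transect segments through the eyespot
#' centre, half-open segment-boundary intervals on the rasterized transect,
#' the true element colours, and the element label mask.  With the same
#' `params`, `Td_level`, `sex` and `individual` the image is bit-identical
#' across calls.
#'
#' @param params a [wing_sim_params()] object.
#' @param Td_level developmental temperature, 19 or 27.
#' @param sex `"F"` or `"M"` (enters the noise sub-stream only; wing colour
#'   differences between sexes are not simulated).
#' @param individual integer id distinguishing wings of the same cell.
#' @return a list of class `synthetic_wing` with elements `image`
#'   (rows x cols x 3 array), `labels` (integer matrix of element codes),
#'   `annotation` (landmarks, boundaries, element colours), `Td`, `sex`,
#'   `individual`.
#' @export
generate_wing_image <- function(params, Td_level = c(19, 27), sex = c("F", "M"),
                                individual = 1L) {
  validate_wing_sim_params(params)
  Td_level <- match.arg(as.character(Td_level[1]), c("19", "27"))
  sex <- match.arg(sex)
  nr <- params$image_size_px[1]; nc <- params$image_size_px[2]
  r <- params$radii_px[[Td_level]]
  ctr <- params$center
  if (ctr[1] - r[3] < 0 || ctr[1] + r[3] > nr - 1 ||
      ctr[2] - r[3] < 0 || ctr[2] + r[3] > nc - 1) {
    stop_wc("invalid geometry: eyespot radius exceeds image bounds")
  }
  if (params$band_cols[2] >= ctr[2] - r[3]) {
    stop_wc("invalid geometry: band overlaps the eyespot")
  }

  # element label grid (0-based pixel coords; R matrices are 1-based)
  row0 <- matrix(0:(nr - 1), nr, nc)
  col0 <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  d2 <- (row0 - ctr[1])^2 + (col0 - ctr[2])^2
  labels <- matrix(1L, nr, nc) # 1 = background
  labels[col0 >= params$band_cols[1] & col0 <= params$band_cols[2]] <- 2L
  labels[d2 <= r[3]^2] <- 3L # outer ring
  labels[d2 <= r[2]^2] <- 4L # dark disc
  labels[d2 <= r[1]^2] <- 5L # focus
  el_names <- c("wing_background", "central_band", "eyespot_outer_ring",
                "eyespot_dark_disc", "eyespot_focus")

  cols <- params$colors[[Td_level]]
  palette <- rbind(cols$background, cols$band, cols$outer_ring,
                   cols$dark_disc, cols$focus)
  img <- array(0, c(nr, nc, 3))
  for (ch in 1:3) img[, , ch] <- matrix(palette[labels, ch], nr, nc)

  if (params$pixel_noise_sd > 0) {
    seed <- derive_seed(params$seed, paste("wing", Td_level, sex), individual)
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    img <- clip01(img + stats::rnorm(length(img), 0, params$pixel_noise_sd))
  }

  landmarks <- default_landmarks(params)
  transect <- rasterize_transect(landmarks)
  tr_lab <- labels[cbind(transect[, 1] + 1L, transect[, 2] + 1L)]
  # annotate only "pure" transect pixels, whose whole 3x3 sampling window
  # sits inside a single element; transition pixels stay unlabelled so that
  # window-averaged samples inside an interval carry that element's colour
  # exactly
  pure <- rep(TRUE, nrow(transect))
  for (dr in -1:1) for (dc in -1:1) {
    nb <- labels[cbind(pmin(pmax(transect[, 1] + 1L + dr, 1L), nr),
                       pmin(pmax(transect[, 2] + 1L + dc, 1L), nc))]
    pure <- pure & nb == tr_lab
  }
  boundaries <- .runs_to_intervals(ifelse(pure, tr_lab, NA_integer_),
                                   el_names)

  structure(list(
    image = img, labels = labels,
    annotation = list(
      landmarks = landmarks,
      boundaries = boundaries,
      element_colors = stats::setNames(
        lapply(1:5, function(i) palette[i, ]), el_names
      )
    ),
    Td = as.numeric(Td_level), sex = sex, individual = as.integer(individual)
  ), class = "synthetic_wing")
}

# landmarks: 0-based (row, col); horizontal transect through the eyespot
# centre.  p1..p3 is the first segment, p3..p5 the second (shared centre).
default_landmarks <- function(params) {
  rr <- params$center[1]
  cc <- params$center[2]
  r_ring <- max(params$radii_px[["19"]][3], params$radii_px[["27"]][3])
  lm <- rbind(
    c(rr, 10L),
    c(rr, as.integer((params$band_cols[2] + cc - r_ring) %/% 2)),
    c(rr, cc),
    c(rr, as.integer(cc + r_ring + 5L)),
    c(rr, params$image_size_px[2] - 10L)
  )
  colnames(lm) <- c("row", "col")
  lm
}

# consecutive equal-label runs -> named list of [start, end) interval
# matrices; NA codes (transition pixels) are left out of every interval
.runs_to_intervals <- function(lab_codes, el_names) {
  rl <- rle(lab_codes)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths
  out <- stats::setNames(vector("list", length(el_names)), el_names)
  for (i in seq_along(rl$values)) {
    if (is.na(rl$values[i])) next
    nm <- el_names[rl$values[i]]
    out[[nm]] <- rbind(out[[nm]], c(start = starts[i], end = ends[i]))
  }
  out[!vapply(out, is.null, logical(1))]
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
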