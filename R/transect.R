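# Landmark transects: rasterization and 3x3 colour sampling.
#
# The transect is the polyline through five landmarks: segment one runs
# p1 -> p2 -> p3, segment two p3 -> p4 -> p5; the two segments share exactly
# the eyespot-centre landmark p3, which is sampled once.  Coordinates are
# 0-based (row, col); rasterization is 8-connected (Bresenham).

#' Construct and validate a landmark set
#'
#' @param points a 5 x 2 matrix (or coercible) of 0-based `(row, col)` pixel
#'   coordinates: five landmarks defining two contiguous transect segments
#'   through the eyespot centre (the third point).
#' @return integer matrix of class `landmark_set`.
#' @export
landmark_set <- function(points) {
  pts <- matrix(as.integer(round(as.matrix(points))), ncol = 2)
  if (nrow(pts) != 5L) stop_wc("exactly five landmarks are required")
  for (i in 2:5) {
    if (all(pts[i, ] == pts[i - 1L, ])) {
      stop_wc("consecutive landmarks must be distinct (points ", i - 1L,
              " and ", i, " coincide)")
    }
  }
  colnames(pts) <- c("row", "col")
  structure(pts, class = c("landmark_set", "matrix"))
}

# Bresenham line between two 0-based points, endpoints included.
.bresenham <- function(p0, p1) {
  dr <- abs(p1[1] - p0[1]); dc <- abs(p1[2] - p0[2])
  sr <- sign(p1[1] - p0[1]); sc <- sign(p1[2] - p0[2])
  n <- max(dr, dc)
  out <- matrix(0L, n + 1L, 2L)
  r <- p0[1]; c <- p0[2]; err <- dc - dr
  for (i in 0:n) {
    out[i + 1L, ] <- c(r, c)
    e2 <- 2L * err
    if (e2 > -dr) { err <- err - dr; c <- c + sc }
    if (e2 < dc)  { err <- err + dc; r <- r + sr }
  }
  out
}

#' Rasterize the two-segment landmark transect
#'
#' @param landmarks a [landmark_set()] or 5 x 2 coordinate matrix.
#' @return integer matrix of 0-based `(row, col)` transect pixels in order;
#'   pixels shared between consecutive legs (the landmarks themselves) appear
#'   once.
#' @export
rasterize_transect <- function(landmarks) {
  lm <- landmark_set(landmarks)
  legs <- lapply(1:4, function(i) .bresenham(lm[i, ], lm[i + 1L, ]))
  out <- legs[[1]]
  for (i in 2:4) out <- rbind(out, legs[[i]][-1L, , drop = FALSE])
  colnames(out) <- c("row", "col")
  out
}

#' Sample mean colours along the transect
#'
#' At every rasterized transect pixel the unweighted mean of its 3 x 3 pixel
#' neighbourhood is taken per channel, on the linearized image.  Every
#' neighbourhood must lie fully inside the image; landmarks (and any transect
#' pixel) closer than one pixel to the border raise an error.
#'
#' @param image rows x cols x 3 numeric array, linear RGB in `[0, 1]`
#'   (a linearized image; apply [apply_calibration()] first if needed).
#' @param landmarks a [landmark_set()] or 5 x 2 matrix of 0-based points.
#' @return a `transect_profile`: data.frame with columns `pos` (0-based
#'   position index along the transect), `row`, `col` (0-based pixel), and
#'   `R`, `G`, `B` (3 x 3 neighbourhood means).
#' @export
sample_transect <- function(image, landmarks) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L) {
    stop_wc("image must be a rows x cols x 3 array")
  }
  nr <- dim(image)[1]; nc <- dim(image)[2]
  px <- rasterize_transect(landmarks)
  if (any(px[, 1] < 1L) || any(px[, 1] > nr - 2L) ||
      any(px[, 2] < 1L) || any(px[, 2] > nc - 2L)) {
    stop_wc("transect pixels must be at least 1 px from the image border ",
            "so 3 x 3 windows fit")
  }
  n <- nrow(px)
  rgb <- matrix(0, n, 3)
  # sum the 9 shifted images once; cheaper than per-pixel window loops
  for (ch in 1:3) {
    acc <- numeric(n)
    for (dr in -1:1) for (dc in -1:1) {
      acc <- acc + image[cbind(px[, 1] + 1L + dr, px[, 2] + 1L + dc, ch)]
    }
    rgb[, ch] <- acc / 9
  }
  out <- data.frame(
    pos = 0:(n - 1L), row = px[, 1], col = px[, 2],
    R = rgb[, 1], G = rgb[, 2], B = rgb[, 3]
  )
  class(out) <- c("transect_profile", "data.frame")
  out
}

#' Validate segment-boundary intervals against a transect profile
#'
#' Boundaries label half-open index intervals `[start, end)` on the transect
#' with the pattern elements: `wing_background` (one or more intervals),
#' `central_band`, `eyespot_outer_ring`, `eyespot_dark_disc`,
#' `eyespot_focus`.
#'
#' @param boundaries named list; each element a matrix (or vector) of
#'   `c(start, end)` rows, 0-based half-open.
#' @param n_samples transect length the intervals must fit in.
#' @return the boundaries, normalized to matrices, invisibly validated.
#' @export
segment_boundaries <- function(boundaries, n_samples) {
  if (is.null(names(boundaries)) || any(!nzchar(names(boundaries)))) {
    stop_wc("boundaries must be a named list of intervals")
  }
  boundaries <- lapply(boundaries, function(b) {
    b <- matrix(as.integer(b), ncol = 2,
                byrow = is.null(dim(b)) && length(b) > 2)
    colnames(b) <- c("start", "end")
    b
  })
  cover <- integer(n_samples)
  for (nm in names(boundaries)) {
    b <- boundaries[[nm]]
    if (any(b[, 1] < 0) || any(b[, 2] > n_samples) || any(b[, 1] >= b[, 2])) {
      stop_wc("interval for '", nm, "' outside transect or empty")
    }
    for (k in seq_len(nrow(b))) {
      idx <- (b[k, 1] + 1L):b[k, 2]
      if (any(cover[idx] != 0L)) stop_wc("intervals of distinct labels overlap")
      cover[idx] <- 1L
    }
  }
  boundaries
}

# indices (1-based, into profile rows) covered by an element's intervals
.interval_indices <- function(b) {
  unlist(lapply(seq_len(nrow(b)), function(k) (b[k, 1] + 1L):b[k, 2]))
}
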