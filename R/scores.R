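# Contrast and crypsis scores on a sampled transect.

#' Mean chromaticity of each labelled pattern element
#'
#' For each labelled element the mean linear RGB over its interval(s) is
#' taken first and the mean converted to chromaticity second
#' (mean-then-convert; see the methods vignette for why this order).
#'
#' @param profile a `transect_profile` from [sample_transect()].
#' @param bounds named boundary list (see [segment_boundaries()]).
#' @return data.frame with one row per element: `element`, `x`, `y`, `Y`.
#' @export
element_mean_colors <- function(profile, bounds) {
  bounds <- segment_boundaries(bounds, nrow(profile))
  rows <- lapply(names(bounds), function(nm) {
    idx <- .interval_indices(bounds[[nm]])
    if (length(idx) == 0L) stop_wc("empty interval for '", nm, "'")
    mrgb <- colMeans(profile[idx, c("R", "G", "B"), drop = FALSE])
    cbind(element = nm, rgb_to_xyY(mrgb))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Internal contrast: element-to-background chromaticity distances
#'
#' One score per non-background element: the Euclidean distance in the CIE
#' xy plane between the element's mean colour and the wing background's mean
#' colour.  A proxy for how conspicuous each pattern element is against its
#' own wing.
#'
#' @inheritParams element_mean_colors
#' @return data.frame `element`, `distance`.
#' @export
internal_contrast <- function(profile, bounds) {
  means <- element_mean_colors(profile, bounds)
  if (!"wing_background" %in% means$element) {
    stop_wc("boundaries must label 'wing_background'")
  }
  bg <- means[means$element == "wing_background", ]
  el <- means[means$element != "wing_background", ]
  data.frame(
    element = el$element,
    distance = sqrt((el$x - bg$x)^2 + (el$y - bg$y)^2)
  )
}

#' Crypsis score: mean chromatic distance of the transect to a reference
#'
#' The mean, over all transect samples, of the CIE-xy distance between each
#' sample's chromaticity and a reference patch chromaticity (the brown or
#' green assay patch).  An inverse proxy for background matching: lower
#' means better colour similarity to the patch.  Degenerate pure-black
#' samples (no defined chromaticity) are excluded from the mean.
#'
#' @param profile a `transect_profile`.
#' @param reference a chromaticity point (e.g. from [reference_patch()]).
#' @return list of class `crypsis_score` with `score`, `n_samples`,
#'   `n_degenerate`, `reference`.
#' @export
crypsis_score <- function(profile, reference) {
  if (nrow(profile) == 0L) stop_wc("profile is empty")
  xy <- rgb_to_xyY(as.matrix(profile[, c("R", "G", "B")]))
  keep <- !xy$degenerate
  if (!any(keep)) stop_wc("all transect samples are degenerate black")
  d <- sqrt((xy$x[keep] - as.numeric(reference[["x"]]))^2 +
            (xy$y[keep] - as.numeric(reference[["y"]]))^2)
  structure(list(
    score = mean(d), n_samples = nrow(profile),
    n_degenerate = sum(!keep),
    reference = c(x = as.numeric(reference[["x"]]),
                  y = as.numeric(reference[["y"]]))
  ), class = "crypsis_score")
}

#' @export
print.crypsis_score <- function(x, ...) {
  cat(sprintf(
    "Crypsis score: %.4f (mean CIE-xy distance over %d samples%s)\n",
    x$score, x$n_samples - x$n_degenerate,
    if (x$n_degenerate > 0) sprintf(", %d degenerate excluded", x$n_degenerate)
    else ""
  ))
  invisible(x)
}

#' Score one annotated wing image
#'
#' Convenience wrapper running the full colorimetric pipeline on one image:
#' transect sampling, element means, internal contrasts, and crypsis scores
#' against the brown and green assay patches.
#'
#' @param image linearized rows x cols x 3 array.
#' @param landmarks 5 x 2 landmark matrix (0-based).
#' @param boundaries named boundary interval list.
#' @return list with `element_means`, `contrast` (data.frame), and
#'   `crypsis_brown`, `crypsis_green` (numeric scores).
#' @export
score_wing <- function(image, landmarks, boundaries) {
  profile <- sample_transect(image, landmarks)
  list(
    element_means = element_mean_colors(profile, boundaries),
    contrast = internal_contrast(profile, boundaries),
    crypsis_brown = crypsis_score(profile, reference_patch("brown"))$score,
    crypsis_green = crypsis_score(profile, reference_patch("green"))$score
  )
}
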