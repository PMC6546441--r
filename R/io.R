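# Image and annotation I/O.

#' Write a wing image to PNG (8-bit) or TIFF (16-bit)
#'
#' @param image rows x cols x 3 array in `[0, 1]`.
#' @param path output path; format chosen by extension (`.png` or `.tif`/
#'   `.tiff`; TIFF needs the tiff package).
#' @export
write_wing_image <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(image, path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop_wc("the tiff package is required for 16-bit TIFF output")
    }
    tiff::writeTIFF(image, path, bits.per.sample = 16L)
  } else {
    stop_wc("unsupported image extension: ", ext)
  }
  invisible(path)
}

#' Read a wing image as a rows x cols x 3 array in `[0, 1]`
#' @param path PNG or TIFF path.
#' @return numeric array.
#' @export
read_wing_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop_wc("the tiff package is required to read TIFF")
    }
    tiff::readTIFF(path)
  } else {
    stop_wc("unsupported image extension: ", ext)
  }
  if (length(dim(img)) == 2L) stop_wc("grayscale image; RGB required")
  img[, , 1:3, drop = FALSE]
}

#' Write / read per-image annotation JSON
#'
#' Landmarks are stored as 0-based `(row, col)` pairs; boundaries as named
#' half-open `[start, end)` intervals on the transect index.
#'
#' @param annotation list with `landmarks` (5 x 2 matrix) and `boundaries`
#'   (named list of interval matrices), as in `synthetic_wing$annotation`.
#' @param path JSON path.
#' @export
write_annotation_json <- function(annotation, path) {
  payload <- list(
    landmarks = unname(apply(annotation$landmarks, 1, as.integer,
                             simplify = FALSE)),
    boundaries = lapply(annotation$boundaries, function(b) {
      unname(apply(matrix(b, ncol = 2), 1, as.integer, simplify = FALSE))
    })
  )
  jsonlite::write_json(payload, path, digits = NA)
  invisible(path)
}

#' @rdname write_annotation_json
#' @export
read_annotation_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  as_pairs <- function(lst, nms) {
    m <- do.call(rbind, lapply(lst, function(p) as.integer(unlist(p))))
    colnames(m) <- nms
    m
  }
  list(
    landmarks = as_pairs(x$landmarks, c("row", "col")),
    boundaries = lapply(x$boundaries, as_pairs, nms = c("start", "end"))
  )
}
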