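#' Read a grayscale stimulus image
#'
#' Reads a PNG (or TIFF, if the tiff package is installed) raster, averages
#' any colour channels, rescales to \[0, 1\], optionally resamples to the
#' canonical width by nearest-neighbour, and applies the aperture mask.
#'
#' @param path File path (`.png`, `.tif`/`.tiff`).
#' @param width_px Canonical width; images of other sizes are resampled.
#'   Default 200.
#' @param identity,expression Metadata labels.
#' @return A [stimulus_image()].
#' @export
read_stimulus_image <- function(path, width_px = 200L, identity = NA,
                                expression = NA) {
  ext <- tolower(tools::file_ext(path))
  px <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF requires the tiff package", call. = FALSE)
    }
    tiff::readTIFF(path)
  } else {
    stop("unsupported image format: ", ext, call. = FALSE)
  }
  if (length(dim(px)) == 3L) px <- apply(px, c(1, 2), mean)
  if (nrow(px) != ncol(px)) stop("stimulus images must be square",
                                 call. = FALSE)
  if (nrow(px) != width_px) {
    i <- round(seq(1, nrow(px), length.out = width_px))
    px <- px[i, i]
  }
  stimulus_image(px, identity = identity, expression = expression)
}

#' Write synthetic stimuli to PNG files
#'
#' @param images List of [stimulus_image()] objects.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the written file paths (named
#'   `id<identity>_<expression>.png`).
#' @export
write_stimuli <- function(images, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(images, function(im) {
    p <- file.path(dir, sprintf("id%02d_%s.png", im$identity,
                                im$expression))
    png::writePNG(im$pixels, p)
    p
  }, character(1))
  invisible(paths)
}

#' Write a feature matrix as CSV
#'
#' One row per image (or trial), header names encoding the geometry
#' (`sf12_or03`, `r04c07_or5`).
#'
#' @param features Feature matrix from [feature_matrix()] or
#'   [trial_difference_matrix()].
#' @param path Output CSV path.
#' @param ids Optional id column values.
#' @export
write_feature_csv <- function(features, path, ids = seq_len(nrow(features))) {
  df <- data.frame(id = ids, features, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a feature geometry descriptor as JSON
#'
#' @param geometry A [fourier_binning()] or [hog_spec()].
#' @param path Output JSON path.
#' @export
write_geometry_json <- function(geometry, path) {
  stopifnot(inherits(geometry, c("fourier_binning", "hog_spec")))
  obj <- unclass(geometry)
  obj$kind <- if (inherits(geometry, "fourier_binning")) "fourier" else "hog"
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
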