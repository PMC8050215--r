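#' Stimulus image container
#'
#' A square grayscale stimulus with intensities in \[0, 1\], a circular
#' aperture of diameter equal to the image width, and class/identity
#' metadata.  Pixels outside the aperture are set to the mean in-aperture
#' intensity (the background).
#'
#' @param pixels Square numeric matrix with values in \[0, 1\].
#' @param identity Identity label (integer or character).
#' @param expression Expression label, e.g. one of
#'   `c("happy", "angry", "sad", "neutral")` or a synthetic class id.
#' @param mask_aperture Apply the aperture mask (default `TRUE`).
#' @return Object of class `"stimulus_image"`.
#' @export
stimulus_image <- function(pixels, identity = NA, expression = NA,
                           mask_aperture = TRUE) {
  stop_if_not_matrix(pixels, "pixels")
  n <- nrow(pixels)
  if (ncol(pixels) != n) stop("stimulus images must be square", call. = FALSE)
  if (mask_aperture) pixels <- apply_aperture(pixels)
  structure(list(pixels = pixels, width_px = n,
                 identity = identity, expression = expression),
            class = "stimulus_image")
}

#' @export
print.stimulus_image <- function(x, ...) {
  cat(sprintf("Stimulus image %dx%d px (identity %s, expression %s)\n",
              x$width_px, x$width_px, x$identity, x$expression))
  invisible(x)
}

# Replace everything outside the inscribed closed disc by the mean
# in-aperture intensity.
apply_aperture <- function(pixels) {
  n <- nrow(pixels)
  ctr <- (n + 1) / 2
  d2 <- outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, "+")
  inside <- d2 <= (n / 2)^2
  pixels[!inside] <- mean(pixels[inside])
  pixels
}

#' Right-minus-left trial feature difference
#'
#' Forms the per-trial predictor used for choice decoding: the feature
#' vector of the right image minus that of the left image, labelled 1 when
#' the right image received the initial eye movement and 0 otherwise.
#' Swapping the two images and the chosen side negates the difference and
#' flips the label.
#'
#' @param left,right Feature vectors of identical kind and length (from
#'   [fourier_features()] or [hog_features()]).
#' @param chosen_side `"left"` or `"right"`.
#' @return List with elements `diff` (numeric vector) and `label` (0/1).
#' @export
trial_difference <- function(left, right, chosen_side = c("left", "right")) {
  chosen_side <- match.arg(chosen_side)
  if (length(left) != length(right)) {
    stop("feature vectors have different lengths", call. = FALSE)
  }
  nl <- names(left); nr <- names(right)
  if (!is.null(nl) && !is.null(nr) && !identical(nl, nr)) {
    stop("feature geometries do not match", call. = FALSE)
  }
  list(diff = right - left, label = as.integer(chosen_side == "right"))
}

#' Feature matrix for a set of stimulus images
#'
#' @param images List of [stimulus_image()] objects (or plain matrices).
#' @param kind `"fourier"` or `"hog"`.
#' @param geometry A [fourier_binning()] or [hog_spec()]; defaults to the
#'   canonical geometry (384 Fourier features, or 10-px HOG cells).
#' @return Numeric matrix, one row per image, with feature-name columns.
#' @export
feature_matrix <- function(images, kind = c("fourier", "hog"),
                           geometry = NULL) {
  kind <- match.arg(kind)
  w <- if (inherits(images[[1]], "stimulus_image")) images[[1]]$width_px
       else nrow(images[[1]])
  if (is.null(geometry)) {
    geometry <- if (kind == "fourier") fourier_binning(width_px = w)
                else hog_spec(10L, width_px = w)
  }
  fun <- if (kind == "fourier") function(im) fourier_features(im, geometry)
         else function(im) hog_features(im, geometry)
  t(vapply(images, fun, numeric(
    if (kind == "fourier") geometry$n_features else geometry$n_features)))
}

#' Per-trial difference matrix and labels from a trial table
#'
#' @param trials Data frame with columns `left_id`, `right_id` (row indices
#'   into `features`) and `chosen_side` (`"left"`/`"right"`).
#' @param features Per-image feature matrix (rows indexed by image id).
#' @return List with `x` (trial x feature matrix of right-minus-left
#'   differences) and `y` (0/1 labels, 1 = right chosen).
#' @export
trial_difference_matrix <- function(trials, features) {
  stopifnot(all(c("left_id", "right_id", "chosen_side") %in% names(trials)))
  x <- features[trials$right_id, , drop = FALSE] -
       features[trials$left_id, , drop = FALSE]
  rownames(x) <- NULL
  list(x = x, y = as.integer(trials$chosen_side == "right"))
}
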