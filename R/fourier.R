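#' Fourier magnitude-spectrum binning geometry
#'
#' Describes how the 2-D discrete Fourier magnitude spectrum of a square
#' stimulus image is partitioned into spatial-frequency (SF) bands and
#' orientation bands.  The canonical geometry uses 24 equal-width linear SF
#' bands spanning (0, Nyquist] cycles per image and 16 orientation bands of
#' 11.25 degrees covering \[0, 180) degrees, giving 24 x 16 = 384 features.
#' Frequencies beyond the cardinal-axis Nyquist limit (width/2 cycles per
#' image) and the DC component are excluded.
#'
#' @param width_px Image width in pixels (square images only). Default 200.
#' @param n_sf_bands Number of spatial-frequency bands. Default 24.
#' @param n_orientation_bands Number of orientation bands over half a turn.
#'   Default 16.
#' @param sf_band_edges Optional monotone vector of `n_sf_bands + 1` band
#'   edges in cycles per image; the first must be 0 (the band is open at 0)
#'   and the last the Nyquist frequency `width_px / 2`.  Defaults to
#'   equal-width linear spacing.
#' @return An object of class `"fourier_binning"`.
#' @examples
#' b <- fourier_binning()
#' b$n_features  # 384
#' @export
fourier_binning <- function(width_px = 200L, n_sf_bands = 24L,
                            n_orientation_bands = 16L,
                            sf_band_edges = NULL) {
  width_px <- as.integer(width_px)
  nyq <- width_px / 2
  if (is.null(sf_band_edges)) {
    sf_band_edges <- seq(0, nyq, length.out = n_sf_bands + 1L)
  }
  stopifnot(length(sf_band_edges) == n_sf_bands + 1L,
            all(diff(sf_band_edges) > 0),
            sf_band_edges[1] == 0,
            abs(sf_band_edges[length(sf_band_edges)] - nyq) < 1e-9)
  ori_edges <- seq(0, 180, length.out = n_orientation_bands + 1L)
  structure(list(
    width_px = width_px,
    n_sf_bands = as.integer(n_sf_bands),
    n_orientation_bands = as.integer(n_orientation_bands),
    sf_band_edges = sf_band_edges,
    orientation_band_edges = ori_edges,
    nyquist_cpi = nyq,
    n_features = as.integer(n_sf_bands * n_orientation_bands)
  ), class = "fourier_binning")
}

#' @export
print.fourier_binning <- function(x, ...) {
  cat(sprintf(
    "Fourier binning: %d SF bands x %d orientation bands = %d features\n",
    x$n_sf_bands, x$n_orientation_bands, x$n_features))
  cat(sprintf("  SF range (0, %g] cycles/image; orientations [0, 180) deg\n",
              x$nyquist_cpi))
  invisible(x)
}

#' Binned Fourier magnitude features of a stimulus image
#'
#' Computes the 2-D FFT magnitude spectrum of a square grayscale image and
#' sums the magnitudes within each (spatial frequency, orientation) band of
#' `binning`.  The DC component is excluded, as are all frequencies whose
#' radial distance exceeds the cardinal-axis Nyquist frequency.  The
#' conjugate-symmetric half-plane is counted once: every frequency and its
#' conjugate contribute a single magnitude (implemented as weight 1/2 on
#' each member of a conjugate pair, weight 1 on self-conjugate Nyquist
#' points).
#'
#' Because the magnitude spectrum discards phase, the features are invariant
#' to circular translation of the image content.
#'
#' @param img A square numeric matrix (grayscale image, any real values) or
#'   a [stimulus_image()].
#' @param binning A [fourier_binning()] geometry; defaults to the canonical
#'   384-feature geometry for the image's width.
#' @return A named numeric vector of length
#'   `n_sf_bands * n_orientation_bands`, ordered SF-major (all orientations
#'   of band 1, then band 2, ...) with names like `"sf03_or11"`.
#' @examples
#' img <- matrix(0.5, 40, 40)
#' f <- fourier_features(img, fourier_binning(width_px = 40))
#' all(f == 0)  # constant image: all energy at the excluded DC
#' @export
fourier_features <- function(img, binning = NULL) {
  if (inherits(img, "stimulus_image")) img <- img$pixels
  stop_if_not_matrix(img, "img")
  n <- nrow(img)
  if (ncol(img) != n) stop("image must be square", call. = FALSE)
  if (is.null(binning)) binning <- fourier_binning(width_px = n)
  if (binning$width_px != n) {
    stop("binning width_px does not match image size", call. = FALSE)
  }

  mag <- Mod(stats::fft(img))
  k <- 0:(n - 1)
  f <- ifelse(k <= n / 2, k, k - n)   # signed frequency per index
  fy <- matrix(f, n, n)               # rows vary along y
  fx <- matrix(f, n, n, byrow = TRUE) # cols vary along x
  r <- sqrt(fx^2 + fy^2)
  ang <- (atan2(fy, fx) * 180 / pi) %% 180

  keep <- r > 0 & r <= binning$nyquist_cpi
  # self-conjugate points (fx, fy both in {0, n/2}) have no distinct mirror
  selfconj <- (2 * fx) %% n == 0 & (2 * fy) %% n == 0
  w <- ifelse(selfconj, 1, 0.5)

  sf_bin <- findInterval(r[keep], binning$sf_band_edges, left.open = TRUE)
  ori_bin <- findInterval(ang[keep], binning$orientation_band_edges)
  nb <- binning$n_orientation_bands
  idx <- (sf_bin - 1L) * nb + ori_bin

  out <- numeric(binning$n_features)
  acc <- rowsum(w[keep] * mag[keep], group = idx)
  out[as.integer(rownames(acc))] <- acc[, 1]
  names(out) <- fourier_feature_names(binning)
  out
}

fourier_feature_names <- function(binning) {
  sprintf("sf%02d_or%02d",
          rep(seq_len(binning$n_sf_bands), each = binning$n_orientation_bands),
          rep(seq_len(binning$n_orientation_bands), binning$n_sf_bands))
}
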