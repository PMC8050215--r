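#' HOG extraction geometry
#'
#' Histogram-of-oriented-gradients geometry for a square image divided into
#' non-overlapping square cells, each yielding a 9-bin unsigned-gradient
#' orientation histogram.  Cells that are not fully contained in the
#' circular stimulus aperture are dropped, since they carry no stimulus
#' information.  At the canonical 200-px width this keeps 276 of 400 cells
#' at 10-px cells (2484 features), 60 cells at 20 px (540 features) and the
#' central 3 x 3 at 40 px (81 features).
#'
#' @param cell_size_px Cell side in pixels; must divide `width_px`.
#' @param width_px Image width in pixels. Default 200.
#' @param n_orientation_bins Orientation bins over \[0, 180). Default 9.
#' @param aperture_diameter_px Aperture diameter in pixels; default equals
#'   `width_px` (the inscribed disc).
#' @return An object of class `"hog_spec"` with the kept-cell list
#'   (`kept_cells`, a two-column row/col matrix in row-major order).
#' @examples
#' s <- hog_spec(10)
#' nrow(s$kept_cells) * s$n_orientation_bins  # 2484
#' @export
hog_spec <- function(cell_size_px, width_px = 200L, n_orientation_bins = 9L,
                     aperture_diameter_px = width_px) {
  width_px <- as.integer(width_px)
  cell_size_px <- as.integer(cell_size_px)
  kept <- aperture_cell_mask(width_px, cell_size_px, aperture_diameter_px)
  structure(list(
    cell_size_px = cell_size_px,
    width_px = width_px,
    n_orientation_bins = as.integer(n_orientation_bins),
    grid_size = width_px %/% cell_size_px,
    aperture_diameter_px = aperture_diameter_px,
    kept_cells = kept,
    n_features = nrow(kept) * as.integer(n_orientation_bins)
  ), class = "hog_spec")
}

#' @export
print.hog_spec <- function(x, ...) {
  cat(sprintf(
    "HOG spec: %d px cells on a %d px image (%dx%d grid), %d/%d cells in aperture, %d features\n",
    x$cell_size_px, x$width_px, x$grid_size, x$grid_size,
    nrow(x$kept_cells), x$grid_size^2, x$n_features))
  invisible(x)
}

#' Grid cells fully inside the circular aperture
#'
#' Returns the cells of a `width_px / cell_size_px` square grid whose entire
#' square extent lies inside the closed disc of diameter
#' `aperture_diameter_px` centred on the image centre.  A cell is kept iff
#' its farthest corner is within the disc (full-containment rule).
#'
#' @inheritParams hog_spec
#' @return Integer matrix with columns `row`, `col` (1-based grid indices),
#'   rows in row-major order.
#' @examples
#' nrow(aperture_cell_mask(200, 10))  # 276
#' nrow(aperture_cell_mask(200, 40))  # 9 (central 3x3)
#' @export
aperture_cell_mask <- function(width_px, cell_size_px,
                               aperture_diameter_px = width_px) {
  width_px <- as.integer(width_px)
  cell_size_px <- as.integer(cell_size_px)
  if (width_px %% cell_size_px != 0L) {
    stop("cell size must divide image width", call. = FALSE)
  }
  n <- width_px %/% cell_size_px
  ctr <- width_px / 2
  R2 <- (aperture_diameter_px / 2)^2
  rows <- rep(seq_len(n), each = n)
  cols <- rep(seq_len(n), n)
  # farthest corner of cell (r, c) from the centre, per axis
  ylo <- (rows - 1L) * cell_size_px - ctr
  yhi <- rows * cell_size_px - ctr
  xlo <- (cols - 1L) * cell_size_px - ctr
  xhi <- cols * cell_size_px - ctr
  dy2 <- pmax(ylo^2, yhi^2)
  dx2 <- pmax(xlo^2, xhi^2)
  keep <- dx2 + dy2 <= R2
  cbind(row = rows[keep], col = cols[keep])
}

#' Aperture-masked HOG features of a stimulus image
#'
#' Per-cell unsigned-gradient orientation histograms: gradients by centred
#' differences (edge-replicated borders), orientations folded into
#' \[0, 180) and voted into 9 bins with bilinear interpolation between the
#' two nearest bin centres, magnitudes accumulated per non-overlapping
#' cell, each cell histogram L2-normalised (small epsilon; a constant cell
#' stays all-zero).  There is no block normalisation: one histogram per
#' cell.  Cells outside the aperture (see [aperture_cell_mask()]) are
#' dropped and the rest concatenated in row-major cell order, orientation
#' fastest.
#'
#' @param img Square numeric matrix or [stimulus_image()]; width must match
#'   `spec$width_px`.
#' @param spec A [hog_spec()].
#' @return Named numeric vector of length `spec$n_features`, names like
#'   `"r04c07_or5"`.
#' @examples
#' img <- matrix(0.5, 200, 200)
#' length(hog_features(img, hog_spec(20)))  # 540
#' @export
hog_features <- function(img, spec) {
  if (inherits(img, "stimulus_image")) img <- img$pixels
  stop_if_not_matrix(img, "img")
  stopifnot(inherits(spec, "hog_spec"))
  n <- spec$width_px
  if (nrow(img) != n || ncol(img) != n) {
    stop("image size does not match spec width", call. = FALSE)
  }
  if (n < spec$cell_size_px) stop("image smaller than one cell", call. = FALSE)

  # centred differences with edge replication
  pad_lr <- img[, c(1, seq_len(n), n)]
  pad_tb <- img[c(1, seq_len(n), n), ]
  gx <- (pad_lr[, 3:(n + 2)] - pad_lr[, 1:n]) / 2
  gy <- (pad_tb[3:(n + 2), ] - pad_tb[1:n, ]) / 2
  mag <- sqrt(gx^2 + gy^2)
  ang <- (atan2(gy, gx) * 180 / pi) %% 180

  nb <- spec$n_orientation_bins
  binw <- 180 / nb
  t <- ang / binw                 # continuous bin coordinate, centres at 0..nb-1
  k0 <- floor(t)
  frac <- t - k0
  blo <- (k0 %% nb) + 1
  bhi <- ((k0 + 1) %% nb) + 1

  cell <- spec$cell_size_px
  g <- spec$grid_size
  rowidx <- matrix(rep(ceiling(seq_len(n) / cell), n), n, n)
  colidx <- matrix(rep(ceiling(seq_len(n) / cell), each = n), n, n)
  cellid <- (rowidx - 1) * g + colidx

  grp <- c((cellid - 1) * nb + blo, (cellid - 1) * nb + bhi)
  votes <- c(mag * (1 - frac), mag * frac)
  hist_all <- numeric(g * g * nb)
  acc <- rowsum(votes, group = grp)
  hist_all[as.integer(rownames(acc))] <- acc[, 1]
  H <- matrix(hist_all, nrow = nb)   # one column per cell (row-major cells)

  # per-cell L2 normalisation; epsilon keeps constant cells at zero
  eps <- 1e-6
  nrm <- sqrt(colSums(H^2) + eps^2)
  H <- sweep(H, 2, nrm, "/")

  kc <- spec$kept_cells
  keep_id <- (kc[, "row"] - 1) * g + kc[, "col"]
  out <- as.vector(H[, keep_id])
  names(out) <- hog_feature_names(spec)
  out
}

hog_feature_names <- function(spec) {
  kc <- spec$kept_cells
  nb <- spec$n_orientation_bins
  sprintf("r%02dc%02d_or%d",
          rep(kc[, "row"], each = nb),
          rep(kc[, "col"], each = nb),
          rep(seq_len(nb), nrow(kc)))
}
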