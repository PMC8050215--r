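#' Per-feature relevance weights from decoding runs
#'
#' Aggregates one or more fitted decoders into a non-negative per-feature
#' weight expressing each feature's percentage contribution to overall
#' above-chance performance: for every fold, each feature in that fold's
#' final selection is credited `max(0, holdout_accuracy - chance)`, and the
#' total is normalised to sum to 100.  Features never selected have weight
#' 0.
#'
#' @param results A fitted [gaze_decoder()] (or [emotion_decoding()] is not
#'   supported -- weights describe choice decoding), or a list of fits over
#'   which to aggregate (e.g. replicate participants).
#' @param chance An [empirical_chance()] result, or a numeric chance level.
#' @param method `"accuracy"` (default, as above), `"frequency"` (credit 1
#'   per selection, ignoring accuracy), or `"coefficient"` (credit by mean
#'   absolute SVM weight of the fold's final model).
#' @return Object of class `"relevance_weights"`: `weights` (named, sums to
#'   100 unless all-zero), `n_features`, `all_zero` flag.
#' @seealso [hog_heatmap()], [sf_orientation_profiles()]
#' @export
feature_weights <- function(results, chance = 0.5,
                            method = c("accuracy", "frequency",
                                       "coefficient")) {
  method <- match.arg(method)
  if (inherits(results, "gaze_decoder")) results <- list(results)
  stopifnot(length(results) >= 1L,
            all(vapply(results, inherits, logical(1), "gaze_decoder")))
  chance_mean <- if (inherits(chance, "chance_estimate")) chance$mean
                 else as.numeric(chance)
  p <- results[[1]]$n_features
  w <- numeric(p)
  for (fit in results) {
    stopifnot(fit$n_features == p)
    for (res in fit$fold_results) {
      sel <- res$final_set
      credit <- switch(method,
        accuracy = max(0, res$final_accuracy - chance_mean),
        frequency = 1,
        coefficient = {
          if (is.null(res$model)) 0
          else abs(as.numeric(linear_svm_weights(res$model)))
        })
      w[sel] <- w[sel] + credit
    }
  }
  all_zero <- sum(w) <= 0
  if (all_zero) {
    warning("no fold performed above chance; weights are all zero")
  } else {
    w <- 100 * w / sum(w)
  }
  names(w) <- results[[1]]$feature_names %||% paste0("f", seq_len(p))
  structure(list(weights = w, n_features = p, all_zero = all_zero,
                 method = method, chance = chance_mean),
            class = "relevance_weights")
}

#' @export
print.relevance_weights <- function(x, ...) {
  nz <- sum(x$weights > 0)
  cat(sprintf(
    "Relevance weights (%s): %d of %d features nonzero, sum %.1f%%\n",
    x$method, nz, x$n_features, sum(x$weights)))
  top <- sort(x$weights, decreasing = TRUE)[seq_len(min(5, nz))]
  if (nz > 0) {
    cat("  top features:\n")
    for (i in seq_along(top)) {
      cat(sprintf("    %-12s %.2f%%\n", names(top)[i], top[i]))
    }
  }
  invisible(x)
}

#' Spatial relevance heatmap of HOG features
#'
#' Projects relevance weights of a HOG feature space onto the image grid:
#' each kept cell receives the sum of the weights of its orientation bins;
#' cells outside the aperture are `NA`.  The in-aperture map conserves the
#' total weight (100% unless the weights were all zero).
#'
#' @param weights A [feature_weights()] result (or plain numeric vector)
#'   over the HOG feature space of `spec`.
#' @param spec The [hog_spec()] that generated the features.
#' @return A `grid_size x grid_size` matrix of class `"hog_heatmap"` (`NA`
#'   outside the aperture).
#' @export
hog_heatmap <- function(weights, spec) {
  stopifnot(inherits(spec, "hog_spec"))
  if (inherits(weights, "relevance_weights")) weights <- weights$weights
  if (length(weights) != spec$n_features) {
    stop("weights do not match the HOG geometry", call. = FALSE)
  }
  g <- spec$grid_size
  nb <- spec$n_orientation_bins
  map <- matrix(NA_real_, g, g)
  kc <- spec$kept_cells
  per_cell <- colSums(matrix(weights, nrow = nb))
  map[cbind(kc[, "row"], kc[, "col"])] <- per_cell
  structure(map, class = c("hog_heatmap", "matrix"))
}

#' @export
plot.hog_heatmap <- function(x, ...) {
  g <- nrow(x)
  graphics::image(seq_len(g), seq_len(g), t(unclass(x)[g:1, ]),
                  xlab = "cell column", ylab = "cell row",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

#' Spatial-frequency and orientation relevance profiles
#'
#' Marginal sums of Fourier-feature relevance weights over the SF x
#' orientation grid: the per-SF-band profile and the per-orientation-band
#' profile, each conserving the total weight (100%).
#'
#' @param weights A [feature_weights()] result (or numeric vector) over the
#'   Fourier feature space of `binning`.
#' @param binning The [fourier_binning()] that generated the features.
#' @return List of class `"sf_orientation_profiles"` with `sf` (length
#'   `n_sf_bands`) and `orientation` (length `n_orientation_bands`), plus
#'   band-centre vectors for plotting.
#' @export
sf_orientation_profiles <- function(weights, binning) {
  stopifnot(inherits(binning, "fourier_binning"))
  if (inherits(weights, "relevance_weights")) weights <- weights$weights
  if (length(weights) != binning$n_features) {
    stop("weights do not match the Fourier geometry", call. = FALSE)
  }
  grid <- matrix(weights, nrow = binning$n_orientation_bands)  # ori x sf
  sf_prof <- colSums(grid)
  ori_prof <- rowSums(grid)
  sf_centres <- (utils::head(binning$sf_band_edges, -1) +
                   utils::tail(binning$sf_band_edges, -1)) / 2
  ori_centres <- (utils::head(binning$orientation_band_edges, -1) +
                    utils::tail(binning$orientation_band_edges, -1)) / 2
  structure(list(sf = sf_prof, orientation = ori_prof,
                 sf_centres = sf_centres, orientation_centres = ori_centres),
            class = "sf_orientation_profiles")
}

#' @export
plot.sf_orientation_profiles <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$sf_centres, x$sf, type = "b",
                 xlab = "spatial frequency (cycles/image)",
                 ylab = "weight (%)", ...)
  graphics::plot(x$orientation_centres, x$orientation, type = "b",
                 xlab = "orientation (deg)", ylab = "weight (%)", ...)
  invisible(x)
}
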