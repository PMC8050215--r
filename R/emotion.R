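#' Decode the emotional content of single images
#'
#' Four-class expression decoding from single-image feature vectors (no
#' trial differencing); chance is 0.25.  Two modes:
#'
#' * `"free"`: the full ensemble selection procedure of [gaze_decoder()]
#'   (chi-squared ranking, budget, filter/wrapper/random/pseudo-random
#'   candidates, best-of-four by hold-out accuracy) run per fold with a
#'   one-vs-one linear SVM, so the selection has the same degrees of
#'   freedom as the behavioural decoder.
#' * `"transferred"`: per fold, the top-n features by an external
#'   behavioural relevance ranking (`weights`, typically from
#'   [feature_weights()] of a choice-decoding run) are used instead, where
#'   n equals the number of features the reference free-selection run used
#'   in that same fold, with identical folding.  This asks whether the
#'   features that predict eye movements also carry the expression
#'   category.
#'
#' @param x Image-by-feature matrix (single images, not differences).
#' @param classes Expression label per image (4 classes).
#' @param mode `"free"` or `"transferred"`.
#' @param reference A `"free"`-mode `emotion_decoding` result on the same
#'   images; required in transferred mode (supplies folding and per-fold
#'   feature counts).
#' @param weights Per-feature relevance, e.g. a [feature_weights()] result
#'   or a plain numeric vector of length `ncol(x)`; required in
#'   transferred mode.  Ties broken by lower feature index.
#' @param n_folds Folds over images. Default 8.
#' @param control A [decoder_control()].
#' @param seed Integer seed.
#' @return Object of class `"emotion_decoding"`: `fold_accuracy`,
#'   `accuracy` (mean), `n_features_per_fold`, `mode`, `selection_types`
#'   (free mode), `folds`.
#' @export
emotion_decoding <- function(x, classes, mode = c("free", "transferred"),
                             reference = NULL, weights = NULL,
                             n_folds = 8L, control = decoder_control(),
                             seed = 1L) {
  mode <- match.arg(mode)
  stop_if_not_matrix(x)
  classes <- as.character(classes)
  stopifnot(nrow(x) == length(classes))

  if (mode == "transferred") {
    if (is.null(reference) || !inherits(reference, "emotion_decoding")) {
      stop("transferred mode needs a free-selection `reference` run",
           call. = FALSE)
    }
    if (is.null(weights)) {
      stop("transferred mode needs behavioural relevance `weights`",
           call. = FALSE)
    }
    if (inherits(weights, "relevance_weights")) weights <- weights$weights
    if (length(weights) != ncol(x)) {
      stop("weights length does not match the feature space", call. = FALSE)
    }
    folds <- reference$folds
    rank_by_w <- order(-weights, seq_along(weights))
    fold_acc <- numeric(folds$n_folds)
    n_feat <- integer(folds$n_folds)
    for (k in seq_len(folds$n_folds)) {
      hold <- which(folds$assignment == k)
      train <- which(folds$assignment != k)
      n_k <- reference$n_features_per_fold[k]
      cols <- rank_by_w[seq_len(n_k)]
      m <- linear_svm_fit(x[train, cols, drop = FALSE], classes[train],
                          control$cost)
      fold_acc[k] <- mean(linear_svm_predict(
        m, x[hold, cols, drop = FALSE]) == classes[hold])
      n_feat[k] <- n_k
    }
    return(structure(list(
      fold_accuracy = fold_acc, accuracy = mean(fold_acc),
      n_features_per_fold = n_feat, mode = mode,
      selection_types = NULL, folds = folds
    ), class = "emotion_decoding"))
  }

  folds <- make_folds(classes, n_folds = n_folds,
                      seed = child_seed(seed, 0L))
  fold_acc <- numeric(n_folds)
  n_feat <- integer(n_folds)
  types <- character(n_folds)
  for (k in seq_len(n_folds)) {
    hold <- which(folds$assignment == k)
    train <- which(folds$assignment != k)
    ranking <- rank_features_kw(x[train, , drop = FALSE], classes[train])
    budget <- selection_budget(ranking, control$mass_fraction)
    res <- assemble_candidates(
      x[train, , drop = FALSE], classes[train],
      x[hold, , drop = FALSE], classes[hold],
      M = budget$M, ranking = ranking, control = control,
      seed = child_seed(seed, k))
    fold_acc[k] <- res$final_accuracy
    n_feat[k] <- length(res$final_set)
    types[k] <- res$final_type
  }
  structure(list(
    fold_accuracy = fold_acc, accuracy = mean(fold_acc),
    n_features_per_fold = n_feat, mode = mode,
    selection_types = types, folds = folds
  ), class = "emotion_decoding")
}

#' @export
print.emotion_decoding <- function(x, ...) {
  cat(sprintf(
    "Emotion decoding (%s mode): mean 4-class accuracy %.4f (chance 0.25)\n",
    x$mode, x$accuracy))
  cat("  features per fold: ",
      paste(x$n_features_per_fold, collapse = " "), "\n")
  invisible(x)
}
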