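#' Fit the ensemble feature-selection choice decoder
#'
#' The core model of the package: predicts, per trial, which of two
#' simultaneously presented faces receives the initial eye movement, from
#' the right-minus-left difference of low-level image features.  The data
#' are split into stratified, temporally interleaved folds; within each
#' fold's training pool every feature is ranked by its Kruskal-Wallis
#' chi-squared statistic, the score mass fixes a feature budget M, four
#' candidate selections of size M are assembled (chi-squared filter,
#' iterative SVM wrapper, random, pseudo-random), and the candidate with
#' the highest hold-out accuracy becomes that fold's final model.  An
#' all-features reference model is fitted alongside.
#'
#' Because the final model is the best of four, its hold-out accuracy is
#' optimistically biased; compare it against [empirical_chance()], which
#' rebuilds the same max-of-four statistic on shuffled features, rather
#' than against 0.5.
#'
#' @param x Trial-by-feature numeric matrix of right-minus-left feature
#'   differences (see [trial_difference_matrix()]).
#' @param y 0/1 labels (1 = right image chosen), in presentation order.
#' @param n_folds Number of cross-validation folds. Default 8.
#' @param control A [decoder_control()].
#' @param seed Integer seed; the whole fit is deterministic given it.
#' @param feature_kind Optional metadata tag (e.g. `"fourier"`, `"hog10"`).
#' @return Object of class `"gaze_decoder"`; see Details.  Key components:
#'   `fold_results` (per-fold [assemble_candidates()] output),
#'   `accuracy` (mean final-model hold-out accuracy),
#'   `full_accuracy` (mean all-features accuracy),
#'   `selection_types` (which candidate won each fold),
#'   `cv_predictions` (per-trial cross-validated predicted labels),
#'   `folds` (the [make_folds()] plan).
#' @seealso [empirical_chance()], [feature_weights()], [bias_baseline()]
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(160 * 12), 160, 12)
#' y <- as.integer(x[, 3] + rnorm(160, sd = 0.5) > 0)
#' fit <- gaze_decoder(x, y, seed = 7)
#' fit$accuracy
#' @export
gaze_decoder <- function(x, y, n_folds = 8L, control = decoder_control(),
                         seed = 1L, feature_kind = NULL) {
  stop_if_not_matrix(x)
  y <- as01(y)
  stopifnot(nrow(x) == length(y))

  folds <- make_folds(y, n_folds = n_folds, seed = child_seed(seed, 0L))
  fold_results <- vector("list", folds$n_folds)
  cv_pred <- rep(NA_integer_, length(y))

  for (k in seq_len(folds$n_folds)) {
    hold <- which(folds$assignment == k)
    train <- which(folds$assignment != k)
    ranking <- rank_features_kw(x[train, , drop = FALSE], y[train])
    # degenerate pool (all scores zero, e.g. all-constant differences):
    # fall back to a budget of one so the fit still reports ~chance
    M <- if (sum(ranking$scores) > 0) {
      selection_budget(ranking, control$mass_fraction)$M
    } else 1L
    res <- assemble_candidates(
      x[train, , drop = FALSE], y[train],
      x[hold, , drop = FALSE], y[hold],
      M = M, ranking = ranking, control = control,
      seed = child_seed(seed, k))
    if (!is.null(res$model)) {
      cv_pred[hold] <- as.integer(linear_svm_predict(
        res$model, x[hold, res$final_set, drop = FALSE]))
    }
    fold_results[[k]] <- res
  }

  acc <- vapply(fold_results, `[[`, numeric(1), "final_accuracy")
  full <- vapply(fold_results, `[[`, numeric(1), "full_accuracy")
  types <- vapply(fold_results, `[[`, character(1), "final_type")

  structure(list(
    fold_results = fold_results,
    folds = folds,
    accuracy = mean(acc),
    fold_accuracy = acc,
    full_accuracy = if (all(is.na(full))) NA_real_ else mean(full),
    fold_full_accuracy = full,
    selection_types = types,
    cv_predictions = cv_pred,
    y = y,
    n_features = ncol(x),
    feature_names = colnames(x),
    feature_kind = feature_kind,
    control = control,
    seed = seed,
    call = match.call()
  ), class = "gaze_decoder")
}

#' @export
print.gaze_decoder <- function(x, ...) {
  cat("Ensemble feature-selection choice decoder\n")
  cat(sprintf("  %d trials, %d features%s, %d folds\n",
              length(x$y), x$n_features,
              if (!is.null(x$feature_kind))
                paste0(" (", x$feature_kind, ")") else "",
              x$folds$n_folds))
  cat(sprintf("  mean hold-out accuracy (final models): %.4f\n", x$accuracy))
  if (!is.na(x$full_accuracy)) {
    cat(sprintf("  mean hold-out accuracy (all features): %.4f\n",
                x$full_accuracy))
  }
  invisible(x)
}

#' @export
summary.gaze_decoder <- function(object, ...) {
  M <- vapply(object$fold_results, `[[`, integer(1), "budget_M")
  structure(list(
    accuracy = object$accuracy,
    full_accuracy = object$full_accuracy,
    fold_accuracy = object$fold_accuracy,
    selection_types = table(factor(
      object$selection_types,
      levels = c("filter", "wrapper", "random", "pseudo_random"))),
    budget_M = M,
    mean_fraction_used = mean(M) / object$n_features,
    n_features = object$n_features,
    n_trials = length(object$y)
  ), class = "summary.gaze_decoder")
}

#' @export
print.summary.gaze_decoder <- function(x, ...) {
  cat("Ensemble feature-selection choice decoder\n")
  cat(sprintf("  trials: %d   features: %d\n", x$n_trials, x$n_features))
  cat(sprintf("  mean final-model accuracy: %.4f\n", x$accuracy))
  if (!is.na(x$full_accuracy)) {
    cat(sprintf("  mean full-model accuracy:  %.4f\n", x$full_accuracy))
  }
  cat("  per-fold accuracy: ",
      paste(sprintf("%.3f", x$fold_accuracy), collapse = " "), "\n")
  cat("  winning selection types:\n")
  print(x$selection_types)
  cat(sprintf("  feature budget M per fold: %s (%.1f%% of features on average)\n",
              paste(x$budget_M, collapse = " "),
              100 * x$mean_fraction_used))
  invisible(x)
}

#' Average linear readout weights of a fitted decoder
#'
#' Maps each fold's final linear-SVM weight vector (in standardized feature
#' space) back into the full feature space, zero elsewhere, and averages
#' across folds.  The sign convention follows the right-minus-left
#' difference with label 1 = right chosen.
#'
#' @param object A fitted [gaze_decoder()].
#' @param ... Unused.
#' @return Named numeric vector of length `n_features`.
#' @export
coef.gaze_decoder <- function(object, ...) {
  w <- numeric(object$n_features)
  nf <- 0L
  for (res in object$fold_results) {
    if (is.null(res$model)) next
    wv <- as.numeric(linear_svm_weights(res$model))
    w[res$final_set] <- w[res$final_set] + wv
    nf <- nf + 1L
  }
  if (nf > 0L) w <- w / nf
  names(w) <- object$feature_names %||%
    paste0("f", seq_len(object$n_features))
  w
}

#' Predict choices for new trials
#'
#' Applies every fold's final model to the new difference vectors and takes
#' the majority vote (ties go to label 1, the right image).
#'
#' @param object A fitted [gaze_decoder()].
#' @param newdata Trial-by-feature matrix with the same feature space.
#' @param ... Unused.
#' @return Integer vector of 0/1 predicted labels.
#' @export
predict.gaze_decoder <- function(object, newdata, ...) {
  stop_if_not_matrix(newdata, "newdata")
  if (ncol(newdata) != object$n_features) {
    stop("newdata has the wrong number of features", call. = FALSE)
  }
  votes <- matrix(NA_real_, nrow(newdata), 0)
  for (res in object$fold_results) {
    if (is.null(res$model)) next
    p <- as.integer(linear_svm_predict(
      res$model, newdata[, res$final_set, drop = FALSE]))
    votes <- cbind(votes, p)
  }
  if (ncol(votes) == 0L) stop("no usable fold models", call. = FALSE)
  as.integer(rowMeans(votes) >= 0.5)
}

#' @export
fitted.gaze_decoder <- function(object, ...) object$cv_predictions

#' @export
residuals.gaze_decoder <- function(object, ...) {
  object$y - object$cv_predictions
}

#' Accuracy overview plot for a fitted decoder
#'
#' Bar plot of the mean hold-out accuracy of the four candidate selection
#' types, the final (best-of-four) model and the all-features model, with
#' an optional empirical-chance reference line.
#'
#' @param x A fitted [gaze_decoder()].
#' @param chance Optional [empirical_chance()] result or numeric level.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.gaze_decoder <- function(x, chance = NULL, ...) {
  cand <- rowMeans(vapply(x$fold_results, `[[`,
                          numeric(4), "holdout_accuracy"), na.rm = TRUE)
  vals <- c(cand, final = x$accuracy, full = x$full_accuracy)
  graphics::barplot(vals, ylim = c(0, 1),
                    ylab = "hold-out accuracy", las = 2, ...)
  if (!is.null(chance)) {
    lev <- if (inherits(chance, "chance_estimate")) chance$mean else chance
    graphics::abline(h = lev, lty = 2)
  }
  invisible(vals)
}
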