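#' Emotion-content bias baseline for choice prediction
#'
#' Predicts initial eye movements from expression-category preferences
#' alone, using the same cross-validation folding as the feature decoder.
#' For every fold and every unordered pair of different expressions, the
#' training folds give the bias (the proportion of trials on which
#' expression A rather than B was chosen); each test trial of that pair is
#' then predicted as a choice of the majority expression's side.  A bias of
#' exactly 0.5 predicts the expression earlier in canonical (alphabetical)
#' order.
#'
#' @param trials Data frame with columns `left_class`, `right_class` and
#'   `chosen_side` (`"left"`/`"right"`); only rows with differing classes
#'   enter the analysis.
#' @param folds A `"fold_plan"` from [make_folds()] covering all rows of
#'   `trials` (the same plan used for the feature decoder).
#' @return Object of class `"bias_baseline"`: `per_pair` data frame (pair,
#'   mean training bias, mean test accuracy over folds), `mean_accuracy`
#'   (across all different-expression test trials), `fold_table` with the
#'   per-fold detail.
#' @export
bias_baseline <- function(trials, folds) {
  stopifnot(inherits(folds, "fold_plan"),
            length(folds$assignment) == nrow(trials),
            all(c("left_class", "right_class", "chosen_side") %in%
                  names(trials)))
  lc <- as.character(trials$left_class)
  rc <- as.character(trials$right_class)
  chosen <- ifelse(trials$chosen_side == "right", rc, lc)
  diffr <- lc != rc
  if (!any(diffr)) {
    stop("no trials with differing expressions", call. = FALSE)
  }
  pairA <- pmin(lc, rc)
  pairB <- pmax(lc, rc)
  pair <- paste(pairA, pairB, sep = ":")

  rows <- list()
  for (k in seq_len(folds$n_folds)) {
    test <- folds$assignment == k & diffr
    train <- folds$assignment != k & diffr
    for (pr in sort(unique(pair[diffr]))) {
      tr <- train & pair == pr
      te <- test & pair == pr
      if (!any(te)) next
      if (!any(tr)) next   # pair absent from training folds: skip
      A <- pairA[which(pair == pr)[1]]
      bias <- mean(chosen[tr] == A)
      predicted <- if (bias >= 0.5) A else pairB[which(pair == pr)[1]]
      acc <- mean(chosen[te] == predicted)
      rows[[length(rows) + 1L]] <- data.frame(
        fold = k, pair = pr, bias = bias, accuracy = acc,
        n_test = sum(te), stringsAsFactors = FALSE)
    }
  }
  ft <- do.call(rbind, rows)
  per_pair <- do.call(rbind, lapply(split(ft, ft$pair), function(d) {
    data.frame(pair = d$pair[1], bias = mean(d$bias),
               accuracy = mean(d$accuracy), n_test = sum(d$n_test),
               stringsAsFactors = FALSE)
  }))
  rownames(per_pair) <- NULL
  mean_acc <- sum(ft$accuracy * ft$n_test) / sum(ft$n_test)
  structure(list(per_pair = per_pair, fold_table = ft,
                 mean_accuracy = mean_acc),
            class = "bias_baseline")
}

#' @export
print.bias_baseline <- function(x, ...) {
  cat(sprintf("Emotion-content bias baseline: mean accuracy %.4f\n",
              x$mean_accuracy))
  print(x$per_pair, row.names = FALSE)
  invisible(x)
}
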