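#' Decoder configuration
#'
#' Tunable parameters of the ensemble feature-selection decoder.  Defaults
#' follow the canonical procedure; only computational knobs (subsample
#' size, SVM cost) are free choices.
#'
#' @param cost Linear SVM regularization constant C. Default 1.
#' @param mass_fraction Score-mass fraction defining the feature budget
#'   (see [selection_budget()]). Default 0.10.
#' @param subsample_size Number of top-priority unselected features tested
#'   per wrapper iteration; `NULL` (default) means
#'   `max(10, ceiling(0.05 * n_features))`.
#' @param prune_fraction Fraction of the budget at which the one-off
#'   pruning checkpoint runs. Default 0.25.
#' @param split_frac Training fraction of each balanced resplit. Default 0.5.
#' @param compute_full Also fit the all-features reference model per fold.
#'   Default `TRUE`.
#' @param max_wrapper_iter Safety cap on wrapper iterations (multiples of
#'   the budget). Default 4.
#' @return A list of class `"decoder_control"`.
#' @export
decoder_control <- function(cost = 1, mass_fraction = 0.10,
                            subsample_size = NULL, prune_fraction = 0.25,
                            split_frac = 0.5, compute_full = TRUE,
                            max_wrapper_iter = 4L) {
  structure(list(cost = cost, mass_fraction = mass_fraction,
                 subsample_size = subsample_size,
                 prune_fraction = prune_fraction,
                 split_frac = split_frac, compute_full = compute_full,
                 max_wrapper_iter = as.integer(max_wrapper_iter)),
            class = "decoder_control")
}

default_subsample <- function(control, n_features) {
  control$subsample_size %||% max(10L, ceiling(0.05 * n_features))
}

#' Iterative SVM wrapper feature selection
#'
#' Builds a feature set of size `M` in a stepwise additive manner.  Each
#' iteration draws a fresh class-balanced train/validation split of the
#' pool, takes the top-`S` unselected features by current priority
#' (initialised from the chi-squared ranking, thereafter updated to each
#' feature's last observed validation F1), trains a linear SVM on the
#' already-selected set plus each candidate, and includes the candidate
#' with the best validation F1.  When the selection first reaches
#' `ceiling(prune_fraction * M)` features, each included feature is removed
#' in turn and dropped if the F1 without it is at least the F1 with it.
#' The loop ends when `M` features are included (or the pool is
#' exhausted).
#'
#' @param x Trial-by-feature matrix (the 7 training partitions of a fold).
#' @param y Labels; 0/1 for choice decoding (validation metric is then the
#'   F1 of class 1), or multi-class (macro F1) for emotion decoding.
#' @param M Feature budget (see [selection_budget()]).
#' @param ranking A `"ranked_features"` object for `x`, `y`.
#' @param control A [decoder_control()].
#' @param seed Integer seed driving the balanced resplits.
#' @return Integer vector of selected feature indices (length <= M).
#' @export
wrapper_selection <- function(x, y, M, ranking, control = decoder_control(),
                              seed = 1L) {
  stop_if_not_matrix(x)
  y <- as.character(y)
  p <- ncol(x)
  M <- as.integer(M)
  stopifnot(M >= 1L)
  S <- default_subsample(control, p)

  # priorities in [0,1]: rank percentile initially, validation F1 after a
  # feature has been evaluated once
  prio <- numeric(p)
  prio[ranking$order] <- seq(1, 1 / p, length.out = p)

  selected <- integer(0)
  pruned <- FALSE
  prune_at <- max(1L, ceiling(control$prune_fraction * M))
  iter <- 0L
  max_iter <- control$max_wrapper_iter * M

  while (length(selected) < M && iter < max_iter) {
    iter <- iter + 1L
    pool <- setdiff(seq_len(p), selected)
    if (length(pool) == 0L) break
    sp <- balanced_split(y, seed = child_seed(seed, iter),
                         frac = control$split_frac)
    cand <- pool[order(-prio[pool], pool)][seq_len(min(S, length(pool)))]
    f1s <- vapply(cand, function(cc) {
      try_subset_f1(x, y, sp$train, sp$validation, c(selected, cc),
                    control$cost)
    }, numeric(1))
    prio[cand[!is.na(f1s)]] <- f1s[!is.na(f1s)]
    if (all(is.na(f1s))) next   # degenerate split: redraw
    best <- cand[which.max(f1s)]
    selected <- c(selected, best)

    if (!pruned && length(selected) >= prune_at) {
      selected <- prune_selection(x, y, sp$train, sp$validation, selected,
                                  control$cost)
      pruned <- TRUE
    }
  }
  selected
}

# One-off pruning checkpoint: each included feature is removed in turn and
# dropped when the validation F1 without it is at least the F1 with it
# (redundant features contribute nothing and are excluded).
prune_selection <- function(x, y, train, val, selected, cost) {
  base <- try_subset_f1(x, y, train, val, selected, cost)
  for (f in selected) {
    rest <- setdiff(selected, f)
    if (length(rest) == 0L) break
    without <- try_subset_f1(x, y, train, val, rest, cost)
    if (!is.na(without) && !is.na(base) && without >= base) {
      selected <- rest
      base <- without
    }
  }
  selected
}

#' Four candidate feature selections and their hold-out accuracies
#'
#' Builds the filter (top-`M` ranked), wrapper (see [wrapper_selection()]),
#' random (uniform draw of `M` features) and pseudo-random (uniform draw of
#' `M` features untouched by filter and wrapper) selections; trains a
#' linear SVM on the full training pool for each; and scores every
#' candidate on the held-out partition.  The final selection is the
#' candidate with the highest hold-out accuracy (ties broken in the fixed
#' order filter, wrapper, random, pseudo-random).  Optionally also fits the
#' all-features reference model.
#'
#' @param x,y Training pool (7 partitions) matrix and labels (0/1 for
#'   choice decoding; multi-class allowed).
#' @param x_holdout,y_holdout Held-out partition.
#' @param M Feature budget.
#' @param ranking A `"ranked_features"` object for `x`, `y`.
#' @param control A [decoder_control()].
#' @param seed Integer seed (wrapper resplits and random draws).
#' @return List of class `"candidate_selections"`: per-candidate index
#'   sets, named `holdout_accuracy` vector, `final_type`, `final_set`,
#'   `final_accuracy`, `budget_M`, `full_accuracy` (or `NA`), and the
#'   fitted final `model`.
#' @export
assemble_candidates <- function(x, y, x_holdout, y_holdout, M, ranking,
                                control = decoder_control(), seed = 1L) {
  y <- as.character(y); y_holdout <- as.character(y_holdout)
  p <- ncol(x)
  M <- as.integer(M)
  if (M > p) stop("budget exceeds the number of features", call. = FALSE)

  filter <- ranking$order[seq_len(M)]
  wrapper <- wrapper_selection(x, y, M, ranking, control,
                               seed = child_seed(seed, 1L))
  sets <- with_seed(child_seed(seed, 2L), {
    rnd <- sort(sample(p, M))
    pool <- setdiff(seq_len(p), union(filter, wrapper))
    if (length(pool) >= M) {
      psr <- sort(sample(pool, M))
    } else {
      # too few untouched features: keep all of them, pad from the rest
      pad <- sample(setdiff(seq_len(p), pool), M - length(pool))
      psr <- sort(c(pool, pad))
    }
    list(random = rnd, pseudo_random = psr)
  })

  cands <- list(filter = sort(filter), wrapper = sort(wrapper),
                random = sets$random, pseudo_random = sets$pseudo_random)
  models <- vector("list", length(cands))
  acc <- rep(NA_real_, length(cands))
  names(acc) <- names(cands)
  for (i in seq_along(cands)) {
    cols <- cands[[i]]
    if (length(cols) == 0L) next
    m <- tryCatch(linear_svm_fit(x[, cols, drop = FALSE], y, control$cost),
                  error = function(e) NULL)
    if (is.null(m)) next
    models[[i]] <- m
    acc[i] <- mean(linear_svm_predict(m, x_holdout[, cols, drop = FALSE]) ==
                     as.character(y_holdout))
  }
  final_i <- which.max(acc)  # ties: first in fixed candidate order
  full_acc <- NA_real_
  if (isTRUE(control$compute_full)) {
    fm <- tryCatch(linear_svm_fit(x, y, control$cost),
                   error = function(e) NULL)
    if (!is.null(fm)) {
      full_acc <- mean(linear_svm_predict(fm, x_holdout) ==
                         as.character(y_holdout))
    }
  }
  structure(list(
    filter = cands$filter, wrapper = cands$wrapper,
    random = cands$random, pseudo_random = cands$pseudo_random,
    holdout_accuracy = acc,
    final_type = names(cands)[final_i],
    final_set = cands[[final_i]],
    final_accuracy = unname(acc[final_i]),
    budget_M = M,
    full_accuracy = full_acc,
    model = models[[final_i]]
  ), class = "candidate_selections")
}
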