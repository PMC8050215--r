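#' Stratified, temporally interleaved cross-validation folds
#'
#' Assigns trials to `n_folds` partitions so that (a) each partition has
#' approximately the same class balance (per-class fold sizes differ by at
#' most one) and (b) each partition contains trials from throughout the
#' session: within each class, consecutive blocks of `n_folds` trials (in
#' presentation order) each contribute exactly one trial per fold, via a
#' fresh seeded permutation per block.
#'
#' @param y Class labels in presentation order (any number of classes).
#' @param n_folds Number of folds. Default 8.
#' @param seed Integer seed; assignment is deterministic given the seed.
#' @return Object of class `"fold_plan"`: list with `assignment` (integer
#'   fold index per trial) and `n_folds`.
#' @export
make_folds <- function(y, n_folds = 8L, seed = 1L) {
  n_folds <- as.integer(n_folds)
  y <- as.factor(y)
  tab <- table(y)
  if (length(tab) < 2L) {
    stop("need at least two classes to stratify", call. = FALSE)
  }
  if (any(tab < n_folds)) {
    stop(sprintf("every class needs at least %d trials for %d folds",
                 n_folds, n_folds), call. = FALSE)
  }
  assignment <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)             # temporal order
      m <- length(idx)
      folds <- integer(m)
      pos <- 1L
      while (pos <= m) {
        take <- min(n_folds, m - pos + 1L)
        folds[pos:(pos + take - 1L)] <- sample(n_folds)[seq_len(take)]
        pos <- pos + take
      }
      assignment[idx] <- folds
    }
  })
  structure(list(assignment = assignment, n_folds = n_folds),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("Fold plan: %d folds over %d trials\n",
              x$n_folds, length(x$assignment)))
  print(table(fold = x$assignment))
  invisible(x)
}

#' Class-balanced train/validation split
#'
#' Draws approximately 50% of a pool of trials as a training set with equal
#' class representation; the remainder is the validation set.  The
#' per-class training count is `floor(frac * n) / n_classes` rounded down,
#' capped by the smallest class, so the training set is exactly balanced
#' even when the pool is not.
#'
#' @param y Class labels of the pool.
#' @param seed Integer seed.
#' @param frac Target training fraction of the pool. Default 0.5.
#' @return List with integer index vectors `train` and `validation`.
#' @export
balanced_split <- function(y, seed = 1L, frac = 0.5) {
  y <- as.factor(y)
  tab <- table(y)
  if (any(tab == 0L) || length(tab) < 2L) {
    stop("both (all) classes must be present in the pool", call. = FALSE)
  }
  k <- length(tab)
  per_class <- min(floor(frac * length(y) / k), min(tab))
  if (per_class < 1L) stop("pool too small for a balanced split", call. = FALSE)
  train <- integer(0)
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      train <- c(train, sample(idx, per_class))
    }
  })
  train <- sort(train)
  validation <- setdiff(seq_along(y), train)
  if (length(validation) == 0L) {
    stop("validation set is empty", call. = FALSE)
  }
  list(train = train, validation = validation)
}
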