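# Internal linear-SVM wrapper: standardization fitted on training data,
# fixed cost, deterministic. Built on e1071 (libsvm).

linear_svm_fit <- function(x, y, cost = 1) {
  x <- as.matrix(x)
  y <- as.factor(y)
  if (nlevels(droplevels(y)) < 2L) stop("single-class training set")
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  xs <- sweep(sweep(x, 2, mu, "-"), 2, sd, "/")
  fit <- e1071::svm(x = xs, y = y, kernel = "linear", cost = cost,
                    scale = FALSE)
  list(fit = fit, mu = mu, sd = sd, levels = levels(y))
}

linear_svm_predict <- function(model, x) {
  x <- as.matrix(x)
  xs <- sweep(sweep(x, 2, model$mu, "-"), 2, model$sd, "/")
  as.character(stats::predict(model$fit, xs))
}

# Primal weight vector (standardized space), one column per binary
# sub-problem; for a two-class fit a single vector.
linear_svm_weights <- function(model) {
  crossprod(model$fit$coefs, model$fit$SV)
}

# F1 of the positive class for two-class problems; unweighted macro F1
# otherwise. Degenerate precision/recall contribute 0.
f1_score <- function(truth, pred, positive = "1") {
  truth <- as.character(truth)
  pred <- as.character(pred)
  lev <- sort(unique(truth))
  per_class <- function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }
  if (length(lev) <= 2L && positive %in% lev) {
    per_class(positive)
  } else {
    mean(vapply(lev, per_class, numeric(1)))
  }
}

# Train on x[train, cols], F1 on x[val, cols]; NA when the fit degenerates.
try_subset_f1 <- function(x, y, train, val, cols, cost) {
  tryCatch({
    m <- linear_svm_fit(x[train, cols, drop = FALSE], y[train], cost)
    p <- linear_svm_predict(m, x[val, cols, drop = FALSE])
    f1_score(y[val], p)
  }, error = function(e) NA_real_)
}
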