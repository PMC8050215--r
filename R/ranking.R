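#' Kruskal-Wallis feature ranking
#'
#' Scores every feature column by its Kruskal-Wallis chi-squared (H)
#' statistic across the label groups, with the standard midrank tie
#' correction.  For two classes this is the rank statistic used to seed the
#' filter and wrapper selections; a feature whose values are all tied
#' scores 0.
#'
#' @param x Trial-by-feature numeric matrix.
#' @param y Group labels (two or more groups, each with at least 2 trials).
#' @return Object of class `"ranked_features"`: list with `scores`
#'   (non-negative per-feature H statistics) and `order` (feature indices
#'   in descending score order, ties broken by lower index).
#' @examples
#' x <- cbind(a = c(1, 2, 3, 4, 5, 6, 7, 8))
#' rank_features_kw(x, rep(0:1, each = 4))$scores  # 16/3
#' @export
rank_features_kw <- function(x, y) {
  stop_if_not_matrix(x)
  y <- as.factor(y)
  tab <- table(y)
  if (length(tab) < 2L || any(tab < 2L)) {
    stop("need at least two groups with >= 2 trials each", call. = FALSE)
  }
  n <- nrow(x)
  grp <- as.integer(y)
  ng <- as.vector(tab)

  scores <- vapply(seq_len(ncol(x)), function(j) {
    r <- rank(x[, j])
    rbar <- vapply(seq_along(ng), function(g) mean(r[grp == g]), numeric(1))
    h <- 12 / (n * (n + 1)) * sum(ng * (rbar - (n + 1) / 2)^2)
    t <- table(x[, j])
    corr <- 1 - sum(t^3 - t) / (n^3 - n)
    if (corr <= 0) 0 else h / corr
  }, numeric(1))
  scores[scores < 0] <- 0

  structure(list(scores = unname(scores),
                 order = order(-scores, seq_along(scores))),
            class = "ranked_features")
}

#' Feature budget from the chi-squared score mass
#'
#' The number of features every candidate selection may use: the smallest
#' count M of top-ranked features whose scores collectively contain
#' `mass_fraction` (default 10%) of the total score sum.  Sharply peaked
#' rankings therefore yield small budgets.
#'
#' @param scores Non-negative per-feature scores (e.g. from
#'   [rank_features_kw()]), or a `"ranked_features"` object.
#' @param mass_fraction Fraction of total score mass. Default 0.10.
#' @return Object of class `"selection_budget"`: list with `M`,
#'   `mass_fraction`, and `order` (descending score order).
#' @examples
#' selection_budget(c(10, 5, 3, 2))$M  # 1: the top score already holds 50%
#' selection_budget(rep(1, 100))$M     # 10
#' @export
selection_budget <- function(scores, mass_fraction = 0.10) {
  if (inherits(scores, "ranked_features")) scores <- scores$scores
  if (any(scores < 0)) stop("scores must be non-negative", call. = FALSE)
  total <- sum(scores)
  if (total <= 0) stop("all scores are zero; no budget defined", call. = FALSE)
  ord <- order(-scores, seq_along(scores))
  cs <- cumsum(scores[ord])
  M <- which(cs >= mass_fraction * total)[1]
  structure(list(M = as.integer(M), mass_fraction = mass_fraction,
                 order = ord),
            class = "selection_budget")
}
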