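test_that("a perfectly separating feature is included immediately", {
  d <- planted_diffs(n = 80, p = 8, k = 1, effect = 6, seed = 31)
  ranking <- rank_features_kw(d$x, d$y)
  sel <- wrapper_selection(d$x, d$y, M = 3, ranking,
                           control = decoder_control(), seed = 1)
  expect_true(1L %in% sel)
  expect_equal(sel[1], 1L)
})

test_that("all-noise pools still return a full budget of features", {
  d <- planted_diffs(n = 64, p = 20, k = 0, effect = 0, seed = 32)
  ranking <- rank_features_kw(d$x, d$y)
  sel <- wrapper_selection(d$x, d$y, M = 5, ranking,
                           control = decoder_control(), seed = 2)
  expect_length(sel, 5L)
  expect_length(unique(sel), 5L)
})

test_that("the pruning checkpoint drops a redundant duplicated feature", {
  d <- planted_diffs(n = 80, p = 6, k = 1, effect = 4, seed = 33)
  x <- cbind(d$x, d$x[, 1])   # column 7 duplicates the informative column 1
  y <- d$y
  sp <- balanced_split(y, seed = 4)
  pruned <- gazeselect:::prune_selection(x, y, sp$train, sp$validation,
                                         selected = c(1L, 7L, 3L), cost = 1)
  # F1 without the duplicate is unchanged, so one of the pair must go
  expect_false(all(c(1L, 7L) %in% pruned))
})

test_that("candidate selections have the right sizes and disjointness", {
  d <- planted_diffs(n = 96, p = 30, k = 2, effect = 1.5, seed = 34)
  fp <- make_folds(d$y, n_folds = 8, seed = 1)
  hold <- fp$assignment == 1
  ranking <- rank_features_kw(d$x[!hold, ], d$y[!hold])
  M <- selection_budget(ranking)$M
  res <- assemble_candidates(d$x[!hold, ], d$y[!hold],
                             d$x[hold, ], d$y[hold],
                             M = M, ranking = ranking, seed = 3)
  expect_length(res$filter, M)
  expect_length(res$random, M)
  expect_length(res$pseudo_random, M)
  expect_lte(length(res$wrapper), M)
  expect_equal(res$filter, sort(ranking$order[seq_len(M)]))
  expect_length(intersect(res$pseudo_random,
                          union(res$filter, res$wrapper)), 0L)
  expect_equal(res$final_accuracy, max(res$holdout_accuracy, na.rm = TRUE))
  expect_true(res$final_type %in% names(res$holdout_accuracy))
  expect_true(all(res$holdout_accuracy >= 0 & res$holdout_accuracy <= 1,
                  na.rm = TRUE))
})

test_that("wrapper selection is deterministic given its seed", {
  d <- planted_diffs(n = 64, p = 15, k = 2, effect = 1, seed = 35)
  ranking <- rank_features_kw(d$x, d$y)
  s1 <- wrapper_selection(d$x, d$y, 4, ranking, seed = 11)
  s2 <- wrapper_selection(d$x, d$y, 4, ranking, seed = 11)
  expect_identical(s1, s2)
})
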