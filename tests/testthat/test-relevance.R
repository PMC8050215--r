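# Minimal hand-built decoder results for exercising the aggregation rules.
fake_fit <- function(n_features, folds) {
  structure(list(
    fold_results = lapply(folds, function(f) {
      list(final_set = f$set, final_accuracy = f$acc, model = NULL,
           budget_M = length(f$set), final_type = "filter",
           full_accuracy = NA_real_,
           holdout_accuracy = c(filter = f$acc, wrapper = NA,
                                random = NA, pseudo_random = NA))
    }),
    n_features = n_features,
    feature_names = paste0("f", seq_len(n_features))
  ), class = "gaze_decoder")
}

test_that("a single fold splits its above-chance credit evenly", {
  fit <- fake_fit(6, list(list(set = c(2L, 5L), acc = 0.6)))
  w <- feature_weights(fit, chance = 0.5)
  expect_equal(unname(w$weights[c(2, 5)]), c(50, 50))
  expect_equal(sum(w$weights), 100)
  expect_true(all(w$weights[c(1, 3, 4, 6)] == 0))
})

test_that("below-chance folds contribute nothing and all-zero is flagged", {
  fit <- fake_fit(4, list(list(set = 1L, acc = 0.45),
                          list(set = 2L, acc = 0.70)))
  w <- feature_weights(fit, chance = 0.5)
  expect_equal(unname(w$weights), c(0, 100, 0, 0))

  dud <- fake_fit(4, list(list(set = 1L, acc = 0.4)))
  expect_warning(w0 <- feature_weights(dud, chance = 0.5), "zero")
  expect_true(w0$all_zero)
  expect_true(all(w0$weights == 0))
})

test_that("weights of disjoint runs add linearly before normalisation", {
  f1 <- fake_fit(6, list(list(set = 1L, acc = 0.6)))
  f2 <- fake_fit(6, list(list(set = 2L, acc = 0.7)))
  w <- feature_weights(list(f1, f2), chance = 0.5)
  expect_equal(unname(w$weights[1] / w$weights[2]), 0.1 / 0.2)
  expect_equal(sum(w$weights), 100)
})

test_that("HOG heatmaps conserve weight and mask the aperture", {
  spec <- hog_spec(40L)   # 3x3 kept cells of a 5x5 grid
  w <- numeric(spec$n_features)
  w[1:9] <- 100 / 9   # all mass on the first kept cell
  hm <- hog_heatmap(w, spec)
  expect_equal(dim(unclass(hm)), c(5L, 5L))
  expect_equal(sum(hm, na.rm = TRUE), 100)
  expect_equal(sum(!is.na(hm)), 9L)
  expect_equal(sum(hm > 0, na.rm = TRUE), 1L)
  kc <- spec$kept_cells
  expect_equal(unname(hm[kc[1, "row"], kc[1, "col"]]), 100)
  expect_error(hog_heatmap(w[-1], spec), "geometry")
})

test_that("SF/orientation profiles are conserving marginals", {
  b <- fourier_binning()
  w <- numeric(b$n_features)
  hot <- (7 - 1) * 16 + 3   # SF band 7, orientation band 3
  w[hot] <- 100
  pr <- sf_orientation_profiles(w, b)
  expect_equal(sum(pr$sf), 100)
  expect_equal(sum(pr$orientation), 100)
  expect_equal(which(pr$sf > 0), 7L)
  expect_equal(which(pr$orientation > 0), 3L)

  set.seed(61)
  w2 <- runif(b$n_features); w2 <- 100 * w2 / sum(w2)
  pr2 <- sf_orientation_profiles(w2, b)
  expect_equal(sum(pr2$sf), 100)
  expect_equal(sum(pr2$orientation), 100)
  expect_error(sf_orientation_profiles(w2[-1], b), "geometry")
})

test_that("planted informative features earn higher weights than noise", {
  d <- planted_diffs(n = 320, p = 20, k = 3, effect = 1.0, seed = 62)
  fit <- gaze_decoder(d$x, d$y, control = fast_control(), seed = 7)
  w <- feature_weights(fit, chance = 0.5)$weights
  expect_gt(mean(w[d$planted]), mean(w[-d$planted]))
})
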