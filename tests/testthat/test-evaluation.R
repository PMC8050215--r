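test_that("empirical chance is a valid accuracy with matching degrees of freedom", {
  d <- planted_diffs(n = 160, p = 12, k = 0, effect = 0, seed = 51)
  ch1 <- empirical_chance(d$x, d$y, control = fast_control(), seed = 4)
  ch2 <- empirical_chance(d$x, d$y, control = fast_control(), seed = 4)
  expect_equal(ch1$per_fold, ch2$per_fold)
  expect_length(ch1$per_fold, 8L)
  expect_true(all(ch1$per_fold >= 0 & ch1$per_fold <= 1))
  chl <- empirical_chance(d$x, d$y, control = fast_control(), seed = 4,
                          shuffle = "labels")
  expect_true(all(chl$per_fold >= 0 & chl$per_fold <= 1))
})

test_that("a missing class is caught before shuffling", {
  x <- matrix(rnorm(200), 20, 10)
  expect_error(empirical_chance(x, rep(1L, 20)), "class")
})

test_that("bias baseline reproduces a hand-computed worked example", {
  # 10 training trials of the pair angry:happy, 6 choosing angry;
  # 4 test trials, 3 choosing angry -> accuracy 0.75
  set.seed(52)
  chosen <- c(rep("angry", 6), rep("happy", 4),  # fold 1 (training)
              c("angry", "angry", "angry", "happy"))  # fold 2 (test)
  side <- sample(c("left", "right"), 14, replace = TRUE)
  trials <- data.frame(
    left_class = ifelse(side == "left", chosen,
                        ifelse(chosen == "angry", "happy", "angry")),
    right_class = ifelse(side == "right", chosen,
                         ifelse(chosen == "angry", "happy", "angry")),
    chosen_side = side)
  fp <- structure(list(assignment = rep(c(1L, 2L), c(10L, 4L)),
                       n_folds = 2L), class = "fold_plan")
  bb <- bias_baseline(trials, fp)
  row <- bb$fold_table[bb$fold_table$fold == 2, ]
  expect_equal(row$bias, 0.6)
  expect_equal(row$accuracy, 0.75)
})

test_that("a total bias with consistent behaviour predicts perfectly", {
  trials <- data.frame(left_class = rep(c("happy", "sad"), 12),
                       right_class = rep(c("sad", "happy"), 12),
                       chosen_side = rep(c("left", "right"), 12))  # always happy
  fp <- structure(list(assignment = rep(1:2, 12), n_folds = 2L),
                  class = "fold_plan")
  bb <- bias_baseline(trials, fp)
  expect_true(all(bb$fold_table$bias == 1))
  expect_equal(bb$mean_accuracy, 1)
})

test_that("an exact 0.5 bias predicts the canonically earlier expression", {
  trials <- data.frame(
    left_class = rep("angry", 12), right_class = rep("happy", 12),
    chosen_side = rep(c("left", "right"), 6))
  fp <- structure(list(assignment = rep(c(1L, 1L, 2L, 2L), 3), n_folds = 2L),
                  class = "fold_plan")
  bb <- bias_baseline(trials, fp)
  # bias exactly 0.5 -> predict "angry"; test folds also split 50/50
  expect_true(all(bb$fold_table$bias == 0.5))
  expect_equal(bb$mean_accuracy, 0.5)
})

test_that("same-expression trials are excluded from the bias analysis", {
  trials <- data.frame(left_class = "happy", right_class = "happy",
                       chosen_side = "left")
  fp <- structure(list(assignment = 1L, n_folds = 1L), class = "fold_plan")
  expect_error(bias_baseline(trials, fp), "differing")
})

test_that("emotion decoding transfers exactly the per-fold feature counts", {
  imgs <- shared_faces()
  X <- feature_matrix(imgs, "fourier")
  cls <- vapply(imgs, `[[`, character(1), "expression")
  free <- emotion_decoding(X, cls, mode = "free",
                           control = fast_control(), seed = 5)
  expect_true(all(free$fold_accuracy >= 0 & free$fold_accuracy <= 1))
  expect_gt(free$accuracy, 0.25)   # classes are strongly separable

  w <- numeric(ncol(X)); w[1:40] <- 1
  tr <- emotion_decoding(X, cls, mode = "transferred",
                         reference = free, weights = w,
                         control = fast_control())
  expect_identical(tr$n_features_per_fold, free$n_features_per_fold)
  expect_identical(tr$folds$assignment, free$folds$assignment)

  expect_error(emotion_decoding(X, cls, mode = "transferred", weights = w),
               "reference")
  expect_error(emotion_decoding(X, cls, mode = "transferred",
                                reference = free), "weights")
})
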