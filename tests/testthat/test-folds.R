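test_that("folds are exactly stratified when counts divide evenly", {
  y <- rep(c(0, 1), each = 40)
  fp <- make_folds(y, n_folds = 8, seed = 1)
  tab <- table(fold = fp$assignment, class = y)
  expect_true(all(tab == 5L))
})

test_that("fold sizes differ by at most one per class otherwise", {
  set.seed(4)
  y <- c(rep(0, 43), rep(1, 38))[sample(81)]
  fp <- make_folds(y, n_folds = 8, seed = 2)
  tab <- table(fp$assignment, y)
  expect_true(all(apply(tab, 2, function(v) diff(range(v))) <= 1))
})

test_that("each fold draws trials from throughout the session", {
  y <- rep(c(0, 1), 60)
  fp <- make_folds(y, n_folds = 8, seed = 3)
  for (cl in c(0, 1)) {
    f <- fp$assignment[y == cl]       # per-class temporal order
    blocks <- split(f, (seq_along(f) - 1) %/% 8)
    full <- blocks[lengths(blocks) == 8]
    expect_true(all(vapply(full, function(b) length(unique(b)) == 8L,
                           logical(1))))
  }
})

test_that("degenerate label vectors are rejected and seeds reproduce", {
  expect_error(make_folds(rep(1, 50), n_folds = 8), "at least")
  expect_error(make_folds(c(rep(0, 5), rep(1, 40)), n_folds = 8), "at least")
  y <- rep(c(0, 1), 50)
  expect_identical(make_folds(y, seed = 9), make_folds(y, seed = 9))
  expect_false(identical(make_folds(y, seed = 9)$assignment,
                         make_folds(y, seed = 10)$assignment))
})

test_that("balanced splits have equal class counts at about half the pool", {
  y <- rep(c(0, 1), each = 40)
  sp <- balanced_split(y, seed = 1)
  expect_length(sp$train, 40L)
  expect_equal(as.vector(table(y[sp$train])), c(20L, 20L))
  expect_length(sp$validation, 40L)
  expect_setequal(c(sp$train, sp$validation), seq_along(y))
})

test_that("the minority class caps the balanced training count", {
  y <- c(rep(0, 40), rep(1, 10))
  sp <- balanced_split(y, seed = 2)
  # floor(0.5 * 50 / 2) = 12 per class, capped at the 10 minority trials
  expect_equal(as.vector(table(y[sp$train])), c(10L, 10L))
  expect_length(sp$validation, 30L)
})

test_that("splits needing an absent class or empty validation fail", {
  expect_error(balanced_split(rep(1, 20)), "classes")
  expect_error(balanced_split(c(0, 1)), "small|empty")
})
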