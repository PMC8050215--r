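test_that("the generator produces 4 x n_identities masked faces deterministically", {
  a <- generate_faces(n_identities = 3, seed = 5)
  b <- generate_faces(n_identities = 3, seed = 5)
  c <- generate_faces(n_identities = 3, seed = 6)
  expect_length(a, 12L)
  expect_identical(a, b)
  expect_false(identical(a[[1]]$pixels, c[[1]]$pixels))
  # metadata layout is seed-independent
  expect_identical(lapply(a, function(im) im[c("identity", "expression")]),
                   lapply(c, function(im) im[c("identity", "expression")]))
  expect_equal(vapply(a[1:4], `[[`, character(1), "expression"),
               c("happy", "angry", "sad", "neutral"))
  px <- a[[1]]$pixels
  expect_true(all(px >= 0 & px <= 1))
})

test_that("zero identity jitter makes within-class images pixel-identical", {
  imgs <- generate_faces(n_identities = 3, identity_jitter = 0, seed = 1)
  expect_identical(imgs[[1]]$pixels, imgs[[5]]$pixels)
  expect_identical(imgs[[1]]$pixels, imgs[[9]]$pixels)
  expect_false(identical(imgs[[1]]$pixels, imgs[[2]]$pixels))
})

test_that("39 identities give the full 156-image set", {
  imgs <- shared_faces()   # 10 identities cached for speed
  expect_length(generate_faces(n_identities = 2, seed = 1), 8L)
  expect_length(imgs, 40L)
})

test_that("the trial table is counterbalanced with distinct identities", {
  imgs <- shared_faces()
  tr <- generate_trials(imgs, reps = 6, catch_reps = 2, seed = 7)
  main <- tr[tr$soa_ms == 0, ]
  expect_equal(nrow(main), 16 * 6)
  expect_equal(nrow(tr) - nrow(main), 16 * 2)
  cond <- table(main$left_class, main$right_class)
  expect_true(all(cond == 6))
  ident <- vapply(imgs, `[[`, numeric(1), "identity")
  expect_true(all(ident[tr$left_id] != ident[tr$right_id]))
  expect_true(all(tr$soa_ms[tr$soa_ms != 0] >= 34 &
                    tr$soa_ms[tr$soa_ms != 0] <= 134))
  # left/right placement of every unordered class pair is balanced
  expect_equal(unname(cond["happy", "angry"]), unname(cond["angry", "happy"]))
  expect_identical(generate_trials(imgs, reps = 6, catch_reps = 2, seed = 7),
                   generate_trials(imgs, reps = 6, catch_reps = 2, seed = 7))
})

test_that("zero catch repeats yield only simultaneous trials", {
  tr <- generate_trials(shared_faces(), reps = 2, catch_reps = 0, seed = 1)
  expect_true(all(tr$soa_ms == 0))
})

test_that("choice simulation honours the probit limits", {
  set.seed(8)
  x <- matrix(rnorm(4000), 400, 10)
  m_noise <- choice_model(1:3, c(1, -1, 2), noise_sd = Inf)
  s <- simulate_choices(x, m_noise, seed = 1)
  expect_true(all(s$p_right == 0.5))
  expect_gt(mean(s$labels), 0.40)
  expect_lt(mean(s$labels), 0.60)

  m_det <- choice_model(1:3, c(1, -1, 2), noise_sd = 0)
  s2 <- simulate_choices(x, m_det, seed = 1)
  dv <- x[, 1] - x[, 2] + 2 * x[, 3]
  expect_equal(s2$labels, as.integer(dv > 0))

  # planted weight on one feature with positive diffs forces all-right
  xp <- matrix(abs(rnorm(100)), 100, 1)
  s3 <- simulate_choices(xp, choice_model(1L, 1, noise_sd = 0), seed = 2)
  expect_true(all(s3$labels == 1L))
})

test_that("lateral bias and lapse shift and shrink the probabilities", {
  x <- matrix(0, 50, 2)
  mb <- choice_model(1:2, c(1, 1), noise_sd = 1, lateral_bias = 0.5)
  expect_true(all(simulate_choices(x, mb)$p_right < 0.5))
  ml <- choice_model(1:2, c(1, 1), noise_sd = 0, lapse_rate = 0.2)
  s <- simulate_choices(x, ml)
  expect_true(all(s$p_right == 0.5))  # dv = 0: guess, lapse symmetric
})

test_that("model validation catches bad ground truth", {
  expect_error(choice_model(integer(0), numeric(0)), "length")
  expect_error(choice_model(1:2, 1), "length")
  expect_error(choice_model(1, 1, noise_sd = -1), "noise_sd")
  m <- choice_model(5L, 2)
  expect_identical(planted_truth(m), 5L)
  expect_identical(planted_truth(m), planted_truth(m))
  expect_error(simulate_choices(matrix(0, 3, 2), m), "out of range")
})

test_that("condition-orthogonal choices remove class-pair bias in expectation", {
  imgs <- shared_faces()
  feats <- feature_matrix(imgs, "fourier")
  tr <- generate_trials(imgs, reps = 24, catch_reps = 0, seed = 3)
  td <- trial_difference_matrix(tr, feats)
  m <- choice_model(1:10, rnorm(10), noise_sd = 0)
  cond <- interaction(tr$left_class, tr$right_class)
  s <- simulate_choices(td$x, m, seed = 4, conditions = cond,
                        condition_orthogonal = TRUE)
  per_cond <- tapply(s$p_right, cond, mean)
  # residualised readout: no condition's latent choice rate strays far
  expect_true(all(abs(per_cond - 0.5) < 0.2))
})

test_that("planted truths are decorrelated, scale-aware and deterministic", {
  set.seed(71)
  # heterogeneous scales and a built-in correlated pair
  x <- matrix(rnorm(400 * 12), 400, 12) %*% diag(c(1e3, rep(1, 10), 1e-3))
  x <- cbind(x, x[, 2] * 0.95 + rnorm(400, sd = 0.31))
  m1 <- planted_choice_model(x, k = 4, seed = 3)
  m2 <- planted_choice_model(x, k = 4, seed = 3)
  expect_identical(m1$informative_features, m2$informative_features)
  expect_equal(m1$readout_weights, m2$readout_weights)
  expect_length(m1$informative_features, 4L)
  cc <- stats::cor(x[, m1$informative_features])
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.5)
  # every planted feature carries comparable marginal signal per sd
  dv <- x[, m1$informative_features] %*% m1$readout_weights
  marg <- abs(stats::cor(x[, m1$informative_features], dv))
  expect_gt(min(marg) / max(marg), 0.2)
  expect_error(planted_choice_model(x, k = 50), "features")
})

test_that("stronger planted signals decode no worse than weak ones", {
  weak <- planted_diffs(n = 240, p = 16, k = 3, effect = 0.15, seed = 37)
  strong <- planted_diffs(n = 240, p = 16, k = 3, effect = 2.5, seed = 37)
  ctl <- fast_control()
  acc <- vapply(list(weak, strong), function(dd) {
    gaze_decoder(dd$x, dd$y, control = ctl, seed = 2)$accuracy
  }, numeric(1))
  expect_gte(acc[2], acc[1])
})
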