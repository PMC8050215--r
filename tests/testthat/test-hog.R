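test_that("aperture mask reproduces the printed cell counts and agrees with pixel membership", {
  # independent check: a cell is kept iff every one of its pixels (as unit
  # squares) lies inside the closed disc
  pixel_oracle <- function(width, cell) {
    R2 <- (width / 2)^2
    n <- width / cell
    keep <- matrix(FALSE, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      px <- ((i - 1) * cell + 1):(i * cell)
      py <- ((j - 1) * cell + 1):(j * cell)
      corners_ok <- TRUE
      for (a in px) for (b in py) {
        d2 <- max((c(a - 1, a) - width / 2)^2) +
              max((c(b - 1, b) - width / 2)^2)
        if (d2 > R2) { corners_ok <- FALSE; break }
      }
      keep[i, j] <- corners_ok
    }
    which(t(keep), arr.ind = TRUE)[, c(2, 1)]  # row-major (row, col)
  }
  expected_n <- c(`10` = 276L, `20` = 60L, `40` = 9L)
  for (cell in c(10L, 20L, 40L)) {
    kc <- aperture_cell_mask(200L, cell)
    expect_equal(nrow(kc), unname(expected_n[as.character(cell)]))
    orc <- pixel_oracle(200L, cell)
    expect_equal(unname(kc[order(kc[, 1], kc[, 2]), ]),
                 unname(orc[order(orc[, 1], orc[, 2]), ]))
  }
})

test_that("an aperture wider than the grid diagonal keeps every cell", {
  kc <- aperture_cell_mask(200L, 20L,
                           aperture_diameter_px = 200 * sqrt(2) + 1)
  expect_equal(nrow(kc), 100L)
})

test_that("canonical HOG feature counts are 2484 / 540 / 81", {
  img <- matrix(runif(200 * 200), 200, 200)
  expect_length(hog_features(img, hog_spec(10L)), 2484L)
  expect_length(hog_features(img, hog_spec(20L)), 540L)
  expect_length(hog_features(img, hog_spec(40L)), 81L)
  # total grid before masking: 20 x 20 x 9 = 3600, so 1116 are excluded
  expect_equal(400L * 9L - 2484L, 1116L)
})

test_that("a constant image yields all-zero histograms", {
  f <- hog_features(matrix(0.6, 200, 200), hog_spec(20L))
  expect_true(all(f == 0))
})

test_that("a pure luminance ramp votes only into the 0-degree bin", {
  n <- 200
  img <- matrix(seq(0, 1, length.out = n), n, n, byrow = TRUE)
  f <- hog_features(img, hog_spec(40L))
  m <- matrix(f, nrow = 9)   # bins x cells
  active <- colSums(m) > 0
  expect_true(any(active))
  expect_true(all(m[2:9, active] == 0))
  # per-cell L2 normalisation puts each active histogram on the unit sphere
  expect_equal(unname(m[1, active]), rep(1, sum(active)), tolerance = 1e-4)
})

test_that("geometry violations are rejected", {
  expect_error(aperture_cell_mask(200L, 30L), "divide")
  expect_error(hog_features(matrix(0, 100, 100), hog_spec(10L)), "size")
})
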