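# Shared fixtures, built in code.

# Horizontal-axis sinusoidal grating: `cpi` cycles per image along x.
make_grating <- function(n, cpi, phase = 0) {
  x <- matrix(seq_len(n) - 1, n, n, byrow = TRUE)
  sin(2 * pi * cpi * x / n + phase)
}

# Independent brute-force oracle for the binned Fourier features: explicit
# double loop over every DFT coefficient, conjugate pairs weighted 1/2,
# self-conjugate Nyquist points weighted 1, DC and super-Nyquist excluded.
oracle_fourier <- function(img, binning) {
  n <- nrow(img)
  Fm <- Mod(stats::fft(img))
  se <- binning$sf_band_edges
  oe <- binning$orientation_band_edges
  nori <- binning$n_orientation_bands
  out <- numeric(binning$n_features)
  for (u in 0:(n - 1)) {
    for (v in 0:(n - 1)) {
      fy <- if (u <= n / 2) u else u - n
      fx <- if (v <= n / 2) v else v - n
      r <- sqrt(fx^2 + fy^2)
      if (r == 0 || r > n / 2) next
      w <- if (fx %in% c(0, n / 2) && fy %in% c(0, n / 2)) 1 else 0.5
      ang <- (atan2(fy, fx) * 180 / pi) %% 180
      sfb <- NA
      for (b in seq_len(length(se) - 1)) {
        if (r > se[b] && r <= se[b + 1]) { sfb <- b; break }
      }
      orb <- NA
      for (b in seq_len(length(oe) - 1)) {
        if (ang >= oe[b] && ang < oe[b + 1]) { orb <- b; break }
      }
      k <- (sfb - 1) * nori + orb
      out[k] <- out[k] + w * Fm[u + 1, v + 1]
    }
  }
  out
}

# Gaussian trial-difference matrix with k planted informative columns whose
# sign separates the classes at the given effect size.
planted_diffs <- function(n, p, k, effect, seed) {
  withr_seed <- function(s, code) gazeselect:::with_seed(s, code)
  withr_seed(seed, {
    x <- matrix(rnorm(n * p), n, p)
    y <- rbinom(n, 1, 0.5)
    sgn <- 2 * y - 1
    for (j in seq_len(k)) x[, j] <- x[, j] + effect * sgn
    list(x = x, y = y, planted = seq_len(k))
  })
}

# Small cached face set shared across test files (rendering is the slow
# part; features are recomputed per geometry as needed).
shared_faces <- local({
  cache <- NULL
  function(n_identities = 10, seed = 42) {
    if (is.null(cache)) {
      cache <<- generate_faces(n_identities = n_identities, seed = seed)
    }
    cache
  }
})

fast_control <- function(...) {
  decoder_control(subsample_size = 10, compute_full = FALSE, ...)
}

# Full-size study fixtures: the 39-identity stimulus set, its canonical
# Fourier features, the 896-trial counterbalanced main design, and (built
# on demand) the 10-px HOG difference matrix. Rendered once per test run.
shared_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      images <- generate_faces(n_identities = 39, seed = 1001)
      features <- feature_matrix(images, "fourier")
      trials <- generate_trials(images, reps = 56, catch_reps = 0,
                                seed = 1002)
      x <- features[trials$right_id, ] - features[trials$left_id, ]
      rownames(x) <- NULL
      cache <<- list(images = images, features = features,
                     trials = trials, x = x)
    }
    cache
  }
})

shared_hog_diffs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      st <- shared_study()
      f <- feature_matrix(st$images, "hog", geometry = hog_spec(10L))
      x <- f[st$trials$right_id, ] - f[st$trials$left_id, ]
      rownames(x) <- NULL
      cache <<- x
    }
    cache
  }
})
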