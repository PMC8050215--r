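#' Expression templates for the synthetic face generator
#'
#' Parameter means of the four synthetic "expression" classes.  Faces are
#' parametric grayscale composites (oval head, Gaussian/bar part
#' primitives) rather than photographs; the parameters control the
#' localized oriented contrast structure that distinguishes the classes:
#' brow angle (degrees, positive = inner ends lowered), eye aperture
#' (vertical scale of the eye blobs), mouth curvature (positive = corners
#' raised), mouth-open contrast (brightness of the teeth band) and
#' nasolabial-fold strength (contrast of the oblique cheek folds).
#'
#' @param means Optional 4-row data frame overriding the built-in class
#'   means (rows named happy/angry/sad/neutral, columns `brow_angle`,
#'   `eye_aperture`, `mouth_curvature`, `mouth_open`, `nasolabial`).
#' @return Object of class `"expression_templates"`.
#' @export
expression_templates <- function(means = NULL) {
  if (is.null(means)) {
    means <- data.frame(
      brow_angle     = c(happy = -8,  angry = 22, sad = -20, neutral = 0),
      eye_aperture   = c(happy = 0.9, angry = 0.75, sad = 0.9, neutral = 1.0),
      mouth_curvature = c(happy = 0.30, angry = -0.12, sad = -0.28,
                          neutral = 0.0),
      mouth_open     = c(happy = 0.30, angry = 0.12, sad = 0.0, neutral = 0.0),
      nasolabial     = c(happy = 0.22, angry = 0.12, sad = 0.05,
                         neutral = 0.08)
    )
  }
  stopifnot(nrow(means) == 4L, !anyDuplicated(rownames(means)))
  structure(list(means = means, classes = rownames(means)),
            class = "expression_templates")
}

# canonical identity-level jitter scales (1 sd at identity_jitter = 1)
.identity_jitter_scales <- c(
  brow_angle = 8, eye_aperture = 0.12, mouth_curvature = 0.08,
  mouth_open = 0.06, nasolabial = 0.06,
  eye_dx = 0.02, eye_y = 0.02, mouth_y = 0.02, face_w = 0.03,
  face_h = 0.03, skin = 0.03)

# Smooth 1/f random field (unit variance), drawn from the current RNG
# stream; emulates the skin/hair textural variability of photographic
# faces that the part primitives lack.
smooth_noise_field <- function(n, exponent = 1) {
  noise <- matrix(stats::rnorm(n * n), n, n)
  k <- 0:(n - 1)
  f <- ifelse(k <= n / 2, k, k - n)
  r <- sqrt(outer(f^2, f^2, "+"))
  H <- 1 / (r + 1)^exponent
  H[1, 1] <- 0   # no DC: textures do not shift mean luminance
  field <- Re(stats::fft(stats::fft(noise) * H, inverse = TRUE)) / (n * n)
  field / stats::sd(field)
}

rotated_bar <- function(xx, yy, cx, cy, len, thick, angle_deg) {
  a <- angle_deg * pi / 180
  xr <- (xx - cx) * cos(a) + (yy - cy) * sin(a)
  yr <- -(xx - cx) * sin(a) + (yy - cy) * cos(a)
  exp(-(xr^2 / (2 * len^2) + yr^2 / (2 * thick^2)))
}

draw_face <- function(width_px, pars, texture = NULL,
                      texture_amplitude = 0) {
  s <- seq(-1, 1, length.out = width_px)
  yy <- matrix(s, width_px, width_px)              # rows: top -> bottom
  xx <- matrix(s, width_px, width_px, byrow = TRUE)

  bg <- 0.5
  ell <- (xx / pars[["face_w"]])^2 + (yy / pars[["face_h"]])^2
  img <- bg + (pars[["skin"]] - bg) / (1 + exp((ell - 1) / 0.02))

  ex <- pars[["eye_dx"]]; ey <- pars[["eye_y"]]
  for (sgn in c(-1, 1)) {
    # eyes: dark horizontal blobs whose vertical extent is the aperture
    img <- img - 0.35 * exp(-((xx - sgn * ex)^2 / (2 * 0.07^2) +
                                (yy - ey)^2 /
                                (2 * (0.035 * pars[["eye_aperture"]])^2)))
    # brows: oriented bars above the eyes, mirrored angle
    img <- img - 0.30 * rotated_bar(xx, yy, sgn * ex, ey - 0.13,
                                    0.10, 0.022,
                                    sgn * pars[["brow_angle"]])
    # nasolabial folds: oblique bars between nose and mouth corners
    img <- img - pars[["nasolabial"]] *
      rotated_bar(xx, yy, sgn * 0.20, 0.26, 0.09, 0.02, sgn * 55)
  }
  # mouth: dark curved line, corners raised when curvature > 0
  my <- pars[["mouth_y"]]
  d <- yy - (my - pars[["mouth_curvature"]] * (xx / 0.35)^2 * 0.1)
  img <- img - 0.30 * exp(-(d^2 / (2 * 0.018^2))) * exp(-xx^2 / (2 * 0.16^2))
  # teeth: bright band just above the mouth line
  if (pars[["mouth_open"]] > 0) {
    img <- img + pars[["mouth_open"]] *
      exp(-(xx^2 / (2 * 0.10^2) + (yy - my + 0.035)^2 / (2 * 0.022^2)))
  }
  if (!is.null(texture) && texture_amplitude > 0) {
    img <- img + texture_amplitude * texture
  }
  pmin(pmax(img, 0), 1)
}

#' Generate synthetic face stimuli
#'
#' Deterministically (given `seed`) renders `4 * n_identities` square
#' grayscale faces: four expression classes sharing class parameter means,
#' identities differing by parameter jitter that is consistent across a
#' given identity's four expressions.  All content lies inside the
#' circular aperture; pixels outside it equal the mean in-aperture
#' intensity.
#'
#' @param templates An [expression_templates()] object.
#' @param n_identities Number of identities (>= 2). Default 39, giving 156
#'   images.
#' @param width_px Image width. Default 200.
#' @param identity_jitter Scale of identity-level parameter jitter (0 makes
#'   within-class images pixel-identical). Default 1.
#' @param texture_amplitude Luminance sd of each identity's smooth 1/f
#'   texture field (shared across that identity's four expressions and
#'   scaled by `identity_jitter`); emulates the high-dimensional textural
#'   variability of photographic faces. Default 0.05.
#' @param seed Integer seed.
#' @return List of `4 * n_identities` [stimulus_image()] objects, ordered
#'   identity-major (identity 1's four expressions first).  Image index of
#'   identity i, class c (in template order) is `(i - 1) * 4 + c`.
#' @export
generate_faces <- function(templates = expression_templates(),
                           n_identities = 39L, width_px = 200L,
                           identity_jitter = 1, texture_amplitude = 0.05,
                           seed = 1L) {
  stopifnot(inherits(templates, "expression_templates"),
            n_identities >= 2L, identity_jitter >= 0)
  classes <- templates$classes
  geom_base <- c(eye_dx = 0.33, eye_y = -0.22, mouth_y = 0.38,
                 face_w = 0.80, face_h = 0.95, skin = 0.62)
  sc <- .identity_jitter_scales * identity_jitter
  images <- vector("list", 4L * n_identities)
  with_seed(seed, {
    for (i in seq_len(n_identities)) {
      offs <- stats::rnorm(length(sc), 0, sc)
      names(offs) <- names(sc)
      tex <- smooth_noise_field(width_px)
      tex_amp <- texture_amplitude * identity_jitter
      for (c in seq_along(classes)) {
        cl <- classes[c]
        pars <- c(unlist(templates$means[cl, ]), geom_base)
        jit_names <- intersect(names(pars), names(offs))
        pars[jit_names] <- pars[jit_names] + offs[jit_names]
        pars[["eye_aperture"]] <- max(pars[["eye_aperture"]], 0.2)
        pars[["nasolabial"]] <- max(pars[["nasolabial"]], 0)
        pars[["mouth_open"]] <- max(pars[["mouth_open"]], 0)
        images[[(i - 1L) * 4L + c]] <- stimulus_image(
          draw_face(width_px, pars, texture = tex,
                    texture_amplitude = tex_amp),
          identity = i, expression = cl)
      }
    }
  })
  images
}

#' Generate a counterbalanced two-face trial table
#'
#' All ordered pairings of the four expression classes (16 conditions) are
#' presented `reps` times with simultaneous onset (`soa_ms = 0`), so every
#' unordered expression pair is exactly counterbalanced for side.  Catch
#' trials add `catch_reps` presentations per condition with a temporal
#' onset offset drawn from `soa_set`.  Identities always differ within a
#' trial; trial order is shuffled so every condition occurs throughout the
#' session.
#'
#' @param images Image list from [generate_faces()] (supplies identities
#'   and classes).
#' @param reps Repeats per condition for main trials. Default 56 (896 main
#'   trials).
#' @param catch_reps Repeats per condition for catch trials. Default 14
#'   (224 catch trials, 1120 total).
#' @param soa_set Candidate onset offsets (ms) for catch trials. Default 7
#'   levels evenly spanning 34-134 ms.
#' @param seed Integer seed.
#' @return Data frame with columns `trial_id`, `left_id`, `right_id` (image
#'   indices), `left_class`, `right_class`, `soa_ms`, and `chosen_side`
#'   (`NA`, to be filled by [simulate_choices()] or real data).
#' @export
generate_trials <- function(images, reps = 56L, catch_reps = 14L,
                            soa_set = round(seq(34, 134, length.out = 7)),
                            seed = 1L) {
  ident <- vapply(images, `[[`, numeric(1), "identity")
  cls <- vapply(images, `[[`, character(1), "expression")
  classes <- unique(cls)
  n_id <- length(unique(ident))
  if (n_id < 2L) stop("need at least two identities", call. = FALSE)
  by_class <- split(seq_along(images), cls)

  make_block <- function(n_reps, soa) {
    rows <- list()
    for (lc in classes) for (rc in classes) {
      li <- sample(by_class[[lc]], n_reps, replace = TRUE)
      ri <- sample(by_class[[rc]], n_reps, replace = TRUE)
      clash <- ident[li] == ident[ri]
      while (any(clash)) {
        ri[clash] <- sample(by_class[[rc]], sum(clash), replace = TRUE)
        clash <- ident[li] == ident[ri]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        left_id = li, right_id = ri, left_class = lc, right_class = rc,
        soa_ms = if (soa) sample(soa_set, n_reps, replace = TRUE)
                 else rep(0L, n_reps),
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  }

  with_seed(seed, {
    main <- make_block(reps, soa = FALSE)
    trials <- if (catch_reps > 0L) {
      rbind(main, make_block(catch_reps, soa = TRUE))
    } else main
    trials <- trials[sample(nrow(trials)), ]
  })
  rownames(trials) <- NULL
  trials$trial_id <- seq_len(nrow(trials))
  trials$chosen_side <- NA_character_
  trials[, c("trial_id", "left_id", "right_id", "left_class",
             "right_class", "soa_ms", "chosen_side")]
}

#' Sparse linear choice model
#'
#' Ground-truth readout generating the synthetic choice behaviour: a sparse
#' linear combination of informative feature differences passed through a
#' probit link, with lateral bias and lapses.
#' `P(choose right) = (1 - lapse) * pnorm((w . d - bias) / noise_sd) +
#' lapse / 2`, where `d` is the informative part of the right-minus-left
#' difference vector.
#'
#' @param informative_features Integer index set (size k >= 1) into the
#'   feature space.
#' @param readout_weights Real weights over the informative features.
#' @param noise_sd Decision noise (>= 0; 0 gives a deterministic readout,
#'   `Inf` pure guessing).
#' @param lateral_bias Decision-variable offset; positive values shift
#'   choices toward the left image.
#' @param lapse_rate Probability of a uniformly random choice, in \[0, 1\].
#' @return Object of class `"choice_model"`.
#' @export
choice_model <- function(informative_features, readout_weights,
                         noise_sd = 1, lateral_bias = 0, lapse_rate = 0) {
  informative_features <- as.integer(informative_features)
  stopifnot(length(informative_features) >= 1L,
            length(readout_weights) == length(informative_features),
            noise_sd >= 0, lapse_rate >= 0, lapse_rate <= 1)
  structure(list(informative_features = informative_features,
                 readout_weights = as.numeric(readout_weights),
                 noise_sd = noise_sd, lateral_bias = lateral_bias,
                 lapse_rate = lapse_rate),
            class = "choice_model")
}

#' @export
print.choice_model <- function(x, ...) {
  cat(sprintf(
    "Sparse linear choice model: k = %d informative features, noise sd %g, bias %g, lapse %g\n",
    length(x$informative_features), x$noise_sd, x$lateral_bias,
    x$lapse_rate))
  invisible(x)
}

#' Ground-truth informative feature set
#'
#' @param model A [choice_model()].
#' @return Integer index set of the planted informative features, for
#'   recovery scoring.
#' @export
planted_truth <- function(model) {
  stopifnot(inherits(model, "choice_model"))
  model$informative_features
}

#' Simulate choices from feature differences
#'
#' Computes the per-trial probability of choosing the right image under a
#' [choice_model()] and samples the 0/1 labels.  With
#' `condition_orthogonal = TRUE` the informative feature differences are
#' residualised against the per-condition (expression-pair) means before
#' the readout, so the simulated choices are feature-driven but carry no
#' emotion-content bias.
#'
#' @param feature_diffs Trial-by-feature matrix of right-minus-left
#'   differences.
#' @param model A [choice_model()].
#' @param seed Integer seed for label sampling.
#' @param conditions Optional per-trial condition factor (e.g.
#'   `interaction(left_class, right_class)`); required when
#'   `condition_orthogonal = TRUE`.
#' @param condition_orthogonal Remove condition means from the informative
#'   differences before the readout. Default `FALSE`.
#' @return List with `labels` (0/1, 1 = right chosen), `p_right` (latent
#'   probabilities) and `decision` (latent decision variable).
#' @export
simulate_choices <- function(feature_diffs, model, seed = 1L,
                             conditions = NULL,
                             condition_orthogonal = FALSE) {
  stop_if_not_matrix(feature_diffs, "feature_diffs")
  stopifnot(inherits(model, "choice_model"))
  if (max(model$informative_features) > ncol(feature_diffs)) {
    stop("informative feature index out of range", call. = FALSE)
  }
  d <- feature_diffs[, model$informative_features, drop = FALSE]
  if (condition_orthogonal) {
    if (is.null(conditions)) {
      stop("condition_orthogonal needs `conditions`", call. = FALSE)
    }
    conditions <- as.factor(conditions)
    for (lev in levels(conditions)) {
      i <- conditions == lev
      d[i, ] <- sweep(d[i, , drop = FALSE], 2,
                      colMeans(d[i, , drop = FALSE]))
    }
  }
  dv <- as.numeric(d %*% model$readout_weights) - model$lateral_bias
  p <- if (model$noise_sd == 0) {
    (dv > 0) + 0.5 * (dv == 0)
  } else {
    stats::pnorm(dv / model$noise_sd)
  }
  p <- (1 - model$lapse_rate) * p + model$lapse_rate / 2
  labels <- with_seed(seed, stats::rbinom(length(p), 1L, p))
  list(labels = as.integer(labels), p_right = p, decision = dv)
}

#' Plant a sparse ground-truth readout in a feature space
#'
#' Draws a [choice_model()] with `k` informative features sampled from the
#' non-degenerate columns of `feature_diffs` and weights of random sign
#' whose magnitudes are expressed per standard deviation of each chosen
#' column.  Scaling by the realised column sd makes every planted feature
#' carry signal of comparable strength regardless of the features' raw
#' units (Fourier band magnitudes span orders of magnitude), so "k
#' informative features" genuinely means k; magnitudes are drawn uniformly
#' from `weight_range` so none is negligible.
#'
#' Identifiability is engineered, because naive planting fails silently
#' in image-feature spaces: (a) the k features are mutually weakly
#' correlated (pairwise |r| below `max_cor`), since near-duplicates with
#' random signs cancel and collapse a nominal k-feature truth onto fewer
#' effective channels; (b) within the planted set the weights solve
#' `S w = c`, where `S` is the planted columns' covariance and `c` the
#' target marginal covariances (random sign, magnitude from
#' `weight_range` per sd), so every planted feature has an
#' equal-magnitude marginal relationship with the decision variable; and
#' (c) draws are rejected until the correlation structure inflates the
#' decision-variable sd by at most `max_inflation` over the orthogonal
#' case — an ill-conditioned planted block would otherwise dilute every
#' feature's marginal signal below the noise floor of the surrounding
#' thousands of features.  The default magnitudes (1 to 1.5 per sd) keep
#' each feature individually detectable by a rank statistic at the
#' study's trial counts.
#'
#' @param feature_diffs Trial-by-feature difference matrix the model will
#'   act on.
#' @param k Number of informative features. Default 10.
#' @param weight_range Magnitude range (per sd) of the target marginal
#'   covariances. Default c(1, 1.5).
#' @param max_cor Maximum pairwise correlation magnitude among the planted
#'   features (escalated by 25% steps if no such set exists). Default 0.3.
#' @param max_inflation Maximum allowed ratio of the decision-variable sd
#'   to its value under an orthogonal planted block. Default 1.25.
#' @param seed Integer seed.
#' @return A [choice_model()] with `noise_sd = 1`; calibrate with
#'   [calibrate_noise_sd()].
#' @export
planted_choice_model <- function(feature_diffs, k = 10L,
                                 weight_range = c(1, 1.5), max_cor = 0.3,
                                 max_inflation = 1.25, seed = 1L) {
  stop_if_not_matrix(feature_diffs, "feature_diffs")
  sds <- apply(feature_diffs, 2, stats::sd)
  usable <- which(sds > 0)
  if (length(usable) < k) stop("not enough non-degenerate features",
                               call. = FALSE)
  pick_set <- function(thr) {
    perm <- sample(usable)
    sel <- integer(0)
    for (j in perm) {
      if (length(sel) == 0L ||
          all(abs(stats::cor(feature_diffs[, j],
                             feature_diffs[, sel])) < thr)) {
        sel <- c(sel, j)
      }
      if (length(sel) == k) break
    }
    sel
  }
  with_seed(seed, {
    best <- NULL
    best_ratio <- Inf
    thr <- max_cor
    for (attempt in 1:100) {
      sel <- pick_set(thr)
      if (length(sel) < k) {    # space too collinear at this cap: relax
        thr <- thr * 1.25
        if (thr > 1) stop("could not find k mutually decorrelated features",
                          call. = FALSE)
        next
      }
      idx <- sort(sel)
      target <- sample(c(-1, 1), k, replace = TRUE) *
        stats::runif(k, weight_range[1], weight_range[2]) * sds[idx]
      S <- stats::cov(feature_diffs[, idx, drop = FALSE])
      w <- tryCatch(solve(S, target), error = function(e) NULL)
      if (is.null(w)) next
      # sd(dv) relative to the orthogonal-block case
      ratio <- sqrt(sum(w * target)) / sqrt(sum((target / sds[idx])^2))
      if (is.finite(ratio) && ratio < best_ratio) {
        best <- list(idx = idx, w = w)
        best_ratio <- ratio
      }
      if (best_ratio <= max_inflation) break
    }
    if (is.null(best)) stop("could not construct a planted model",
                            call. = FALSE)
    choice_model(best$idx, best$w)
  })
}

#' Calibrate decision noise to a target latent accuracy
#'
#' Chooses `noise_sd` so that the model's latent (Bayes-optimal) accuracy
#' `mean(pnorm(|w . d| / noise_sd))` on the given difference matrix equals
#' `target` (no bias, no lapses).  Used to plant signals of a stated
#' discriminability.
#'
#' @param feature_diffs Trial-by-feature difference matrix.
#' @param model A [choice_model()] (its `noise_sd` is ignored).
#' @param target Target latent accuracy in (0.5, 1). Default 0.70.
#' @return The calibrated noise sd (numeric scalar).
#' @export
calibrate_noise_sd <- function(feature_diffs, model, target = 0.70) {
  stopifnot(target > 0.5, target < 1)
  d <- feature_diffs[, model$informative_features, drop = FALSE]
  dv <- abs(as.numeric(d %*% model$readout_weights))
  if (all(dv == 0)) stop("degenerate decision variable", call. = FALSE)
  f <- function(lsd) mean(stats::pnorm(dv / 10^lsd)) - target
  10^stats::uniroot(f, c(-8, 8))$root
}

#' One-call synthetic experiment
#'
#' Convenience wrapper tying the generator together: renders faces,
#' extracts features, builds the counterbalanced trial table, and simulates
#' choices for the main (simultaneous-onset) trials.
#'
#' @param n_identities Identities. Default 39.
#' @param reps,catch_reps Per-condition repeats. Defaults 56 / 14.
#' @param kind Feature kind for the decoding matrix (`"fourier"` or
#'   `"hog"`).
#' @param geometry Optional feature geometry (defaults canonical).
#' @param model A [choice_model()] on that feature space, or `NULL` for a
#'   pure-guessing observer.
#' @param target_bayes If not `NULL`, calibrate the model's noise to this
#'   latent accuracy on the realised main-trial differences (see
#'   [calibrate_noise_sd()]).
#' @param identity_jitter Identity jitter scale. Default 1.
#' @param condition_orthogonal Passed to [simulate_choices()].
#' @param seed Integer seed controlling faces, trials and choices.
#' @return List with `images`, `features` (per-image matrix), `trials`
#'   (all trials; `chosen_side` filled for main trials), `x`/`y` (main
#'   trial difference matrix and labels), `main` (row filter used), and
#'   `model` (with calibrated noise if requested).
#' @export
synthetic_experiment <- function(n_identities = 39L, reps = 56L,
                                 catch_reps = 14L,
                                 kind = c("fourier", "hog"),
                                 geometry = NULL, model = NULL,
                                 target_bayes = NULL, identity_jitter = 1,
                                 condition_orthogonal = FALSE, seed = 1L) {
  kind <- match.arg(kind)
  images <- generate_faces(n_identities = n_identities,
                           identity_jitter = identity_jitter,
                           seed = child_seed(seed, 1L))
  features <- feature_matrix(images, kind = kind, geometry = geometry)
  trials <- generate_trials(images, reps = reps, catch_reps = catch_reps,
                            seed = child_seed(seed, 2L))
  main <- trials$soa_ms == 0L
  x <- features[trials$right_id[main], , drop = FALSE] -
       features[trials$left_id[main], , drop = FALSE]
  rownames(x) <- NULL
  if (is.null(model)) {
    model <- choice_model(1L, 0, noise_sd = Inf)
  }
  if (!is.null(target_bayes)) {
    model$noise_sd <- calibrate_noise_sd(x, model, target_bayes)
  }
  cond <- interaction(trials$left_class[main], trials$right_class[main])
  sim <- simulate_choices(x, model, seed = child_seed(seed, 3L),
                          conditions = cond,
                          condition_orthogonal = condition_orthogonal)
  trials$chosen_side[main] <- ifelse(sim$labels == 1L, "right", "left")
  list(images = images, features = features, trials = trials,
       x = x, y = sim$labels, p_right = sim$p_right, main = main,
       model = model, seed = seed)
}
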