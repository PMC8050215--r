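---
title: "Decoding initial eye movements from low-level image features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding initial eye movements from low-level image features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

When two faces appear simultaneously left and right of fixation and an
observer saccades to whichever they perceive first, what drives the choice?
One account appeals to the emotional content of the expressions (a "happy
superiority" or "angry superiority" effect); another holds that differences
in low-level image statistics — contrast energy at particular spatial
frequencies and orientations, localized edge structure around the mouth,
cheeks and brows — are sufficient to predict the eye movement, and that
emotional-content effects are largely a by-product of those image
differences.

`gazeselect` implements the second account as a testable pipeline: it
extracts two complementary low-level descriptions of each face, forms
right-minus-left difference vectors per trial, and trains a linear decoder
on a *selected subset* of those differences to predict the chosen side.
Decoding accuracy above a properly constructed chance level means the
selected features are behaviourally relevant, and the selection itself
says *which* image properties matter.

## Feature spaces

**Fourier features.** The 2-D FFT magnitude spectrum of a square grayscale
image is partitioned into 24 spatial-frequency bands and 16 orientation
bands and summed per band, giving 384 features describing contrast energy
by scale and orientation while discarding spatial position (phase). The
DC component is excluded, as is everything beyond the cardinal-axis
Nyquist frequency (width/2 cycles per image), and each conjugate pair of
coefficients is counted once. SF bands are equal-width and linear over
(0, Nyquist]; orientation bands are 11.25° wide over [0°, 180°). Nothing
in the band counts forces linear spacing — logarithmic SF bands would be
equally defensible — but equal-width linear bands are the minimal
assumption and the geometry is fully configurable through
`fourier_binning()`.

**HOG features.** The image is divided into non-overlapping square cells
(10, 20 or 40 px on the canonical 200-px image); per cell, gradient
orientations (unsigned, [0°, 180°), centred differences with
edge-replicated borders) are voted into 9 bins with bilinear interpolation
between the two nearest bin centres, weighted by gradient magnitude, and
the 9-bin histogram is L2-normalised per cell (ε = 1e-6, so constant cells
stay zero). There is deliberately *no* block normalisation: the printed
feature counts (2484/540/81 after aperture masking; 3600 before at 10-px
cells) are only consistent with one independent histogram per cell.
Cells not fully contained in the circular aperture carry no stimulus
information and are dropped; full containment of the cell square in the
closed inscribed disc is the unique geometric rule that reproduces all
three published counts, which the test suite verifies against a
brute-force pixel-membership check.

**Canonical width.** Stimuli are analysed at 200 × 200 px. The 20 × 20
cell grid at 10-px cells (3600 = 20·20·9 features) fixes this size;
images supplied at other resolutions are resampled before extraction.

**Trial differences.** Each trial's predictor is the right image's
feature vector minus the left image's, labelled 1 when the right image
received the initial eye movement. The opposite convention merely flips
every weight sign; one convention is fixed and documented in
`trial_difference()`.

## The ensemble feature-selection decoder

`gaze_decoder()` runs, per participant (or synthetic replicate):

1. **Folds.** Eight stratified partitions, each with the two choice
   classes in near-equal proportion and with members drawn from
   throughout the session (within each class, every consecutive block of
   eight trials is dealt across the eight folds by a fresh seeded
   permutation). Seven partitions form the training pool; one is held
   out.
2. **Ranking.** Every feature is scored by its Kruskal–Wallis chi-squared
   (H) statistic across the two classes, with midrank tie correction.
3. **Budget.** The number of features M every candidate may use is the
   smallest count of top-ranked features holding 10% of the total score
   mass — sharply peaked rankings licence smaller models.
4. **Candidates.** Four selections of size M:
   *filter* (the top-M ranked features); *wrapper* (stepwise additive:
   each iteration redraws a class-balanced ~50/50 train/validation split
   of the pool, tests the top-S unselected features by current priority
   together with the running selection in a linear SVM, includes the best
   by validation F1, and updates priorities to the observed F1; when a
   quarter of the budget is reached, each included feature is removed in
   turn and dropped if F1 does not fall); *random* (uniform); and
   *pseudo-random* (uniform over features untouched by filter and
   wrapper — a control for the possibility that the rankings themselves
   are uninformative).
5. **Final model.** Each candidate trains a linear SVM on the full pool
   (standardized by training statistics) and is scored on the held-out
   partition; the best hold-out accuracy wins (ties resolved in the fixed
   order filter > wrapper > random > pseudo-random). An all-features
   model is fitted for comparison.

The validation metric inside the wrapper is the F1 of the
"right-chosen" class because validation sets are not class-balanced; the
hold-out metric is plain accuracy. The SVM is linear with C = 1
throughout — the procedure is a feature-selection device, not a
hyperparameter search, and keeping the classifier fixed keeps the four
candidates comparable.

Free parameters the procedure itself does not pin down were fixed as
follows and are configurable through `decoder_control()`: wrapper
subsample size S = max(10, ⌈0.05·p⌉); one inclusion and one fresh
balanced resplit per iteration; priorities initialised to the ranking's
rank percentile so unevaluated features are explored in score order;
ranking ties broken by lower feature index. With all-constant difference
columns every score is zero and no budget is defined; the fit falls back
to M = 1 so a degenerate input still reports (chance-level) accuracy
rather than failing.

## Empirical chance

The final model is the *maximum* of four hold-out accuracies, so its
expectation exceeds 0.5 even on pure noise. `empirical_chance()` therefore
permutes every feature column independently across trials (preserving
marginals, destroying any feature–label link), re-runs the identical
four-candidate pipeline with the same configuration, and reports the
per-fold maximum. Row-relabeling (`shuffle = "labels"`) is available as an
alternative reading of "shuffling". Comparisons of decoding accuracy
should always be against this estimator, never against 0.5.

## Bias baseline and emotion decoding

`bias_baseline()` asks how far expression-category preferences alone
predict the choices: per fold and unordered expression pair, the training
folds yield the proportion choosing expression A over B, and test trials
of that pair are predicted as the majority expression's side (a bias of
exactly 0.5 predicts the alphabetically earlier expression — a
measure-zero tie rule). If feature-based decoding beats this baseline,
the features carry information beyond category-level preference.

`emotion_decoding()` classifies the four expressions from single-image
features (chance 0.25). In *free* mode the full ensemble selection runs
with a one-vs-one linear SVM (macro-F1 inside the wrapper; one-vs-one is
the standard multi-class reduction for SVMs and the choice is otherwise
unconstrained). In *transferred* mode, each fold instead uses the top-n
features by a behavioural relevance ranking, with n matched exactly to
the free run's per-fold feature count and identical folding — asking
whether the features that predict eye movements are the ones that define
expression category.

## Relevance maps

`feature_weights()` turns runs into per-feature percentages: every fold
credits its final selection with max(0, hold-out accuracy − chance), and
credits are normalised to sum to 100. The credit rule is the minimal
reading of "average performance associated with the selected features";
selection frequency and SVM coefficient magnitude are provided as
alternatives (`method =`), and with multiple runs the weights aggregate
over all folds of all runs before normalisation. `hog_heatmap()` projects
HOG weights to grid cells (summing the 9 orientation bins; out-of-aperture
cells are `NA`), and `sf_orientation_profiles()` gives the SF and
orientation marginals; all three conserve the total weight.

## The synthetic study

No face database ships with the package; `generate_faces()` renders
parametric grayscale composites — an oval head with eye blobs, oriented
brow bars, a curved mouth line with an optional bright "teeth" band, and
oblique nasolabial-fold bars — inside the circular aperture. Four classes
(happy/angry/sad/neutral) differ in brow angle, eye aperture, mouth
curvature, mouth-open contrast and fold strength; identities share a
class's means and differ by parameter jitter that is consistent across
that identity's four images. On top of the part primitives, every
identity carries a smooth 1/f random texture field (luminance sd 0.05,
scaled by the jitter parameter). The texture matters statistically, not
cosmetically: part primitives alone span only a dozen latent dimensions,
which makes every feature space extracted from the faces nearly
rank-deficient and pathologically collinear — nothing like photographs,
and a space in which no sparse ground truth is identifiable. The texture
restores the high-dimensional variability that real stimuli have. The
generator remains fully deterministic under a seed, and still does *not*
emulate photographic skin reflectance, hair, or natural identity
covariation, so passing tests demonstrate the pipeline's correctness and
sensitivity, not human-stimulus effect sizes.

The default design mirrors the study conditions: 39 identities × 4
expressions (156 images), 16 ordered expression pairings × 56 repeats =
896 simultaneous-onset trials, identities always distinct within a trial,
sides exactly counterbalanced. Catch trials (onset offsets of 34–134 ms)
default to 14 repeats per condition, giving 1120 trials in total; the
count is configurable because the published trial arithmetic does not pin
it down uniquely.

Choices come from `choice_model()`: a sparse linear readout of k
informative feature differences through a probit link,
P(right) = (1 − lapse)·Φ((w·d − bias)/σ) + lapse/2. Planted ground
truths are built with `planted_choice_model()`, which (a) samples the k
informative features under a mutual-correlation cap, and (b) solves for
weights giving every planted feature an equal-magnitude marginal
covariance with the decision variable, on the per-standard-deviation
scale. Both steps exist because naive planting fails silently: feature
magnitudes span orders of magnitude (raw-scale weights concentrate all
signal in one or two features) and correlated features with random-sign
weights cancel, either way turning a nominal k = 10 model into an
effectively k ≈ 1 model whose "informative set" is not recoverable even
in principle. σ is usually set via
`calibrate_noise_sd()` so the latent (Bayes-optimal) accuracy on the
realised differences hits a stated target — 0.70 in the validation
studies, a moderate, realistic discriminability. `condition_orthogonal =
TRUE` residualises the informative differences against expression-pair
means first, producing behaviour that is feature-driven yet carries no
emotional-content bias: the construction used to show the dissociation
between feature-based and bias-based prediction.

## Validation design and problem sizes

The test suite validates each stage against independent oracles
(brute-force spectrum summation, first-principles Kruskal–Wallis,
pixel-membership aperture checks, hand-computed bias examples) and then
runs four synthetic studies end to end, all at the full 896-trial scale:
(i) no-signal data over the 384 Fourier features, where the final-model
accuracy distribution over 20 seeds is statistically indistinguishable
from the empirical-chance distribution and both exceed 0.5; (ii) a
planted 10-feature readout at latent accuracy 0.70 in the 2484-feature
HOG space — high-dimensional enough that the all-features model is
genuinely hurt by noise dimensions — where feature selection beats both
empirical chance and the all-features model and recovers planted
features far above the random-inclusion rate; (iii) 20
feature-driven-but-emotion-orthogonal replicates, where feature decoding
beats the bias baseline in at least 75% of replicates; (iv) separable
synthetic classes, where free-selection emotion decoding is far above
0.25 and class-irrelevant transferred features fall below it. The
replicated studies use a reduced wrapper subsample (S = 10) and skip the
all-features reference model where it plays no role in the comparison;
the single-run study uses the full defaults.

## Known limitations

* Synthetic faces are caricatures; effect sizes, feature-noise spectra
  and inter-identity correlation structure of photographic stimuli will
  differ, and human behavioural medians are not reproducible from
  synthetic data.
* The wrapper's subsample size, priority-update rule and
  single-inclusion-per-iteration policy are one reasonable resolution of
  an underdetermined procedure; alternatives (multiple inclusions,
  resplit per candidate) would change selection paths but not the
  construction of the chance control, which always mirrors the chosen
  configuration.
* Column-wise shuffling destroys within-trial coupling between features;
  if that coupling itself inflates selection optimism, the chance level
  is conservative. The label-shuffling alternative preserves coupling.
* All SVMs are linear; interactions between features are only captured
  insofar as the selection includes the features involved.
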