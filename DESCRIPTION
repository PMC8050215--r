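Package: gazeselect
Title: Decoding Initial Eye Movements to Faces from Low-Level Image Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Predicts which of two simultaneously presented face images
    receives the initial eye movement from differences in low-level image
    features.  Provides binned Fourier magnitude-spectrum features and
    aperture-masked histogram-of-oriented-gradients (HOG) features, an
    ensemble feature-selection decoder combining a chi-squared filter
    ranking with an iterative linear-SVM wrapper and random fallbacks,
    empirical chance estimation by feature shuffling, emotion-content
    bias baselines, emotion decoding with transferred features,
    relevance-map aggregation, and a synthetic face-stimulus and choice
    generator with known ground truth for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    png,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
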