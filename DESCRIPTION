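Package: trajentropy
Title: Trajectory Unpredictability via Maximum-Entropy Differential Entropy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the unpredictability of animal locomotion from
    frame-indexed 3-D tracking data. Per-frame displacement vectors are
    normalized into the unit cube and the maximum-entropy continuous
    probability density matching their empirical moments is fitted by
    convex dual optimization with tensor Gauss-Legendre quadrature; the
    differential entropy of that density is the unpredictability metric.
    Includes speed and direction marginal projections of the fitted
    density, a mixed-pool resampling test for entropy differences
    between datasets, Froude-number gait-transition speed predictions,
    open-field (thigmotaxis) scoring, and synthetic trajectory
    generators for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
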