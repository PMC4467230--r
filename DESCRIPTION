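Package: tgmvpa
Title: Time-Resolved Multivariate Decoding with Temporal Generalization
    and Classification Endurance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Time-resolved multivariate pattern analysis (MVPA) of
    MEG/EEG epochs for studies of conscious and unconscious perception.
    Provides per-timepoint linear support-vector decoding with calibrated
    class probabilities, cross-condition generalization (the asymmetry
    test between seen and unseen trials), temporal generalization
    matrices, the Classification Endurance decoder half-life statistic
    and its repeated-measures ANOVA, blindsight chance correction of
    correct-trial decoding, global field power and cluster-based
    permutation statistics for evoked contrasts, an adaptive
    mask-contrast staircase simulator, and a synthetic epoch generator
    that emulates staged location codes so that the whole pipeline is
    testable without recorded data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
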