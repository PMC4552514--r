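Package: eegwcst
Title: EEG Spectral Correlates of Wisconsin Card Sorting Test Performance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying electroencephalographic (EEG) correlates of
    executive function assessed with the Wisconsin Card Sorting Test (WCST).
    Provides WCST trial-log scoring (completed categories, perseverative and
    nonperseverative errors), cohort standardization and performance
    clustering; EEG preprocessing with zero-phase Butterworth filters,
    ICA-based ocular artifact correction, spherical-spline current source
    density, fixed-length epoching and amplitude-based artifact rejection;
    spectral analysis with individualized (alpha-peak-anchored) theta and
    alpha bands, electrode-pool band power and magnitude-squared coherence,
    and baseline correction; and the accompanying statistical designs
    (two-way ANOVA, linear regression, partial correlation). A synthetic
    cohort generator with known ground truth (age-structured spectra,
    calibrated inter-regional coherence, simulated WCST agents, planted
    artifacts) supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    car,
    jsonlite
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
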