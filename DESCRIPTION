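Package: ppirel
Title: Test-Retest Reliability of Psychophysiological Interaction Effects
    in Task fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for assessing the test-retest reliability of
    task-modulated functional coupling measured with psychophysiological
    interaction (PPI) analysis of multi-run, multi-day task fMRI. Provides
    encodings of three emotional face-processing task designs
    (event-related emotion identification, blocked face matching, blocked
    gender classification), canonical double-gamma haemodynamic response
    convolution, a synthetic BOLD study generator with user-set
    between-subject, between-day and between-run variance components (so
    the true intraclass correlation of the coupling coefficient is known
    analytically), per-run PPI general linear models with seed extraction
    and optional deconvolution, group-level statistics (one-sample tests,
    Cohen's d, 2x2 day-by-run repeated-measures ANOVA, accuracy
    correlations, Fisher-z sample-size calculation), and a five-cell
    two-way mixed-effects consistency ICC reliability battery with F-based
    confidence intervals and conventional interpretation bands.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
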