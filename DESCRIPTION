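Package: trialpath
Title: Multi-State Markov Models of Clinical Trial Phase Progression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models drug-development trajectories through clinical trial
    phases (Phase I, II, III, approval, failure) as a continuous-time
    multi-state Markov process observed as panel data.  Provides
    deterministic classification rules turning raw trial records into
    state histories, a maximum-likelihood fitting engine for transition
    intensities with proportional covariate effects (for example,
    biomarker-based patient selection), likelihood-ratio comparison of
    nested models, per-transition hazard ratios with Wald intervals, and
    a synthetic cohort generator for validating every stage of the
    analysis against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    yaml
Config/testthat/edition: 3
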