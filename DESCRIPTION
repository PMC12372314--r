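Package: movieisc
Title: Inter-Subject and Inter-Region Correlation Analysis of Movie-Viewing fMRI Timecourses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for naturalistic movie-viewing fMRI studies of
    social brain networks at the region-of-interest (ROI) level. Implements
    filtered framewise displacement (FDfilt4) motion quantification with
    artifact censoring and subject-level exclusion rules, temporal denoising
    of ROI timecourses (artifact interpolation, Butterworth high-pass,
    z-scoring), inter-region correlation (IRC) within and across the Theory
    of Mind and Pain networks, inter-subject correlation (ISC) to a
    leave-one-out reference-group average and within/across-group pairwise
    similarity, event response magnitude extraction, and a covariate-adjusted
    group inference battery (pruned linear models, paired and Welch t-tests,
    Cohen's d, BIC-based Bayes factors). A seeded synthetic-cohort generator
    emulates the shared-response factor structure of group movie-viewing
    data (group-specific evoked loadings, idiosyncratic subject components,
    cross-network leakage, motion artifacts, coupled behavioral scores) so
    the full pipeline is testable without access to raw imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
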