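Package: eegcomplexity
Title: Multifractal, Entropy and Phase-Lag Connectivity Analysis of EEG Aging Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for resting-state multichannel EEG contrasting
    younger and older groups on temporal complexity and functional connectivity.
    Implements wavelet-leader multifractal analysis with log-cumulants c1 and c2,
    multiscale sample entropy over coarse-graining scales 1-30, phase-lag-index
    connectivity with node strength across five canonical frequency bands,
    mixed-design repeated-measures ANOVA with Greenhouse-Geisser correction and
    partial eta squared, Benjamini-Hochberg corrected post-hoc comparisons, and
    aging classification by logistic regression on principal components fitted
    inside cross-validation with repeated-CV ROC/AUC. Includes a synthetic
    two-group cohort generator (fractional Brownian motion and multifractal
    random walk backbones, band-limited lagged coupling, zero-lag common source)
    so every stage is testable without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    car,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
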