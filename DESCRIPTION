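Package: polysel
Title: Pre- and Post-Copulatory Sexual Selection Analysis for Group-Mating
    Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying sexual selection in replicated
    group-mating experiments in which one genetically marked focal male
    competes with rival males for a set of females, and paternity is scored
    from offspring markers.  Computes opportunity-for-selection indices
    (I, I_S, I_P) with bootstrap confidence intervals, mean- and
    variance-standardised univariate and multivariate Bateman gradients
    (including Jones' index / s'max), a delta-method decomposition of the
    variance in relative male reproductive success, sperm competition
    intensity (SCI) and its correlation with male mating success (SCIC)
    with a margin-preserving randomization null, adjusted paternity share,
    and a focal-male resampling estimator of the standardised variance in
    paternity share.  Includes an agent-based simulator of the experimental
    design (females with tunable post-mating refractory periods, paternity
    by copulation-count raffle) so the whole pipeline can be exercised and
    validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
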