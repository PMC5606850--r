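Package: hfqtail
Title: Ensemble Statistics and Binding Analysis for Autoinhibitory
    Disordered Tails of Hfq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how the acidic, intrinsically disordered C-terminal
    tail of the bacterial RNA chaperone Hfq folds back onto the basic rim of
    its Sm core. Reads multi-model structural ensembles, scores tail-core
    residue pairs with a documented electrostatic surrogate potential, and
    summarises them as per-residue interaction counts and energies, the
    expected energetic contribution (EEC) with bootstrap errors, and the
    on-target versus off-target specificity difference (delta-EEC). Also
    provides worm-like-chain effective-concentration estimates for tethered
    tail tips, fitters for saturation, Hill, competition (IC50) and
    exponential progress-curve data, three-state fluorescence-anisotropy
    deconvolution, and seeded synthetic-data generators (coarse-grained
    Monte-Carlo tail ensembles and noisy titrations) with known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
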