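Package: leidaplsc
Title: Dynamic Functional Connectivity States and Partial Least Squares
    Correlation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Phase-coherence dynamic functional connectivity analysis in the
    leading-eigenvector (LEiDA) style: Hilbert-transform instantaneous phases,
    cosine phase-coherence matrices, leading-eigenvector time series, k-medians
    clustering of recurring connectivity states, and per-subject state
    reconfiguration metrics (occurrence, dwell time, transition number,
    transition probabilities, Manhattan transition distances, idiosyncrasy).
    Brain-behavior association via Partial Least Squares Correlation (PLSC)
    with confound residualization, family-block-aware permutation tests,
    block bootstrap stability ratios, split-half reproducibility Z-scores and
    cross-validated out-of-sample correlations. Includes a synthetic cohort
    generator with planted Markov phase-locking state dynamics, family
    structure, confounds and a low-rank behavior association, so that every
    stage of the pipeline can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    yaml,
    optparse,
    knitr
Config/testthat/edition: 3
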