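Package: dyadsync
Title: Dyadic Nonverbal Synchrony from Motion Energy Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies nonverbal synchrony between two interactants from
    video-derived motion energy time series. Extracts per-region motion
    energy by thresholded frame differencing, computes windowed lagged
    cross-correlation synchrony with a leading/following decomposition,
    tests observed synchrony against surrogate (pseudosynchrony) null
    distributions built by between-dyad shuffling, and provides the
    session-level descriptive, paired-test and regression layer used to
    relate pre/post-intervention synchrony to self-reported therapy
    readiness. Includes a coupled burst-process simulator of dyadic
    movement so the full pipeline can be exercised and validated on
    synthetic data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
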