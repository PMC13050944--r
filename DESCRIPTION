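Package: premstates
Title: Pre-Movement EEG Microstate Analysis with Planted-Truth Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Two-level, polarity-invariant topographic clustering of
    pre-movement EEG into microstates, with global field power peak
    detection, a seven-criterion meta-criterion for choosing the number of
    template maps, backfitting, per-condition occurrence and global
    explained variance statistics, nonparametric load-effect tests
    (Friedman with Dunn post-hoc) and Pearson correlations, and a
    simplified distributed source stage (three-shell spherical lead field,
    sLORETA standardized inverse, sign-flip max-statistic permutation
    contrasts). A synthetic-data generator plants known template maps,
    prevalences, behavioral effects and EMG so that every stage of the
    pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    jsonlite,
    yaml,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
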