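Package: pmkin
Title: Analysis of Phenotype Microarray Kinetic Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Desk-scale analysis of OmniLog-style phenotype microarray (PM)
    kinetic data. Parses per-plate kinetic CSV exports into well-level growth
    curves with full metadata, supports hierarchical record filtering and
    replicate grouping, and provides the standard PM analysis battery:
    replicate outlier detection by median Pearson correlation,
    negative-control quantile curves for signal/noise calibration, bar plots,
    pairwise correlation matrices, growth-profile pattern search, k-means
    clustering of z-score scaled kinetic profiles, and heat-map comparison of
    test strains against a parent strain with signed fold changes and Welch's
    t-tests. Includes a synthetic-experiment generator with planted ground
    truth (outliers, clusters, fold changes) and a subcommand CLI.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    optparse
Suggests:
    mclust,
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
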