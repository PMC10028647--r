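Package: temponet
Title: Temporal Clustering and Test-Retest Reliability of Dynamic Brain Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds sliding-window dynamic functional brain networks from
    region-of-interest (ROI) time series, binarizes them by proportional
    thresholding over a density sweep, and computes the temporal clustering
    coefficient of the resulting binary multilayer networks at nodal,
    subnetwork, and global scales, together with static comparator metrics
    (binary clustering coefficient and local efficiency). Provides ICC(3,1)
    test-retest reliability across repeated scans with density-averaged
    summaries and qualitative classification, sex contrasts via the
    between-subject stratum of a repeated-measures ANCOVA, partial Spearman
    age associations, and Bonferroni correction. A regime-switching Gaussian
    cohort simulator with tunable temporal persistence, subject random
    effects, and sex/age effects supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
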