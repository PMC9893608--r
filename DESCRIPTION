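Package: flexitau
Title: Quantitative Tau Aggregation and PTM Landscape Analysis from Targeted Proteomics
Version: 0.1.0
Authors@R:
    person("flexitau", "maintainers", email = "flexitau@example.org", role = c("aut", "cre"))
Description: A pipeline for quantitative analysis of Tau aggregation and its
    post-translational modification (PTM) landscape from targeted proteomics
    data. Converts transition-level selected-reaction-monitoring (SRM) peak
    area reports into light/heavy peptide ratios, absolute insoluble/soluble
    Tau abundances calibrated against a heavy-isotope-labeled full-length Tau
    standard carrying a FLEX reporter peptide, and per-peptide modification
    extents. Combines PTM site tables from multiple search engines into
    canonical-numbered consensus matrices with a replicate-frequency filter,
    and provides the downstream progression statistics: complete-linkage
    hierarchical clustering, temporal PTM category annotation relative to
    tangle onset, fold changes versus baseline, Welch t-tests, and Pearson
    correlations of modification with insoluble Tau burden. A synthetic-data
    module generates ground-truth scenarios emulating the measurement
    structure of P301S and P301L tauopathy mouse-model studies so the whole
    pipeline is testable without raw mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
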