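Package: slcss
Title: Sliding-Window Longest Common Subsequence Similarity for
    Univariate and Multivariate Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes similarity indexes of symbol sequences and multivariate
    time series with a non-metric, sliding-window longest common subsequence
    (LCSS) heuristic: a greedy windowed matching pass repeated over suffix
    starts with early termination, followed by cross-variable refinement of
    the matched index pairs. Ships a classical dynamic-programming LCS
    baseline as optimality reference, min-max normalization, a synthetic
    pair generator with planted matches for benchmarking, FASTA/CSV readers,
    JSON/TSV result writers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    Biostrings,
    optparse,
    yaml,
    utils,
    stats,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
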