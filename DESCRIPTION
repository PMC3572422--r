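Package: anchoralign
Title: Long-Read Mapping by Successive Refinement with Anchor Combinatorics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Maps long, indel-noisy single-molecule sequencing reads to a
    reference genome by successive refinement: exact-match anchors are found
    with a suffix array supporting count/locate/longest-common-prefix
    queries, chained into candidate clusters, refined by sparse dynamic
    programming over short fixed-length matches, and finally aligned by
    banded dynamic programming scored with per-base quality values.  Each
    alignment receives a Bayesian mapping quality value.  The package also
    provides the exact combinatorics of alignment anchors in error-corrupted
    reads (composition counts by generating functions and by a closed form
    evaluated in exact big-integer arithmetic, moments, normal asymptotics,
    waiting lengths), an anchor-similarity metric between sequences, and a
    parametric read simulator with a geometric error-free run-length model
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    jsonlite,
    withr
Config/testthat/edition: 3
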