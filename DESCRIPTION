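Package: finsoc
Title: Social Structure Inference from Photo-Identification Sighting Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring the social structure of individually
    identifiable animals (e.g. photo-identified cetaceans) from group
    sighting records. Implements half-weight association indices with the
    standard inclusion filters (daily de-duplication, minimum sighting
    counts, calf exclusion, identification-coverage thresholds),
    group-permutation null models restricted to daily sampling periods with
    SD and CV test statistics, weighted social network metrics (strength,
    clustering coefficient, affinity) with bootstrap errors, maximum
    likelihood estimation of social differentiation, average-linkage
    dendrograms with cophenetic diagnostics and modularity-based community
    division, lagged association rate estimation with an eight-model
    exponential family ranked by QAIC, and a fission-fusion society
    simulator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
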