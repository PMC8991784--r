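Package: claimsnet
Title: Patient-Sharing Physician Networks from Ambulatory Claims Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Constructs informal networks of ambulatory physicians from
    administrative claims data using a five-step social-network-analysis
    pipeline: cohort definition via ambulatory-care-sensitive diagnosis
    groups (M1Q/M2Q validation rules), a patient-sharing graph thresholded
    on absolute and relative shared-patient counts, size-constrained
    modularity-based community detection applied iteratively, unique
    allocation of patients to their usual provider network by majority of
    treatment days, and per-network characteristics with Spearman rank
    correlations. Ships a synthetic claims generator with planted physician
    communities so the whole pipeline is testable without access to
    restricted billing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    igraph (>= 1.3),
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
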