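Package: hmmensemble
Title: Protein Family Classification with Ensembles of Profile HMMs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Represents each protein family's curated seed alignment by a
    nested ensemble of profile hidden Markov models, built by recursively
    decomposing a guide tree at its centroid edge with a stopping rule
    driven by subset size and mean pairwise sequence identity.  Query amino
    acid sequences are assigned to the family whose ensemble contains the
    highest-scoring profile above a per-family gathering-cutoff threshold.
    Includes a dependency-free reference scoring engine, an adapter to
    HMMER, a cross-validation and precision/recall evaluation harness with
    fragmentary queries, and a synthetic family simulator so the whole
    pipeline runs without external databases.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
SystemRequirements: HMMER (>= 3.0) for the optional external scoring engine
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
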