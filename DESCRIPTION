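Package: dtlor
Title: Maximum Parsimony Gene Tree Reconciliation in the DTLOR Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconciles a rooted gene tree against a rooted binary species
    tree under the DTLOR event model, which extends classical
    duplication-transfer-loss (DTL) reconciliation with origin events (entry
    of a gene lineage from outside the sampled species tree) and
    rearrangement events (changes of syntenic region along the genome).
    Provides exact dynamic-programming solvers for binary gene trees
    (decoupled species and synteny programs) and for multifurcating gene
    trees (a fixed-parameter joint program over per-vertex binary
    resolutions), deterministic traceback to a full reconciliation, exact
    counting of co-optimal reconciliations, brute-force reference
    implementations for verification, and seeded generators of synthetic
    instances and forward-simulated gene histories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
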