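Package: scaffmatch
Title: Scaffold-Window Substructure Classification of Endogenous
    Biochemical Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies small molecules as endogenous mammalian
    biochemicals or synthetic compounds by exact substructure and
    superstructure matching against a curated list of biochemical
    scaffolds.  Candidate-specific scaffold windows bounded by atom-count
    thresholds are searched in proximity order so that the first match
    found is guaranteed to be the best-scoring one, allowing early
    termination.  Includes the four classification rules (first-match,
    sum-of-best-scores, and their per-atom-count-bin variants), dataset
    curation filters, nested cross-validation threshold tuning with the
    sensitivity-equals-specificity cutoff rule, leave-one-out scaffold
    experiments, and a deterministic synthetic-molecule generator for
    fully reproducible end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineOB,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
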