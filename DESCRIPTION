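Package: PPIscreen
Title: Structure-Based Screening of Protein-Protein Interactions from
    Predicted Complex Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Decides whether two proteins interact, given predicted complex
    models and their per-model confidence data (per-residue pLDDT, pairwise
    predicted aligned error, pTM/iPTM). Implements interface detection by the
    beta-carbon distance rule, confidence / structural-counting / interface-
    energy feature blocks, DockQ model-quality filtering, compelling-decoy
    construction by nearest-structural-analog swapping (TM-score), gradient-
    boosted classification with leakage-safe grouped splits, sequential
    backward feature selection, threshold-performance tables, and all-vs-all
    family selectivity screening. Ships a synthetic-fixture generator so the
    whole pipeline is testable without external structure prediction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    jsonlite,
    xgboost,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
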