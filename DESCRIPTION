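Package: stageopt
Title: Metaheuristic-Tuned Dual-Layer Classification of Alzheimer's Disease Stages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for four-stage dementia grading from brain images with a
    two-tier classifier: a lightweight convolutional network trained end-to-end
    and truncated at its dropout layer to emit feature embeddings, followed by a
    gradient-boosted tree classifier over those embeddings. Hyperparameters of
    both tiers are tuned by a stagnation-aware variable neighborhood search with
    quasi-reflexive population initialization and elitist rollback, using the
    multiclass Matthews correlation coefficient as the objective. Includes the
    full evaluation harness (per-class metrics, macro and weighted aggregation,
    confusion-marginal reconstruction from published per-class tables,
    repeated-run summaries and nonparametric tests), kernel Shapley feature
    attribution with an exact enumeration oracle, and a synthetic labeled-image
    generator with controllable class separability so the whole method runs at
    desk scale without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    xgboost,
    jsonlite,
    yaml,
    png,
    car,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
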