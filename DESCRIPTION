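Package: cellfishing
Title: Similarity-Based and SVM Prediction of Compound-Cell Line Sensitivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ligand-based "cell fishing": predicts which cell lines are
    sensitive to a query compound from its Tanimoto similarity (over hashed
    circular Morgan fingerprints) to each cell line's known sensitive
    compounds, and compares this against per-cell-line RBF-kernel support
    vector machines trained after hierarchical-clustering class balancing.
    Includes an activity-data curation pipeline that turns raw IC50/GI50/CC50
    assay tables into a sensitive/resistant ligand-cell-line association
    database, a synthetic data generator embodying the molecular similarity
    principle, cross-validation and external-validation drivers with
    per-cell-line macro metrics and interaction-space micro metrics, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
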