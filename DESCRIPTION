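Package: ontoeval
Title: Hierarchical Multi-Label Evaluation of Ontology Annotation Predictions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Benchmarks predictors of ontology annotations (e.g. Gene
    Ontology protein function predictions) against a ground truth.
    Parses an OBO ontology into per-namespace directed acyclic graphs,
    propagates ground-truth annotations and prediction scores to the
    root(s) in linear time via a topological order, and sweeps score
    thresholds to produce precision/recall/F-measure curves, their
    information-accretion-weighted variants, and remaining-uncertainty/
    misinformation semantic-distance curves, with macro- or
    micro-averaging and CAFA-compatible normalization. Includes
    synthetic-benchmark generators, an independent set-based reference
    evaluator for validation, table outputs, team deduplication, and
    curve plotting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    parallel,
    Matrix,
    ggplot2
Suggests: testthat (>= 3.0.0), optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'ontology.R'
    'annotations.R'
    'propagation.R'
    'metrics.R'
    'evaluation.R'
    'fixtures.R'
    'oracle.R'
    'plotting.R'
    'ontoeval-package.R'
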