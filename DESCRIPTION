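Package: gradientScope
Title: Functional Connectome Gradients and Network Segregation Metrics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds parcellated functional connectomes, extracts PCA-based
    connectivity gradients from sparsified cosine-affinity matrices with
    Procrustes alignment of individual embeddings to a group reference,
    computes integration/segregation metrics (network median distance,
    gradient range and variation, network peak distance, eccentricity,
    within- and between-network dispersion), and relates them to
    questionnaire traits (AQ, GSQ) with motion-aware Spearman and
    ordinary-least-squares statistics. Includes a synthetic cohort
    generator with planted gradient-expansion effects so the full
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
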