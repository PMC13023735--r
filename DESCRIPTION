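Package: fedradsim
Title: Federated Learning Simulation for Multi-Institutional Radiological Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale simulator and analysis library for privacy-preserving
    federated learning on radiological imaging cohorts. Generates procedural
    chest-radiograph-like cases with anatomical masks and multi-label pathology
    annotations, partitions them into heterogeneous (non-IID) institutional
    nodes, and trains shared models under FedAvg, FedProx, or
    confidence-weighted aggregation with optional differentially private local
    updates (per-example gradient clipping plus Gaussian noise). Includes a
    composite segmentation loss with an anatomical-prior regularizer, Grad-CAM
    saliency maps and their localization scores, a privacy attack battery
    (loss-threshold membership inference, gradient-matching reconstruction),
    structural-similarity scoring, report-text metrics (BLEU-n, ROUGE-L,
    CIDEr-n), and communication-cost accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
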