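Package: fedsim
Title: Simulated Federated Learning Benchmarks for Multi-Site Tumor Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained simulator for benchmarking federated-learning
    (FL) aggregation and client-selection algorithms on multi-institution
    segmentation problems. Generates synthetic multi-site datasets with skewed
    site sizes, site-specific intensity shifts and nested tumor sub-regions
    (NCR/ED/ET label convention); trains a miniature residual encoder-decoder
    locally at each simulated institution; implements a catalogue of
    weighting-term aggregators (dataset size, validation loss, cost ratio,
    inverse parameter distance, PID-controller terms), server-side optimizers
    and client-selection policies; simulates per-round wall time from
    per-client normal distributions; and scores runs with Dice, 95th-percentile
    Hausdorff distance and an area-under-the-projected-DSC-curve convergence
    score. Includes mask post-processing operators, challenge-style
    rank-then-aggregate ranking schemes and an annotation quality-control
    screen.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    RNifti,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
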