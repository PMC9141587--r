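Package: bcmnet
Title: BCM Synaptic Plasticity Networks with Lateral Connections
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Rate-based simulation of Bienenstock-Cooper-Munro (BCM)
    synaptic plasticity in the Law-Cooper formulation: a sliding
    modification threshold computed as a moving average of batch-averaged
    squared postsynaptic activity, uniform lateral (cortico-cortical)
    coupling between neurons of one layer, ReLU/linear/logistic
    activations, and plain or Adam-stepped batch training. Includes
    generators for synthetic pattern environments with known fixed-point
    structure, selectivity and overlap (competitiveness) metrics,
    memorization-capacity accounting, receptive-field bitmap export, and
    readers for the MNIST IDX and CIFAR-10 binary image formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
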