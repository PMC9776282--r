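Package: ferpcvt
Title: Facial Expression Recognition for Stroke Rehabilitation with a
    Patch-Convolutional Vision Transformer
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements FER-PCVT, a lightweight hybrid
    convolution-transformer classifier for the facial expressions of
    stroke patients during rehabilitation training. Provides eye-landmark
    face alignment, Facial Action Coding System (FACS) based emotion
    labeling and dataset statistics, the PCVT backbone (convolutional
    patch embedding and pyramid transformer stages with convolutional
    Q/K/V projections), the valence-arousal-like classifier head with a
    batch-shared neutral baseline, CPU training and evaluation with
    per-class metrics, an analytic parameter/FLOP profiler, attention
    rollout maps, and a seeded generator of schematic action-unit-driven
    synthetic faces so the whole pipeline is testable without any
    external dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pracma
Config/testthat/edition: 3
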