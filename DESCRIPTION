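Package: kdistill
Title: Stage-Wise Knowledge Distillation for Imbalanced Histopathology
    Image Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Teacher-student knowledge distillation for multi-class
    classification of severely imbalanced histopathology-like image
    datasets. Both networks are partitioned into four corresponding
    stage blocks; training combines a stage-wise feature-map matching
    loss (through learnable 1x1 channel adapters), a temperature-scaled
    soft-label cross-entropy against the teacher's logits, and a
    class-weighted focal loss against the ground-truth labels. Includes
    miniature staged CNN backbones trainable on a CPU, a deterministic
    stratified 8:1:1 dataset splitter, an augmentation and preprocessing
    pipeline, a synthetic imbalanced image generator for end-to-end
    testing, a confusion-matrix/macro-metrics evaluation suite, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    png,
    EBImage,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
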