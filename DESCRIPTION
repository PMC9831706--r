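Package: drgrader
Title: Diabetic Retinopathy Severity Grading with a Vision Transformer and
    Class-Specific Residual Attention
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Grades diabetic retinopathy severity (0 = no DR through
    4 = proliferative, plus 5 = ungradable) from colour fundus photographs.
    A vision-transformer feature extraction block turns an image into a
    spatial feature map via patch embedding and a stack of multi-head
    self-attention encoder layers; a class-specific residual attention
    (CSRA) grading head pools the map with per-class temperature-controlled
    spatial softmax scores added, weighted by a residual coefficient, to
    global average pooling. Includes hand-written stochastic gradient
    descent training with per-class binary cross-entropy loss, a full
    confusion-matrix metrics engine (per-class precision, recall,
    specificity, false omission rate, F1, accuracy, macro averages,
    one-vs-rest ROC/AUC and Youden-index thresholding), a synthetic
    fundus-image generator with grade-determined lesion content for
    download-free experiments, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    png,
    yaml,
    stats,
    utils,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
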