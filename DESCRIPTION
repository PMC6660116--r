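Package: ffgf
Title: Fourier-Spectrum Geometric Features and Classifiers for Ultrasound
    Tumor Images
Version: 0.1.0
Authors@R:
    person("FFGF", "Maintainers", email = "maintainers@ffgf.dev",
           role = c("aut", "cre"))
Description: Computer-aided classification of B-mode ultrasound tumor
    images from the geometry of their Fourier power spectrum.  Images are
    transformed to the frequency domain, the log-spectrum is binarized at
    a trained quantile threshold, and the central spectral blob is
    summarized by the axes and area of its best-fit moment ellipse
    ("FFGF" features).  Four classifier families operating on these
    3-dimensional descriptors are implemented from scratch: k-nearest
    neighbors with Minkowski metrics, a least-squares linear discriminant,
    linear support vector machines (SMO and least-squares training), and
    extreme learning machines including the optimally pruned variant
    (LARS neuron ranking with PRESS leave-one-out selection).  A
    leave-one-out cross-validation harness reports accuracy, AUC,
    sensitivity and specificity, and a seeded phantom generator produces
    synthetic two-class ultrasound-like benchmarks for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    png,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
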