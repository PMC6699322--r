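Package: ivimhsi
Title: IVIM Diffusion MRI Analysis with Hyperspectral Target Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for intravoxel incoherent motion (IVIM) diffusion-weighted
    MRI of the breast. Fits mono- and biexponential signal-decay models
    pixel by pixel to obtain ADC, slope, D, D* and perfusion-fraction maps;
    expands a multi-b-value cube into correlated band images (band expansion
    process); detects lesions with unsupervised hyperspectral target
    detection (automatic target generation, spectral angle mapping, and
    constrained energy minimization with linear or RBF kernels); converts
    detection maps to binary masks with co-occurrence local-entropy or Otsu
    thresholding; extracts the breast region from a slice; and classifies
    tissue into central tumor, peripheral tumor, cyst and normal classes
    with a threshold decision tree plus histogram statistics. Includes a
    seeded digital phantom generator so the whole pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
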