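Package: mritexture
Title: Multiparametric MRI Texture Classification of Regional Tumor Content
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Classifies 8x8-voxel biopsy-site regions of coregistered
    multiparametric MRI (eight contrasts: T1+C, T2W, rCBV, EPI+C, p, q,
    MD, FA) as high- versus low-tumor-content (at least 80 percent versus
    under 80 percent tumor nuclei) and renders tumor-probability maps for
    glioblastoma. Implements gray-level co-occurrence matrix, local binary
    pattern and discrete orthonormal Stockwell transform texture features,
    block-wise principal component reduction at an 85 percent variance
    rule, diagonal linear and quadratic discriminant and support vector
    machine classifiers, sequential forward feature selection under
    leave-one-out cross-validation, confusion-matrix evaluation with zone
    stratification, and a synthetic multi-contrast cohort generator with a
    ground-truth tumor-fraction field so every stage is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    RNifti,
    e1071,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
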