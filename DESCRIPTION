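Package: mixshape
Title: Soft-Label CNN Estimation of Cell Mixture Proportions from
    Microscopy Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies homogeneous cell populations (parental cancer,
    chemoresistant cancer, normal control) and approximates the mixture
    proportions of heterogeneous populations from microscopy images by
    treating class labels as points on the probability simplex. Provides
    a seeded synthetic cell-image generator, the hold-out plus five-fold
    cross-validation splitting scheme, soft-label-aware resampling
    (random oversampling, SMOTE, Borderline-SMOTE, edited nearest
    neighbours), a compact convolutional network trained as a regressor
    with mean-squared error against simplex labels, bagging ensembles
    with soft voting, a macro-averaged metric suite with a soft-label
    RMSE, and Grad-CAM saliency maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
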