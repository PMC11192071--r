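Package: mulchmap
Title: Mapping Rock Gardens from Multispectral Imagery and Modelling the
    Population They Could Feed
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An island-scale remote-sensing pipeline for lithic-mulch
    ("rock garden") agriculture. Simulates paired VNIR/SWIR multispectral
    scenes with class-conditional Gaussian spectra, trains and compares
    three supervised land-cover classifiers (Gaussian maximum likelihood,
    maximum entropy realized as L2-penalized multinomial logistic
    regression, and a bootstrapped decision-tree ensemble), pan-sharpens
    SWIR imagery by PCA component substitution, assesses accuracy with
    confusion-matrix metrics including Cohen's kappa, converts classified
    rasters into cleaned garden polygons and kernel-density surfaces, and
    feeds garden area into a sweet-potato carrying-capacity model that
    translates cultivated hectares into supported-population estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    Rcpp,
    jsonlite,
    pracma,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    nnet,
    randomForest,
    caret
Config/testthat/edition: 3
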