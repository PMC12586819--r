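Package: nodulefab
Title: Design and Validation of 3D-Printable Part-Solid Lung Nodule CT Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Digital workflow for manufacturing part-solid pulmonary nodule
    phantoms for computed tomography research. Segments Hounsfield-unit (HU)
    bands from CT-like volumes, designs cubic beam-lattice structures whose
    air/material fill fraction emulates target radiodensities through the
    partial-volume effect, assembles a single printable multi-density mesh by
    exact Boolean operations on rectilinear solids, predicts CT appearance with
    a virtual-CT simulator, and provides the observer-study statistics
    (confusion matrices, bootstrap confidence intervals, Conger's kappa,
    chi-square goodness of fit) used to validate phantom realism against
    patient nodules.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
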