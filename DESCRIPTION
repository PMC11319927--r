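Package: parityQuant
Title: Demographic-Parity Multi-Quantification of Maxillary Basal Bone Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automatic multi-quantification of the nine maxillary
    alveolar basal-bone indices (four lengths, five widths) from 2D sagittal
    sections, with a demographic-parity workflow for auditing and mitigating
    subgroup bias. Provides exact geometric measurement operators on annotated
    tooth/bone cross-sections, a demographically structured synthetic
    sagittal-section generator with analytically exact ground truth, a
    shared-backbone multi-head residual regression network with Grad-CAM
    explanations, agreement statistics (paired Wilcoxon signed-rank with exact
    tie-aware null, ICC(2,1), Bland-Altman, Pearson), and a subgroup audit that
    identifies the sensitive demographic attribute and retrains per-stratum
    submodels pooled into a routing ensemble.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    withr,
    EBImage
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
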