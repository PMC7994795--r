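Package: volstorm
Title: Volumetric Scanning 3D-dSTORM Localization Processing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Processing pipeline for volumetric single-molecule localization
    microscopy acquired by repeated axial piezo scanning with astigmatic 3D
    detection. Reads rapidSTORM-style and CSV localization tables, builds
    width-versus-z calibrations from bead stacks, assembles repeated-scan
    movies into drift-corrected volumetric point clouds using coverslip
    fiducials, segments presynaptic protein clusters from kernel-density
    isosurfaces with size, volume and density metrics, flags border-truncated
    clusters, runs localization-reduction robustness experiments, assigns
    clusters to membrane-labelled boutons, and simulates ground-truth
    acquisitions so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
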