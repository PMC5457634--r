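Package: arcdosim
Title: Dosimetric Comparison of Conformal Arc and Static-Field Thoracic Plans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the dosimetric comparison of dynamic conformal arc
    (DCAT) and static-field conformal (3D CRT) thoracic radiotherapy plans.
    Reads DICOM RT Dose and RT Structure Set objects, rasterizes contours
    to voxel masks, and computes geometric target descriptors (volume,
    surface area, sphericity and a CTV/PTV shell-based sphericity
    surrogate), dose-volume histogram metrics (conformation number,
    homogeneity index, dose homogeneity dispersion, VxGy, mean and
    hot-volume doses), gamma-index agreement between measured and
    calculated dose planes, a per-medium systematic/random error
    decomposition across plan cohorts, and paired nonparametric cohort
    statistics. A synthetic thorax phantom and beam model generates
    paired arc and static plans so the whole pipeline runs end-to-end
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
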