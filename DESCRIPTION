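Package: bonefabric
Title: Trabecular Bone Morphometry and Mean-Intercept-Length Fabric
    Anisotropy from Micro-CT Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies bone microstructure in calibrated micro-computed
    tomography density volumes the way preclinical bone laboratories do:
    Gaussian noise filtering and global density thresholding, axial
    region-of-interest definition with cortical/trabecular compartment
    splitting, bone volume fraction (BV/TV), Euler-characteristic
    connectivity density (Conn.D), and the mean-intercept-length (MIL)
    fabric tensor with its degree of anisotropy (DA) computed from
    triangulated bone-surface projections. Includes a synthetic phantom
    generator (anisotropic plate and cylinder lattices, isotropic Boolean
    structures, tumor-like osteolysis and disorganized periosteal woven
    bone), rank-based group statistics, and an end-to-end deterministic
    study pipeline with NIfTI and multi-page TIFF I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml,
    EBImage,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
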