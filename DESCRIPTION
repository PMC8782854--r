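Package: jqma
Title: Automated Alignment, Subdivision and Morphometry of Small-Animal
    Knee Joints from MicroCT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-invariant preprocessing and 3D quantitative morphometric
    analysis (QMA) of segmented small-animal knee joints. The tibia is put
    into a common orientation from a truncated spherical-harmonic (SPHARM)
    description of its surface followed by principal component analysis, the
    joint is split into medial and lateral volumes of interest at the
    intercondylar valley located by 1D persistence watershedding, and joint
    metrics (centre-of-mass vector angles, contact area under virtual
    loading, joint space width and volume) are measured together with
    reproducibility statistics (two-way consistency ICC with confidence
    intervals, precision errors, RMSE). Includes a synthetic phantom joint
    generator with known ground truth for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE, load = "source")
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    pracma,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
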