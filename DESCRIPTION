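Package: lungphantom
Title: Synthetic Lung-Phantom CT Simulation and Image-Quality / Radiomics
    Comparison of Photon-Counting and Energy-Integrating Detectors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generates digital cylindrical lung-lesion phantoms and simulates
    dose-matched CT acquisitions for a photon-counting (PCCT) and an
    energy-integrating (EIDCT) scanner model, with per-dose lung-parenchyma
    noise calibrated to published measurements.  Provides region-of-interest
    Hounsfield-unit statistics, image noise and contrast-to-noise ratios, a
    from-scratch 107-feature radiomics extractor (first-order, mesh-based
    shape, and GLCM/GLRLM/GLSZM/GLDM/NGTDM texture families with
    IBSI-style definitions), principal-component cluster consistency and
    separability statistics, and a normality-gated paired testing framework.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    nortest,
    withr
Config/testthat/edition: 3
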