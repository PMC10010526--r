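Package: pcdct
Title: Photon-Counting Detector CT Simulation and Projection-Based
    Material Decomposition for Metal Artifact Reduction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates two-energy-bin photon-counting detector (PCD)
    fan-beam CT acquisitions of digital phantoms and reconstructs virtual
    monochromatic CT images via projection-domain basis-material
    decomposition.  Includes embedded X-ray attenuation tables, a
    polychromatic tube spectrum model, a Siddon ray-tracing forward
    projector with Poisson counting noise, flat-detector filtered
    backprojection, two decomposition algorithms (reverse polynomial and
    linear maximum-likelihood estimation with an error-correction
    look-up table), conventional sinogram-inpainting metal artifact
    reduction baselines (linear interpolation and normalized
    interpolation), and image-quality metrics (PSNR, NRMSE, SSIM,
    circularity).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
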