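# pcdct

Simulation and reconstruction toolkit for studying **metal artifact
reduction (MAR) in photon-counting detector (PCD) CT** through virtual
monochromatic imaging.

Metallic implants (dental fixtures, spine hardware, hip prostheses)
produce beam-hardening cupping and bright/dark streaks in CT images.
Conventional fixes inpaint the metal trace in the sinogram — linear
interpolation (LMAR) or prior-normalized interpolation (NMAR) — at the
cost of blurring tissue near the implant.  A PCD acquires each
projection in two energy bins simultaneously, which permits a different
route: decompose every ray into effective basis-material thicknesses
and re-synthesize an ideal single-energy ("virtual monochromatic")
sinogram that is free of beam hardening by construction.  `pcdct`
implements the full comparison pipeline on synthetic phantoms, for
researchers evaluating projection-domain MAR methods.

## The model

A two-bin PCD measures, per ray,

    N_k = n0 * sum_E S(E) D_k(E) exp( -A_m1 f_m1(E) - A_m2 f_m2(E) ),   k = 1, 2

where `S(E)` is the tube spectrum, `D_k(E)` the bin-`k` response,
`f_m(E)` the linear attenuation of basis material `m` (PMMA and
aluminium here), and `A_m` the effective thickness of `m` along the
ray.  With log projections `P_k = -ln(N_k / N_0k)`, the decomposition
inverts `(P_1, P_2) -> (A_m1, A_m2)` by one of two calibrated models:

* **VMI-Poly** — reverse polynomial: each thickness is a six-term
  quadratic in `(P_1, P_2)`, `A_m = d_1 + d_2 P_1 + d_3 P_2 + d_4 P_1^2
  + d_5 P_1 P_2 + d_6 P_2^2`, least-squares fitted to a step-wedge
  calibration (10 x 10 thickness pairs, PMMA 0-50 cm, Al 0-10 cm).
* **VMI-Atable** — linear maximum-likelihood estimation with an
  error-correction look-up table: fit `P ≈ M A` over the calibration,
  estimate `A_MLE = (M' R^-1 M)^-1 M' R^-1 P`, then correct the
  beam-hardening bias with `dA = A_calib - A_MLE` interpolated over the
  deformed calibration lattice, `A = A_MLE + dA(A_MLE)`.

The virtual monochromatic sinogram at energy `E` is
`P(E) = mu_m1(E) A_m1 + mu_m2(E) A_m2`, reconstructed by flat-detector
fan-beam filtered backprojection and displayed in HU.  Image quality is
scored by PSNR, NRMSE (test-image normalized), global SSIM, and rod
circularity `4 pi Area / Perimeter^2`.

## Worked example

Three copper rods in a 30-mm PMMA cylinder — a classic metal-artifact
evaluation phantom — scanned at 140 kVp with thresholds at 20/90 keV,
corrected by all four methods and scored against the 100-keV
monochromatic reference:

```r
library(pcdct)

beam <- apply_filtration(generate_spectrum(140), "al", 0.2)  # +2 mm Al
pcd  <- detector_model(20, 90)

calib  <- simulate_calibration(make_calibration_design(10, 10, 50, 10),
                               beam, pcd, n0 = 1e7)
atable <- fit_atable(calib)
atable
#> <atable_model> M =
#>        [,1]   [,2]
#> [1,] 0.2239 0.6594
#> [2,] 0.1915 0.4468
#>   LUT: 100 nodes (max |dA| = 8.19 cm)

phantom  <- make_mae_phantom(0.1)
geometry <- geometry_preset("dental", "test")
config   <- pipeline_config(phantom, geometry, n0 = 1e7, seed = 1,
                            out_n = 256)
result   <- run_pipeline(config)
result$metrics[result$metrics$roi == "whole", ]
#>       method   roi     psnr      nrmse      ssim
#>  uncorrected whole 24.26476 0.29081386 0.7513428
#>         lmar whole 24.79086 0.27807663 0.8309957
#>         nmar whole 24.85553 0.27607985 0.7743193
#>     vmi_poly whole 44.61703 0.03883206 0.9961840
#>   vmi_atable whole 40.87286 0.06083533 0.9929998
```

The fitted `M` is the effective attenuation of PMMA and Al in each bin
(1/cm); the look-up table stores up to ~8 cm of beam-hardening
correction at the deep end of the wedge.  In the metrics table the two
virtual monochromatic reconstructions sit 16-20 dB above the
uncorrected image and far above the inpainting baselines, whose
interpolation smooths real structure near the rods — the mechanism this
package exists to quantify.  `run_pipeline()` also returns the images
themselves, fitted models, and line profiles; `write_pipeline_outputs()`
saves everything (float TIFF + CSV + JSON).  A YAML-driven command-line
entry point is included at `inst/scripts/pcdct_run.R`.

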