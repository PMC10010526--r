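---
title: "Models and methods behind pcdct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pcdct}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`pcdct` simulates two-energy-bin photon-counting CT acquisitions and
compares four metal-artifact-reduction strategies on equal footing:
sinogram inpainting (LMAR, NMAR) and virtual monochromatic imaging from
projection-domain material decomposition (VMI-Poly, VMI-Atable).  This
vignette records the models, the tunable parameters, and the design
decisions a user should understand before trusting results.

## Physical model and its assumptions

Photon transport is primary-beam Beer-Lambert only: an ideal point
source, no scatter, no detector blur, and a PCD with perfect energy
separation and efficiency, so the bin response is an indicator function
of the threshold interval.  Expected counts per ray are

$$N_k = n_0 \sum_E S(E)\,D_k(E)\,
        \exp\Big(-\sum_m \mu_m(E) L_m\Big),$$

summed over a 1-keV energy grid from 1 to 150 keV; measurements are
independent Poisson draws around these means.  These are deliberate
simplifications: the questions under study (beam hardening and its
correction) live entirely in the energy dependence of $\mu$, which is
retained exactly.

**Attenuation tables.** Linear attenuation for water, soft tissue,
cortical bone, PMMA, Al, Ti, Cu and air is embedded as plain-text CSV
(1-keV grid), built from published standard-grid mass attenuation
values times standard densities (water 1.0, soft tissue 1.06, bone
1.92, PMMA 1.19, Al 2.699, Ti 4.506, Cu 8.96 g/cm^3), log-log
interpolated between grid points with K edges of Al/Ti/Cu bracketed.
Below 10 keV the tissue-like mixtures are power-law extrapolations;
nothing in the pipeline evaluates them there, because the detector low
threshold (20 keV) removes those energies from every measurement.

**Tube spectrum.** The generator is a Kramers continuum
$S(E)\propto(\mathrm{kVp}-E)/E$ with tungsten K lines at 59.3, 67.2 and
69.1 keV, filtered by anode self-absorption modelled as a 5-mm
Al-equivalent slab plus 1.6-mm inherent and (by default) 2-mm added Al.
The bare Kramers law overestimates low-energy fluence badly because it
ignores absorption of photons generated at depth in the target; the
5-mm Al-equivalent default was set from published beam-quality figures
for a heavily filtered 140-kVp tungsten beam (mean detected energy
around 65 keV) *before* any end-to-end checks were run.  The spectrum
is a qualitative stand-in, not a tabulated model — users with a
measured or tabulated spectrum should import it via
`read_spectrum_csv()`; every downstream algorithm is calibration-based
and adapts to whatever spectrum is supplied.

**Energy bins.** Thresholds default to 20/90 keV.  The internal
convention is half-open: bin 1 is $[low, high)$, bin 2 $[high, kVp]$.
On the integer grid a threshold pair (30, 80) therefore collects
energies 30-79 and 80-140; quoted ranges like "[31 80]" in the
literature count from the keV above the threshold.

## Decomposition algorithms

Calibration is simulated in slab geometry (closed form, no ray
tracing) on a full-factorial step-wedge: 10 equal steps of PMMA from 0
to 50 cm crossed with 10 steps of Al from 0 to 10 cm.  Calibration is
noise-free by default (a seed can be supplied); noise-free means are
used as-is without the count floor, since the floor exists only to keep
logs of integer zero counts finite.

**VMI-Poly** fits each thickness channel on the quadratic basis
$\{1, P_1, P_2, P_1^2, P_1P_2, P_2^2\}$ by least squares and records
the RMS calibration residual per channel.

**VMI-Atable** fits the effective attenuation matrix $M$ by
no-intercept least squares of $P_{calib}$ on $A_{calib}$, computes
$A_{MLE} = (M^T R^{-1} M)^{-1} M^T R^{-1} P$ with
$R = \mathrm{diag}(1/N_1, 1/N_2)$ (the first-order Poisson covariance
of a log projection; for the square two-bin system the weights cancel
exactly), and stores corrections $\delta A = A_{calib} - A_{MLE}$ at
the nodes $A_{MLE,calib}$.  The nodes form a deformed but structured
$10\times10$ lattice in MLE space, so interpolation works on that mesh
directly: locate the containing quad by convexity tests, invert the
cell's bilinear map by Newton iteration (12 steps, far past
convergence), and interpolate $\delta A$ bilinearly.  This is exact at
every node.  A Catmull-Rom bicubic variant was evaluated and rejected:
the correction field is strongly curved across the first Al step
(where one centimetre of Al removes most of the soft flux in the low
bin), and the cubic stencil overshoots there, roughly doubling the
worst between-node error.  Queries outside the mesh take the
nearest-node correction and are counted (`outside_frac`).

Between LUT nodes the correction error is bounded by the bilinear
interpolation error of $\delta A$ on the prescribed design; it is
largest, *relative to the local thickness*, in the thin-thickness cells
where $\delta A$ has curvature comparable to its own magnitude.  The
acceptance suite measures this honestly rather than hiding it: the
worst-case relative error on a 3x finer grid is reported by
`scripts/acceptance.R`.

Negative thickness estimates are kept by default
(`clip_negative = FALSE` in `synthesize_vmi()`): zeroing them before
ramp filtering biases the reconstruction; the switch exists for users
who need physical thickness maps.

## Reconstruction

Flat-detector fan-beam FBP: cosine pre-weighting on the virtual
detector at the isocenter, band-limited ramp kernel applied by padded
FFT (pure ramp by default — no apodization is assumed anywhere, a Hann
window is available), then distance-weighted backprojection over the
full 360-degree scan with the half-weight that compensates double
coverage.  Output is in 1/cm.

HU conversion needs a water reference matched to the image's energy
scale: virtual monochromatic and reference images use
$\mu_{water}(E_{VMI})$; polychromatic uncorrected images use
$\mu_{water}$ at the spectrum's mean detected energy (above the low
threshold).  Both references are recorded in the image metadata.

Geometry presets copy the two bench configurations (dental: SAD
400 mm, AID 200 mm, 0.5-mm pitch; conventional: SAD 600 mm, AID
400 mm, 1-mm pitch) with 1080 views and 1024 detector pixels at full
scale.  The `test` scale keeps 360 views and 256 pixels at four times
the pitch so the detector span — and therefore the reconstructable
field of view — is preserved; all shipped tests and the acceptance
script run at this scale to stay within seconds-to-a-minute runtimes.

## MAR baselines

LMAR and NMAR operate on the summed-bin (energy-blind) log projection,
as a conventional CT would.  Metal is segmented at 3000 HU (default),
its trace found by forward projecting the mask, and trace samples
replaced per view by linear interpolation between the nearest
non-trace neighbours.  NMAR first divides by the forward projection of
a three-class prior (air -1000 HU / flat soft tissue 0 HU / bone kept;
class cuts at -500 and +500 HU) built from the LMAR image, with a
+1000 HU offset keeping the prior positive — the offset cancels in the
ratio.  Where the prior sinogram falls below $10^{-6}$ of its maximum
the method passes through to plain LMAR for that sample.  Both methods
restore out-of-trace samples bit-exactly, and metal pixels are
reinserted from the uncorrected image for display and scoring.

## Metrics

PSNR and NRMSE follow the definitions with the *test* image in the
NRMSE denominator (a reference-normalized switch exists).  SSIM is
evaluated globally — single image-wide moments — with
$C_1 = (0.01L)^2$, $C_2 = (0.03L)^2$, $L$ the reference dynamic range.
Circularity is $4\pi\,\mathrm{Area}/\mathrm{Perimeter}^2$ with area
from the pixel count and perimeter from the marching-squares length of
the 0.5-level contour of the lightly smoothed (3x3 box, twice) mask.
The smoothing recovers the sub-pixel boundary of smooth convex regions
(a rasterized 25-px-radius disk scores above 0.98, where staircase
perimeters would deflate it to about 0.88), at the cost of slightly
rounding sharp corners; rod cross-sections, the intended use, have
none.  Values marginally above 1 are clipped with the raw value kept
as an attribute.

## What the phantoms do and do not emulate

The generators are deterministic geometric surrogates: a step-wedge
calibration design, the three-Cu-rod PMMA cylinder (rod centers on a
9-mm circle at 90/210/330 degrees — positions chosen once, as the
symmetric layout is only specified qualitatively), analytic disks for
oracles, and head/abdomen/hip slices built from ellipses (skull ring,
vertebral body, femoral heads) with titanium shapes burned in.  Field
of view per region: 256 mm (head), 409.6 mm (abdomen), 512 mm (hip).
They reproduce the *artifact mechanisms* — beam hardening through
thick tissue, bone and metal, photon starvation behind metal, paired
implants casting joint shadows — but not anatomical texture,
heterogeneous tissue composition, or scanner non-idealities (scatter,
detector spectral distortion, focal-spot blur).  Passing tests
therefore validate the algorithms and their implementation, not
clinical performance.

## Numerical choices and degenerate inputs

* Count floor 0.5 before any log of measured (noisy) counts;
  photon-starved rays stay finite.  Noise-free expected counts are
  used without flooring.
* Mid-design conventions: with an even number of design steps the
  "central" calibration node is taken at the lower median index pair.
  At that node the noisy-calibration bias of the Atable estimator is
  within the acceptance bound; deeper nodes transmit only a few
  photons at $n_0 = 10^5$ and acquire the well-known log-count bias,
  which the package reports rather than masks.
* Poisson noise is seeded explicitly and restores the caller's RNG
  state; per-stage pipelines derive all randomness from the single
  configured seed, so a `run_config` reproduces bit-identical outputs.
* Whole-row metal traces (a ray fully inside metal for every detector
  pixel) fall back to a view-mean fill and are the only inpainting
  case that is not interpolation.
* The ray tracer is an exact Siddon-style traversal; rays missing the
  grid return zero path length, and phantoms larger than the scan
  field of view are rejected rather than silently truncated.

## Known limitations

Two-material decomposition only (no K-edge imaging); 2-D fan beam
(no cone beam); the spectrum model is parameterized, not tabulated;
LMAR/NMAR implementation details (no trace dilation, per-view 1-D
interpolation) follow the common descriptions rather than any specific
vendor implementation.  On phantoms whose rays stay well inside the
calibration range both decomposition algorithms are near-exact and
their ranking can come down to fractions of a dB; the decisive
advantages of the MLE+LUT route appear at heavy attenuation and with
spectra richer in low-energy flux than the built-in stand-in.
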