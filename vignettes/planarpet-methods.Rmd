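---
title: "Methods: simulating and characterizing a dual-head planar PET camera"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and characterizing a dual-head planar PET camera}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(planarpet)
```

`planarpet` models a PET camera made of two opposed planar detector heads
and reproduces the NEMA NU-4-adapted measurement protocols used to
characterize such systems. This vignette is the package's account of the
science: the model and its assumptions, the calibrations and tunable
parameters, what the synthetic data do and do not emulate, the numerical
choices, and the known limitations.

## Geometry and coordinate convention

Each head tiles `modules_nx = 4` by `modules_ny = 3` square modules of
pitch 57.66 mm, each carrying a 24 × 24 array of 2.32 × 2.32 × 13 mm³
scintillator crystals. Tiling is seamless, so the sensing area is exactly
`4 × 57.66 = 230.64` mm by `3 × 57.66 = 172.98` mm. The XY plane is
parallel to the heads, Z runs from one head to the other, and the origin
sits midway between them: heads at `z = ±separation/2`. The 4 mm housing
offset is carried as metadata only. Sensing-area membership uses half-open
intervals `[-L/2, L/2)` so that edge events belong to exactly one bin.

For a point between the heads, the set of directions whose back-to-back
photon pair intercepts both sensing areas is a box in the tangent plane
`t = (d_x/|d_z|, d_y/|d_z|)`, and its solid angle has the classical
closed form (corner-decomposed `arctan` terms). The package uses this
closed form (`pair_acceptance_analytic()`) as the analytic oracle for the
Monte Carlo acceptance estimator and as the MLEM sensitivity image; for a
centered source it reduces to the textbook rectangle solid angle
(`rect_solid_angle()`).

## Detector response and its two calibrations

The per-photon detection probability is modeled as

\[ p(\theta) \;=\; \eta \, \bigl(1 - e^{-\mu \ell / \cos\theta}\bigr), \]

Beer–Lambert interaction of the 13 mm crystal slab at incidence angle
θ (`μ = 0.87` cm⁻¹ for LYSO at 511 keV) times a scale η collecting
everything the package does not model photon-by-photon (photopeak
fraction, trigger and readout losses). Two consequences matter:

* **η is calibrated, not guessed.** `calibrate_pair_efficiency()` solves
  `η² I = S_target` where `I` is the obliquity-weighted acceptance
  integral at the FOV center, so the simulated center-of-FOV absolute
  sensitivity equals the measured peak (3.5 % at 60 mm separation by
  default). With the defaults this gives η ≈ 0.26.
* **The angle dependence is load-bearing.** Oblique photons cross more
  crystal and are detected more often. Edge positions of a sensitivity
  scan only admit near-normal rays in X, so their sensitivity falls
  faster than the bare solid angle; with a constant per-photon efficiency
  the scan average would come out ≈ 2.7 % (peak calibrated to 3.5 %),
  while the angle-dependent model predicts ≈ 2.5 %, matching the measured
  2.4 % within its tolerance.

Detected endpoint coordinates receive an isotropic Gaussian blur of FWHM
`positioning_fwhm = 3.25` mm, then are clamped into the sensing area
(Anger readout piles mispositioned edge events at the module border
rather than losing them, so counting measurements are unaffected). The
value is the package's second calibration: the coincidence response at
the midplane is the endpoint blur divided by √2, and 3.25 mm ≈ √2 × 2.3 mm
reproduces the measured in-plane reconstructed resolution of this class
of camera; it is consistent with the 2.32 mm crystal pitch plus
light-guide sharing in a 64:4 multiplexed Anger readout. Energies are
blurred with fractional FWHM 0.15 at 511 keV scaling as `1/√E` (a typical
LYSO/SiPM figure; the window 350–700 keV then cuts essentially no
photopeak events).

The third calibration is the dead time: `calibrate_dead_time()` estimates
the prompt-rate constant from a short seeded acquisition and sets the
paralyzable `τ = 1/n(A_peak)` so the observed count-rate curves roll over
near the nominal peak concentration (10.5 kBq/mL of the 300 mL scatter
phantom, i.e. 3.15 MBq). Real electronics constants are not published for
this class of system; simulated absolute rate magnitudes are therefore
calibration-dependent, and only rate *structure* (linearity at low
activity, rollover, NECR ≤ T, label bookkeeping) is asserted in tests.

## Sources, phantoms and the synthetic-data contract

* `point_source()`: 0.3 mm Na-22 sphere, 89.9 kBq calibrated activity,
  branching ratio 0.9060, used for resolution and sensitivity. Its
  acrylic carrier is geometric support only — no attenuation, matching
  protocols that apply no corrections to point-source data.
* `nu4_scatter_phantom()`: rat-sized HDPE cylinder (Ø50 × 150 mm,
  0.98 g/cm³, μ₅₁₁ = 0.0967 cm⁻¹) with a 3.5 mm line cavity of 142 mm
  fillable length offset 17.5 mm from the axis, filled with 51 MBq F-18
  (half-life 109.77 min, branching 0.9686). The offset is placed along
  +Y so the rebinned line peak sits at y = 17.5 mm. Although sometimes
  described as an "axial" offset, under the rat-phantom convention it is
  a radial offset from the cylinder axis, which is what we implement.
  Concentrations are reported against the nominal 300 mL volume (so
  10.5 kBq/mL ↔ 3.15 MBq), not the geometric 294.5 mL, to stay
  consistent with how such systems tabulate count-rate data.
* `micro_hotspot_phantom()`: six 60° sectors of rods (diameters
  2.4/2.0/1.7/1.35/1.0/0.75 mm by default, configurable; spacing twice
  the diameter), rods along Z, 1 MBq F-18. Only the 1.7 and 1.35 mm
  sectors carry quantitative claims.

The simulator emulates: decaying Poisson emission with time stamps,
isotropic pair emission, geometric acceptance, angle-dependent stopping,
single Compton scatter in the phantom body (Klein–Nishina at 511 keV,
interaction depth from a truncated exponential), energy blur and window,
randoms at `2τS_AS_B` with endpoints resampled from the singles spatial
distribution, and paralyzable (or non-paralyzable) dead time on the
prompt stream. Ground-truth labels (`true`/`scatter`/`random`) ride along
every event and partition the prompts exactly.

It does **not** emulate: positron range or annihilation-photon
acollinearity (sub-0.5 mm effects at these separations — simulated
resolutions are therefore calibration-limited, not physics-limited),
multiple or detector-side scatter, depth-of-interaction, inter-crystal
scatter, scintillator intrinsic radioactivity background, or per-single
dead time (the dead-time model acts on the coincidence stream). Passing
tests consequently validate the *analysis chain and its estimators
against a controlled truth*, not the absolute physics of any real camera.

## Event filters

The energy window keeps events with both photons inside `[low, high]`
keV. The angle-allowance filter keeps events whose endpoint displacement
in the XY plane does not exceed the allowance; the default metric is the
Euclidean displacement `√(ΔX² + ΔY²)` (a single scalar allowance reads
naturally as a radius), with a per-axis mode (`|ΔX| ≤ a` and `|ΔY| ≤ a`)
available since hardware implementations differ. Both filters only drop
records, never modify them; they are idempotent, commute, and nest with
increasing allowance.

The imaging protocols (resolution, hotspot) apply a 60 mm allowance by
default: oblique-LOR discrimination is part of this camera family's
image processing, and the angular aperture it sets is what produces the
characteristic cross-plane/in-plane resolution anisotropy of a planar
pair (about 2–3×). The sensitivity protocol is a pure counting
measurement and is analyzed unfiltered; the count-rate protocol takes
the allowance as a configuration axis (60/90/110/144 mm), with peak
rates monotone in the allowance by the nesting property.

## Reconstruction

**SSRB** assigns each LOR to the plane midway between the heads at its
crossing point; with symmetric heads this is the endpoint midpoint.

**Back-projection and MLEM** share one system model: each LOR is a ray
traversed through the voxel grid with exact intersection lengths
(incremental Siddon/Amanatides–Woo traversal in C++). The list-mode MLEM
update is

\[ \lambda_j \leftarrow \frac{\lambda_j}{s_j} \sum_i
   \frac{a_{ij}}{\sum_k a_{ik}\lambda_k}, \]

with the sensitivity image `s` either uniform or the per-voxel analytic
pair acceptance. After each iteration the median root prior correction
`λ ← λ / (1 + β(λ − med λ)/med λ)` is applied over a 3×3×3 window when
enabled (default β = 0.3; the prior literature's window, with β a
package default since no published value exists for this camera).
Voxels whose 27-neighborhood median is zero are left untouched, and any
non-finite voxel aborts with a diagnostic. With the prior disabled and
uniform sensitivity, MLEM conserves total counts each iteration and
non-decreases the Poisson log-likelihood — both are asserted in tests.

Numerical choices: images start from a uniform positive field; grids are
centered with the slice count `separation/2.67` rounded *down to odd* so
one slice center lies exactly on the midplane; profiles for PSF fitting
pass through the global maximum voxel (first index wins ties);
back-projection PSF fits include a constant baseline term because
back-projected point images sit on a broad ramp. Gaussian PSF fits use
Levenberg–Marquardt least squares with moment-based starts;
`FWHM = 2√(2 ln 2)σ` and `FWTM = 2√(2 ln 10)σ` (ratio 1.8226). The
cosmetic hotspot post-processing (Gaussian blur σ = 1 px + unsharp mask
σ = 7 px, weight 0.6) is provided for display parity but excluded from
every quantitative assertion.

## Count-rate analysis and the scatter-tail band

Per frame, prompts are all accepted events. Transverse (Y) profiles of
the rebinned frame are aligned on their maxima; counts outside a band
around the peak, plus a linear interpolation of the band-edge levels
under the peak, estimate scatter+randoms. The scatter fraction is taken
from the lowest-activity quartile of frames (randoms negligible there),
randoms per frame follow from `R = P − T/(1 − SF)`, and `NECR = T²/P`.

The rat-phantom analysis tradition uses a ±7 mm band, sized for ring
scanners where scattered LORs rebin far from the source. In a close
planar geometry the trues ridge is only ≈ 2.3 mm FWHM wide and scatter
stays much nearer the line, so the band default here is ±5 mm, validated
against the simulator's ground-truth labels: across all angle allowances
the estimator then agrees with the label-derived scatter fraction to
within about 2 percentage points (the ±7 mm band under-reads by 3–5
points in this geometry; it remains selectable via `band_mm`). The
estimator has a floor of roughly 1–2 % in a scatter-free acquisition:
trues emitted off the midplane rebin slightly off-peak through oblique
LORs and feed the band-edge interpolation.

## Problem sizes and determinism

Every stochastic operation takes an explicit seed and restores the
caller's RNG state; identical configuration and seed reproduce list-mode
files byte-for-byte, and `run_pipeline()` records seeds, config and file
digests in a run manifest. The shipped protocol sizes are chosen so the
whole characterization runs on a laptop-class machine: 10⁵ decays per
scan position (113 positions) for sensitivity, ≈ 10⁵ prompts for a
resolution point source reconstructed on a 128 × 128 × 29 grid of
0.2 mm × 2.67 mm voxels, count-rate series with per-frame decay caps
(caps shorten the effective acquisition rather than bias the rates), and
a few × 10⁶ decays for the hotspot phantom. Statistical assertions in the
test suite are sized to ≥ 3–5 standard errors at these scales.

## Known limitations

* Absolute count-rate magnitudes, dead time and randoms levels are
  calibration-dependent (no published electronics constants); only
  structure and estimator consistency are claimed.
* The positioning blur is a single isotropic Gaussian; real Anger
  readouts have position-dependent resolution and edge compression
  beyond the simple clamping used here.
* Single-scatter-only transport underestimates the true scatter
  fraction of a real acquisition; scatter-fraction claims are about the
  estimator versus labeled truth, not about absolute scatter levels.
* Cross-plane (Z) resolution depends strongly on the angle-allowance
  aperture; the shipped 60 mm imaging default reproduces the 2–3×
  in-plane/cross-plane anisotropy but other allowances will shift the
  absolute Z widths.
* `anger_position()` is exercised by its own light-sharing fixture; the
  main pipeline positions events from exact intercepts plus blur, since
  the multiplexing happens in hardware upstream of list mode.
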