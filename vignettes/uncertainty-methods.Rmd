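---
title: "A deterministic dose engine for preclinical proton uncertainty budgets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A deterministic dose engine for preclinical proton uncertainty budgets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protonuq)
```

## Scope and model

`protonuq` quantifies how individual uncertainty sources on a 68 MeV
preclinical proton line move three observables — the plateau dose, the
proton range R80 and the homogeneity index HI98 — and combines them into a
quadrature budget. Condensed-history Monte Carlo transport is deliberately
out of scope: the engine is a deterministic central-axis model whose
absolute peak-depth accuracy is specified as ±0.5 mm, while the
*sensitivities* to I-values, thicknesses, densities and HU — the
quantities the budget is made of — are carried exactly by the underlying
physics.

### Stopping power and range

Protons of kinetic energy 1–250 MeV are described by the relativistic
Bethe mass stopping power without shell, density-effect or Barkas
corrections; those omissions are below 1% above a few MeV and cancel
almost entirely in the deltas the pipeline reports. The CSDA range is the
integral of the inverse stopping power from a 1 MeV cutoff, plus a fixed
sub-cutoff residual of 0.0025 g/cm² (the fine-grid value for water;
sub-cutoff transport is irrelevant for plateau metrics). Ranges and their
inverses are cached as monotone (Hyman) splines on a 4000-point
log-energy grid; the test suite holds both against a brute-force adaptive
quadrature oracle to 0.5% over 5–70 MeV. Compound I-values come from the
Bragg additivity rule (electron-weighted mean of log I); measured values
override it where the study provides them (water 78±2 eV, aluminum
166±2 eV, tungsten 727±30 eV, Kapton 79.6±4.8 eV, air 85.7±5.1 eV;
tissues carry the ±6% default).

### Beamline transport

The component stack — Kapton window, optional 51.7 µm tungsten scattering
foil, two aluminum monitor foils, a copper ionization-chamber foil and a
2.5 cm aluminum collimator, target entrance at 169.50 cm — is transported
slab by slab: the mean energy follows the range equation (exactly
additive over slab splits), Bohr energy-straggling variance and Highland
scattering angles accumulate in quadrature. Every gap not listed as a
component is filled with air at 1.205 mg/cm³; this air drift dominates
the ~1.9 MeV (2.8%) energy loss of the line. The second moment of lateral
spread at the collimator plane, `sigma_spot² + Σ (θ_i D_i)²` over the
upstream scatterers with lever arms `D_i`, sets a relative on-axis
fluence amplitude `∝ 1/σ²`: this is what makes the plateau dose drop when
the tungsten foil thickens (≈ −4.6% for +5% thickness, against the
reported ±3.5%) while leaving the range untouched.

### The fluence phenomenology and its calibration

No beam-optics information (divergence, focus, halo) is available for the
line, yet two printed observables constrain the on-axis fluence behind
the collimator: the plateau dose falls by 4.4%/cm (with scatterer) or
1.4%/cm (without) when the target moves downstream, and the plateau is
homogeneous (HI98 ≤ 0.12) over 20 mm of water without the scatterer and
15 mm with it — despite a ~40% rise of the stopping power over 20 mm.
The engine therefore uses a two-parameter phenomenology,

F(z) = (L / (L + d₀ + z))² · [1 − exp(−a² / 2σ(z)²)], σ(z) = σ₀ + m·z,

an inverse-square term with effective source distance `L` anchored at the
collimator exit, and an in-field erosion term in which the lateral spread
grows with depth *inside the target*. `L` is rooted (per configuration)
so a +1 cm target shift reproduces the printed per-cm sensitivity
exactly; `m` is rooted so the dose at the end of the configuration's
usable window equals the entrance dose. Because erosion depends only on
in-target depth, the two calibrations decouple. The fitted erosion rates
(≈ 0.032–0.035 mm/mm) exceed the Highland angular spread of the beam in
air (6–12 mrad) several-fold: the physical in-air divergence cannot
produce the observed flatness, so the rate is an effective constant
fitted to the combined observable, not a scattering prediction. `σ₀` is
fixed at 2.5 mm. The resulting HI98 values (0.036 over 20 mm without the
scatterer, 0.013 over 15 mm with it, computed by the acceptance script)
are outcomes of this calibration, not inputs.

### Bragg curves

Dose-to-water is computed in water-equivalent (WE) depth: the energy
deposited per 0.05 mm cell is the exact difference of the range–energy
relation at the cell boundaries (this preserves the integrable peak
singularity, which is what makes R80 insensitive to range spread); range
straggling — Bohr accumulation in the medium plus the beamline's
straggling mapped through 1/S — is a Gaussian blur in residual-range
space; nuclear removal is an exponential survival with a 100 cm (water)
mean free path, i.e. ~1%/cm. R80 and HI98 move by less than 0.05 mm and
0.02 under ±50% changes of that constant (tested). Source energy spread
is a 9-node Gauss–Hermite mixture of monoenergetic curves, each
transported through the stack; doubling the nodes changes the metrics by
under 0.1% (tested). Heterogeneous columns map geometric depth to WE
depth through per-voxel relative stopping powers at the entrance energy
and resample the WE-space dose back to the geometric 0.2 mm grid, so an
all-water column reproduces the water tank bit-for-bit.

A deliberate property of this construction, confirmed against an
independent power-law convolution oracle: the *dose maximum* of the
blurred curve sits about 0.9σ (≈ 0.4 mm) proximal to the CSDA range,
while the distal 80% point sits at the range itself. With the full air
fill mandated for the unlisted gaps, the engine's mean energy at the
target is 66.06 MeV and the peak lands at 36.49 mm (no scatterer) /
35.99 mm (with), against published values of 37.1 / 36.3 mm. The
published depths, together with the line's own "about 2%" energy-loss
statement, are consistent with ~0.6 MeV less air-equivalent material than
the full air fill provides; since the gap composition is not printed, the
air-fill assumption is kept and the residual ~0.5 mm offset is accepted
as the engine's absolute-depth accuracy. The with/without-scatterer
difference (0.50 mm) and all sensitivities are unaffected.

## Synthetic phantoms

The generator emulates what the imaging chain delivers, not how it
images: deterministic (seeded) parametric anatomies on 0.2 mm isotropic
grids. The head is a soft-tissue ellipsoid in a 0.6 mm bone shell (16 mm
across the beam); the thorax (20 mm) holds two textured −520 HU lung
lobes and bone rib studs; the abdomen (25.6 mm) is soft tissue with
randomized −800 HU gas pockets. All tissue regions carry mild voxel
noise so block-mean grid degradation (0.4 / 0.8 mm) produces realistic
partial-volume behaviour; pooling conserves total HU exactly. The ±40 HU
budget scenario is a uniform whole-image offset — the conservative
reading of modifying the images "in the range of ±40 HU" — with a
voxelwise mode available for exploration.

HU→material conversion uses five classes (air, lung, adipose,
water-equivalent soft tissue, bone) with the standard single-ramp density
calibration (ρ = 1 + HU/1000 below water, floored at air; slope
6×10⁻⁴ g/cm³ per HU above), anchored exactly at HU 0 → water,
1.000 g/cm³. This replaces a 125-tissue interpolated table that is not
published; the consequence, stated openly, is a steeper density-per-HU
response, so the ±40 HU range shift on the synthetic mouse (~±0.7 mm)
overshoots the published ±0.3 mm while its direction (+HU ⇒ shorter
range) and its non-significance for dose and HI98 are reproduced. What
passing phantom tests demonstrate is therefore the *machinery* —
conversion, resampling, WE mapping, metric extraction and significance
classification — not agreement with any real mouse's numbers, which
depend on the real CBCT and tissue table.

## Metrics, significance and the budget

Plateau dose is the mean over the target region (the study does not say
point or region; budget entries move by <0.3 percentage points under the
alternative). R80 interpolates the distal 80% crossing linearly; the
peak position refines the grid maximum with a 3-point parabola. HI98
uses linear-interpolation percentiles of the axial samples (D2 = 98th,
D98 = 2nd, D50 = 50th), held against a sort-based oracle to 1e-12.
Significance follows the stated wording literally: range deltas under
0.2 mm are null (strict), dose deltas at or under 1.0% (inclusive), HI98
deltas under 0.02 (strict).

Per-source magnitudes enter the budget either from the engine
(`run_scenario()`: max |delta| over the perturbation values, and over
the brain/lungs/abdomen localizations for CT-related sources, zeroed
when NS) or in *literature mode* (`literature_budget()`), the published
per-source table. The quadrature layer is the same for both; the
shipped Table-3 twin uses literature mode so its arithmetic —
commissioning 2.0% ⊕ thickness ⊕ position ⊕ setup = 6.5%/5.3% raw,
2.0 ⊕ setup = 4.8%/2.4% commissioned, and range totals 0.7 mm (mice,
excluding the water-I entry) / 0.2 mm (biological samples, excluding
CT-dependent entries) — is testable independently of engine calibration.
Two engine-computed entries are worth flagging: the water I-value range
sensitivity comes out at ±0.13 mm, just below the 0.2 mm significance
floor that equals the published table's quantization, and the
component-position dose entry is dominated by the collimator–target
geometry, so the engine cannot reproduce the published 2.7%/4.7%
ordering, which must reflect unprinted beam optics.

## Problem sizes and numerical choices

All computations are desk-scale: 0.05 mm internal / 0.2 mm scoring
grids over ≤ 65 mm of depth, phantoms of 0.3–0.8 M voxels, spline-cached
range tables, and a one-off fluence calibration (two univariate roots,
cached per configuration). The full test suite runs in ~20 s and the
acceptance script in a few seconds on one core. Ties in percentile
computation are immaterial after interpolation; degenerate inputs
(zero-length media, shoot-through profiles, stops-in-slab transport,
out-of-domain HU or energies) raise typed errors rather than silent
extrapolation.

## Known limitations

* Central axis only: no lateral profiles, 3-D dose grids, or secondary
  transport; the beam spot FWHM is recorded but unused on axis.
* The fluence model is a calibrated phenomenology; it reproduces the
  observables it was fitted to (setup sensitivity, plateau flatness) and
  the tungsten-thickness direction, but is not predictive for arbitrary
  geometry changes, and absolute peak depth carries the ~0.5 mm offset
  discussed above.
* Five tissue classes with a linear density ramp, not a measured
  stoichiometric table; spread-out Bragg peaks, RBE/LET and dose-rate
  effects are out of scope.
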