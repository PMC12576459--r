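---
title: "ctdosim: model, assumptions, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ctdosim: model, assumptions, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ctdosim` estimates organ absorbed doses in abdominal CT by Monte Carlo
photon transport over voxel phantoms, with tube current modulation (TCM)
represented as per-projection weighting factors mined from the DICOM
headers of reconstructed images. This vignette records the model, its
assumptions, the tunable parameters, and the numerical decisions that a
maintainer would otherwise have to reverse-engineer.

## 1. Source model

**Spectrum.** The tube spectrum is a Kramers-type bremsstrahlung
baseline, $N(E) \propto (E_0 - E)/E$ in uniform 0.5 keV bins spanning
(5, kVp] keV, plus tungsten K characteristic lines (57.98, 59.32, 67.2,
69.1 keV) folded into their bins with a fixed 8% fluence share when the
tube voltage exceeds the K edge. Inherent filtration (1.2 mm Al) and a
target-angle-dependent self-filtration term shape the low-energy end.
This baseline is deliberately simple: the only beam-quality constraint a
scanner provides in practice is the measured first half-value layer
(HVL), and `calibrate_filtration()` forces the model to reproduce it by
bisecting the added aluminum filtration on [0, 20] mm until the HVL of
the generated spectrum matches the measurement within 0.01 mm. The
default target is 7.56 mm Al at 120 kVp, which calibrates to about
7.5 mm of added aluminum and a mean energy near 62 keV. Any spectrum
model with the correct HVL produces very similar dose ratios at
diagnostic energies; absolute output is fixed separately by
normalization (section 5).

**HVL definition.** A half-value layer is defined on air-kerma-weighted
transmission, $K(t) = \sum_i \Phi_i E_i (\mu_{en}/\rho)_{air}(E_i)
e^{-\mu_{Al}(E_i) t}$, matching what a pencil ionization chamber
measures; bisection stops at a relative kerma error of $10^{-8}$.

**Bowtie filter.** The bowtie enters as a multiplicative statistical
weight $e^{-\mu_{Al}(E)\, t(\theta)}$ on each emitted photon, where
$t(\theta)$ is an equivalent aluminum thickness versus fan angle. A
parametric body-bowtie profile ships as an editable CSV;
`bowtie_from_fixed_tube_measurements()` builds a profile from
user-measured exposure ratios via $t = -\ln(r)/\mu_{Al,eff}$ at
$\theta = \arctan(y/\mathrm{SID})$. Weighting (rather than rejection)
was chosen because it preserves the photon budget per projection
exactly, which the TCM weighting scheme assumes.

**Geometry.** Source at SID 62.6 cm from isocenter, 47° full fan, beam
width 80 mm at isocenter. Gantry angle 0° is 12 o'clock; rotation is
clockwise viewed from the feet (dose to the symmetric phantoms used for
validation is insensitive to the direction, so it is a convention, and
the start angle is an explicit parameter because surface organs are
sensitive to it). The collimator is a perfect aperture: photons are
emitted only inside the fan/cone; collimator penetration and scatter are
ignored. One rotation is discretized into 40 projections at 9° steps;
helical schedules advance the table by pitch × beam width per rotation
and use a ceiling rule for the projection count so the scheduled range
covers the full scan length (175 mm at pitch 0.508, 80 mm beam → 173
projections). Over-ranging beyond the scheduled range is out of scope.

## 2. Transport physics

Photon-only analog Monte Carlo with local deposition of transferred
energy (collision kerma). Secondary electrons are not tracked: at
≤120 keV their ranges are below the voxel scale, so charged-particle
equilibrium justifies depositing the electron energy at the interaction
site. Photons are terminated below 5 keV, depositing their remaining
energy locally, or on leaving the grid.

* **Path sampling** uses Woodcock (delta) tracking against a global
  per-energy majorant cross-section — exact in heterogeneous voxel
  grids with no surface-crossing logic. Voxel lookup guards the box
  bounds explicitly before integer truncation (truncation-toward-zero
  of slightly negative coordinates is a classic off-by-one-voxel trap).
* **Compton** scattering is free-electron Klein–Nishina, sampled with
  Kahn's composition-rejection method; the scattered energy follows the
  Compton relation and $E - E'$ is deposited on the spot. No Doppler
  broadening or binding.
* **Rayleigh** scattering deflects with the Thomson
  $(1 + \cos^2\theta)$ distribution and deposits nothing. Form-factor
  anisotropy is ignored; at these energies Rayleigh mainly smears the
  primary beam slightly.
* **Photoelectric** events absorb the photon locally; fluorescence is
  ignored (K-edge photons of tissue elements fall below the 5 keV
  cutoff anyway).
* **Pair production** is impossible below 1.022 MeV and is not
  implemented.

**Kerma-consistent cross-section split.** Total attenuation
$\mu/\rho(E)$ per material comes from bundled NIST-style grids
(log-log interpolated; mixtures by mass-fraction additivity). The split
into channels is derived, not tabulated: incoherent = Klein–Nishina
cross-section × electrons per gram; photoelectric is then chosen so
that the *expected deposited energy per unit path matches the tabulated
mass energy-absorption coefficient*,
$\mu_{pe} = \mathrm{clamp}(\mu_{en} - \mu_{incoh}\bar f_{KN}(E))$, with
$\bar f_{KN}$ the mean Klein–Nishina energy-transfer fraction; coherent
is the remainder. A naive split (photoelectric as the residual after KN
and a form-factor coherent term) was tried first and made analog
deposition disagree with $\mu_{en}$ by tens of percent below 60 keV,
because free-electron KN overestimates incoherent scattering there.
With the kerma-consistent split the two estimators below agree within a
few percent over the calibrated spectrum, which is the accuracy claim
of a photon-only kerma engine — individual channel coefficients are
approximate, their energy-weighted sum is anchored to the tables.

**Two dose estimators.** Every run scores (a) *analog* energy actually
deposited per voxel and per region — this satisfies the exact invariant
"region dose = Σ voxel energy / region mass" and strict energy
conservation per history; and (b) a *track-length (collision) kerma*
estimator: at every Woodcock collision point (real or fictitious) the
score $w E (\mu_{en}/\rho) \rho / \Sigma_{maj}$ is added to the voxel's
region. The kerma estimator is unbiased and has orders of magnitude
lower variance in thin media, where analog interactions are rare; it is
what makes CTDI chamber bores (air cavities) and the free-in-air
calibration tractable at desk-scale photon budgets. A configurable
majorant floor (default 0.05 cm⁻¹) inflates the majorant in thin media
to plant extra, unbiased collision points; it does not affect phantoms
whose majorant already exceeds it. Dosimetry pipelines use the kerma
estimator; the analog tally drives the dose maps and the conservation
checks.

**Reproducibility.** Each projection uses its own Mersenne-Twister
stream seeded `base_seed + projection index`; identical seeds give
bit-identical tallies, and projections can be reproduced in isolation.
Uncertainties come from batch statistics (default 10 batches): standard
error of batch means over the grand mean.

## 3. Voxel phantoms

CT volumes are converted with a piecewise HU calibration in the style
of stoichiometric CT-to-material mappings: contiguous HU bins, each
with a catalog material and a density linear in HU. The bundled table
(editable CSV) uses six bins — air, lung, adipose, soft tissue, a
50/50 soft-tissue/cortical-bone transitional mix, cortical bone — with
a continuous density line (1.030 + 0.001·HU in the soft-tissue range),
monotone over the full sweep. The exact bin count of published
calibrations varies by implementation; correctness here is enforced
through invariants (coverage, monotone density, purity) rather than
specific bin values, and the CSV is a user-serviceable part.

Coarse-graining averages HU and density in blocks (default 4 × 4 × 1,
0.68 → 2.72 mm in-plane at 5 mm slices) and re-bins the *block-mean HU*
to pick the block material, keeping material and density consistent;
block labels take the modal nonzero label. Mass is conserved to
rounding because the block mean preserves it by construction;
non-divisible dimensions are padded with air and flagged.

The built-in phantoms:

* `make_ctdi_phantom()` — 32 cm diameter, 15 cm long PMMA cylinder
  (ρ = 1.19 g/cm³) with five air bore channels (center + 12/3/6/9
  o'clock at 1 cm depth, the universal CTDI phantom layout); labels
  mark the central 100 mm of each bore, the pencil-chamber active
  length.
* `make_air_phantom()` — free-in-air chamber at isocenter for the
  CTDI_air calibration run.
* `make_synthetic_abdomen()` — elliptic-cylinder soft-tissue body
  (default 300 × 200 mm, 175 mm long) with six labeled ellipsoidal
  organs (liver, stomach, gallbladder, spleen, pancreas, paired
  kidneys), a cortical-bone vertebral column, and air-filled lung bases
  at the cranial end. Organ positions approximate adult anatomy at the
  sizes needed for stable tallies; the seed jitters centers by ±2 mm.
  Overlap is resolved by fixed precedence (lung, bone, then organs in
  a fixed order; first label wins), so labels are disjoint by
  construction and organ volumes stay within 5% of their analytic
  ellipsoid values at the default grid.

The patient table (carbon-fiber shell, ρ 1.6 g/cm³, over a foam core,
ρ 0.015 g/cm³) is stamped into the voxel grid below the phantom. Shell
thickness defaults to 2 mm but is quantized to the voxel size — at
coarse grids the shell is thicker than nominal, which overstates table
attenuation somewhat; use a finer y-spacing when the 6 o'clock reading
matters.

## 4. TCM profiles and weighting

`extract_tube_currents()` reads one (z, mA) sample per reconstructed
slice from tag (0018,1151), falling back to Exposure/rotation-time if
absent, sorted by z with same-z duplicates averaged.
`per_rotation_average()` folds samples into windows of one table feed
(pitch × beam width) anchored at the first slice (configurable, since
the true tube start position is unknown), averaging mA per window —
this collapses angular modulation into the rotation mean, a
longitudinal approximation that validation studies place within a few
percent for abdominal anatomy. Empty windows are interpolated and
flagged. `projection_weights()` assigns each projection an mA by linear
interpolation of rotation means at its z (piecewise-constant is
available by flag), clamps projections outside the reconstructed range
to the nearest rotation (over-ranging mA is simply absent from image
headers), and normalizes so the weight mean is exactly 1 — the total
simulated particle count is unchanged, modulation only re-shapes the
dose. The absolute scale travels separately as effective mAs per
projection (mean mA × rotation time / projections per rotation).
Because per-projection region sub-tallies are stored, re-weighting is
an exact dot product; this linearity is asserted, not approximated, in
the tests.

## 5. Normalization and dosimetry

Tallies are Gy per source photon. The free-in-air calibration run
(axial, 120 kVp, 100 mA, 1 s, 80 mm beam) mirrors a chamber CTDI_air
measurement; the normalization factor NF = measured / simulated
converts per-photon doses to mGy at the calibration mAs, and a protocol
scales further by its total effective mAs / calibration mAs. CTDI_100 is
(1/NT)·∫D(z)dz over the 100 mm chamber (mean chamber dose × 100/NT for
a flat tally); CTDI_w = center/3 + 2·periphery-mean/3. The
glass-dosimeter equations (correction factor C = K_chamber/K_dosimeter;
organ dose = mean (M_i − M_b)·C·(μen/ρ)ratio at the HVL-derived
effective energy) are provided for the measurement side of a
validation. Comparison metrics are the signed relative difference
(sim − meas)/meas × 100 and the dose reduction (fixed − TCM)/fixed ×
100, both recomputable exactly from any stored report.

## 6. What the synthetic fixtures do and do not establish

`make_fixture_series()` renders standards-conformant DICOM slices
(explicit VR little endian, written by the package's own minimal codec
because no DICOM library is available in the target environment) from
the synthetic abdomen: pixel data are nominal HU plus Gaussian noise
(σ = 8 HU), headers carry per-slice tube current profiles (constant,
ramp, or a smooth bump emulating longitudinal modulation around a
chosen mean), and UIDs derive from the seed so a series is
byte-reproducible. This exercises the full pipeline — header mining,
phantom building, weighting, transport — with no external data.

Green tests on these fixtures establish internal correctness: schedule
arithmetic, estimator exactness, sampling distributions against closed
forms, HU round-trips, and the *ordering and ratio structure* of doses
(fixed > higher-noise-index > lower-dose profiles; table attenuation at
6 o'clock; peripheral bore symmetry). They do not establish absolute
agreement with a physical scanner: that requires the user's measured
HVL, bowtie ratios, and CTDI_air, and a phantom derived from real CT
data. The synthetic abdomen has idealized organs and no angular mA
variation beyond the rotation mean; real-patient uncertainty will be
dominated by anatomy and by the unknown tube start angle, both exposed
as parameters rather than guessed.

## 7. Default parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| kVp | 120 | kV | abdominal protocol standard |
| target angle | 10 | deg | manufacturer-typical anode angle |
| first HVL | 7.56 | mm Al | measured beam-quality anchor |
| SID / SDD | 62.6 / 110 | cm | scanner data sheet values |
| fan angle | 47 | deg | scanner data sheet value |
| beam width | 80 | mm | wide-cone abdominal collimation |
| projections/rotation | 40 (9° steps) | — | angular discretization; dose converges well before 40 |
| pitch | 0.508 | — | protocol value; feed 40.64 mm |
| rotation time | 0.5 | s | protocol value |
| scan length | 175 | mm | abdominal range |
| slice thickness (TCM mining) | 0.625 | mm | thin recon gives dense mA sampling |
| cutoff | 5 | keV | photon-mode cutoff; sub-range of any tissue voxel |
| majorant floor | 0.05 | 1/cm | kerma-estimator support in air; no effect in tissue |
| calibration CTDI_air | 12.0 | mGy/100 mAs | representative wide-cone scanner output; user-replaceable measured scalar |
| batches | 10 | — | batch-statistics uncertainty |

## 8. Known limitations

No electron transport, fluorescence, Doppler broadening, or bound
Compton corrections; channel-level cross sections are approximate by
design (section 2) while their energy-weighted sum is table-anchored.
No over-ranging, gantry tilt, focal-spot size, or detector model. The
start angle of a physical scan is generally unknown and materially
affects surface organs (kidneys); it is a parameter, not a prediction.
Angular TCM is folded into rotation means. The DICOM codec reads
explicit-VR little-endian only.
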