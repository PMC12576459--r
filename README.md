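# ctdosim

Monte Carlo organ dosimetry for abdominal CT, with tube current
modulation (TCM) taken from the DICOM headers of the reconstructed
images.

## The problem

Organ absorbed dose in CT depends on the scanner (spectrum, bowtie
filter, gantry geometry), the protocol (kVp, mAs, pitch, collimation),
and — under TCM — on how the tube current varied while the table moved.
Modern scanners modulate the current per rotation and per angle, so a
fixed-mAs dose estimate can be wrong by a factor of several. The raw
modulation data live in proprietary projection data or service logs, but
a usable longitudinal summary is sitting in plain sight: every
reconstructed slice header carries the tube current used at its
position (tag 0018,1151). `ctdosim` turns that header trail into
per-projection weighting factors for a photon Monte Carlo simulation
over a voxel phantom, and provides the dosimetry toolkit (CTDI_100,
CTDI_w, free-in-air normalization, organ dose reports) needed to
validate the model against ionization-chamber and glass-dosimeter
measurements.

It is intended for medical physicists who want protocol-specific organ
doses from routine CT images without vendor assistance, and it ships
synthetic DICOM/phantom generators so the entire pipeline is testable
with no external data.

## The model

* **Spectrum** — Kramers-type 120 kVp tungsten bremsstrahlung plus K
  characteristic lines in 0.5 keV bins, with added aluminum filtration
  calibrated so the first half-value layer equals the measured one
  (default 7.56 mm Al). The HVL is evaluated as air-kerma-weighted
  transmission, matching a pencil-chamber measurement.
* **Gantry** — source at 62.6 cm from isocenter, 47° fan, 80 mm
  collimated beam, 40 projections per rotation at 9° steps; helical
  schedules advance the table by pitch x beam width per rotation (175 mm
  at pitch 0.508 gives 173 projections). The bowtie filter enters as an
  energy-dependent statistical weight; the carbon-fiber/foam patient
  table is stamped into the voxel grid.
* **Transport** — photon-only analog Monte Carlo with Woodcock (delta)
  tracking, free-electron Klein–Nishina Compton sampling (Kahn's
  method), Thomson-distributed Rayleigh scattering, a 5 keV cutoff, and
  local deposition of transferred energy (collision kerma, valid under
  charged-particle equilibrium at diagnostic energies). Region doses are
  also scored with a low-variance track-length kerma estimator —
  essential for air cavities such as CTDI chamber bores.
* **Phantoms** — CT volumes become voxel phantoms through a piecewise
  HU → (material, density) calibration, optionally coarse-grained in
  4 x 4 x 1 blocks (0.68 → 2.72 mm in plane); the standard 32 cm PMMA
  CTDI phantom and a labeled synthetic abdomen are built in.
* **TCM** — per-slice tube currents are averaged per rotation window
  against table position, interpolated at each projection's z, and
  converted to weights with mean exactly 1 (constant total particle
  count); the absolute scale (effective mAs) is applied at
  normalization, where simulated per-photon doses are anchored to a
  measured free-in-air CTDI.

## Worked example

CTDI validation of the scanner model (desk-scale photon budget):

```r
library(ctdosim)
geom <- scanner_geometry()                  # 62.6 cm SID, 47 deg fan, 80 mm beam
sp   <- calibrated_spectrum(120, 10, 7.56)  # HVL forced to 7.56 mm Al
air  <- simulate_ctdi_air(geom, sp, default_bowtie(), 20000, seed = 2)
nf   <- normalization_factor(12.0, air$ctdi_air_per_photon)
pmma <- simulate_ctdi_pmma(geom, sp, default_bowtie(), 20000, seed = 1)
round(pmma$ctdi100_per_photon * nf, 2)
#> center    o12     o3     o6     o9
#>   2.63   7.52   7.70   6.65   7.61
round(pmma$ctdi_w_per_photon * nf, 2)
#> [1] 5.79
```

The five numbers are CTDI_100 in mGy per 100 mAs at the center and the
12/3/6/9 o'clock bores of the 32 cm PMMA phantom, normalized to a
measured free-in-air CTDI of 12 mGy; the 6 o'clock bore reads low
because the beam crosses the patient table. CTDI_w combines them as
center/3 + 2 x periphery mean/3. Beam-quality scalars derived from the
same calibrated model:

```r
effective_energy(7.56)                                   # 52.7 keV
muen_ratio("soft_tissue", "air", effective_energy(7.56)) # 1.051
```

Worked-example arithmetic on published dose tables:

```r
ctdi_w(3.59, c(7.75, 7.70, 6.87, 7.71))   # 6.20 mGy (measured column)
ctdi_w(3.67, c(7.92, 7.86, 7.41, 7.88))   # 6.40 mGy (simulated column)
dose_reduction_percent(33.3, 11.6)        # 65.2 % (liver, NI 9)
```

End-to-end organ doses (synthetic abdomen, TCM from a generated DICOM
series) are exercised by the CLI:

```sh
exec/ctdosim make-fixtures --out run --shape bump --mean-ma 109 --seed 4
exec/ctdosim extract-tcm --dicom run/dicom --out run
exec/ctdosim simulate --mode tcm --dicom run/dicom --out run --seed 2
```

## Layout

* `R/`, `src/` — implementation (spectrum, geometry, phantoms, Rcpp
  transport engine, TCM, dosimetry, DICOM codec, CLI, fixtures)
* `inst/extdata/` — attenuation grids, material catalog, HU calibration,
  default bowtie profile (editable CSV)
* `vignettes/ctdosim-methods.Rmd` — model assumptions, numerical
  choices, and what the synthetic fixtures do and do not establish
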