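# End-to-end orchestration: CTDI validation runs, free-in-air
# normalization, and organ-dose simulation with or without TCM.

#' Simulate the free-in-air calibration run
#'
#' One axial rotation onto the free-in-air chamber phantom under the
#' calibration protocol (120 kVp, 100 mA, 1 s, 80 mm beam, non-helical),
#' mirroring the CTDI_air measurement. Returns the chamber CTDI_air in
#' Gy per source photon (chamber dose x 100 / beam width).
#'
#' @param geometry a `scanner_geometry` (the table is ignored: the
#'   chamber hangs free in air).
#' @param spectrum an `xray_spectrum`.
#' @param bowtie a `bowtie_profile`.
#' @param n_photons_per_projection histories per projection.
#' @param seed base seed.
#' @return list with `ctdi_air_per_photon` (Gy/photon), `tally`.
#' @export
simulate_ctdi_air <- function(geometry, spectrum, bowtie,
                              n_photons_per_projection = 20000,
                              seed = 1L) {
  ph <- make_air_phantom()
  prot <- scan_protocol(mode = "axial", tube_current_ma = 100,
                        rotation_time_s = 1)
  tal <- run_scan(ph, geometry, prot, spectrum, bowtie,
                  n_photons_per_projection, base_seed = seed)
  dose <- region_dose(tal)
  chamber <- dose$dose_gy_per_photon[dose$region == "chamber"]
  list(ctdi_air_per_photon = ctdi100_from_tally(chamber,
                                                geometry$beam_width_mm),
       tally = tal)
}

#' Simulate CTDI100 in the standard PMMA body phantom
#'
#' One axial rotation onto the 32 cm CTDI phantom (with the patient
#' table unless the geometry says otherwise); returns per-bore CTDI100
#' in Gy per source photon plus CTDIw.
#'
#' @inheritParams simulate_ctdi_air
#' @param phantom optionally a pre-built CTDI phantom.
#' @param with_table stamp the geometry's table under the phantom.
#' @export
simulate_ctdi_pmma <- function(geometry, spectrum, bowtie,
                               n_photons_per_projection = 20000,
                               seed = 1L, phantom = NULL,
                               with_table = TRUE) {
  if (is.null(phantom)) phantom <- make_ctdi_phantom()
  if (with_table && !is.null(geometry$table))
    phantom <- add_table(phantom, geometry$table)
  prot <- scan_protocol(mode = "axial", tube_current_ma = 100,
                        rotation_time_s = 1)
  tal <- run_scan(phantom, geometry, prot, spectrum, bowtie,
                  n_photons_per_projection, base_seed = seed)
  dose <- region_dose(tal)
  bores <- c("center", "o12", "o3", "o6", "o9")
  d <- setNames(dose$dose_gy_per_photon[match(bores, dose$region)], bores)
  ctdi100 <- vapply(d, ctdi100_from_tally, 0,
                    beam_width_mm = geometry$beam_width_mm)
  list(ctdi100_per_photon = ctdi100,
       ctdi_w_per_photon = ctdi_w(ctdi100["center"], ctdi100[2:5]),
       uncertainty = setNames(dose$rel_uncertainty[
         match(bores, dose$region)], bores),
       tally = tal)
}

#' Simulate organ doses for a scan protocol
#'
#' Runs the helical schedule over the phantom, optionally weighted by a
#' TCM profile, and converts region tallies to absolute organ doses via
#' the free-in-air normalization factor and the protocol's effective
#' mAs.
#'
#' @param phantom a labeled `voxel_phantom`.
#' @param geometry,protocol,spectrum,bowtie scan model objects.
#' @param tcm_profile a `tcm_profile`, or NULL for fixed tube current.
#' @param nf normalization factor: measured CTDI_air (mGy at the 100 mAs
#'   calibration) / simulated CTDI_air (Gy per source photon).
#' @param calibration_mas mAs of the calibration rotation (default 100).
#' @param n_photons_per_projection histories per projection.
#' @param base_seed seed for projection 1.
#' @param z0_mm table z of the first projection in phantom coordinates.
#' @param with_table stamp the geometry's table under the phantom.
#' @return list with `report` (a `dose_report`), `tally`, `weights`,
#'   `total_mas`.
#' @export
simulate_organ_doses <- function(phantom, geometry, protocol, spectrum,
                                 bowtie, tcm_profile = NULL, nf = 1,
                                 calibration_mas = 100,
                                 n_photons_per_projection = 5000,
                                 base_seed = 1L, z0_mm = 0,
                                 with_table = TRUE) {
  if (with_table && !is.null(geometry$table))
    phantom <- add_table(phantom, geometry$table)
  sched <- projection_schedule(protocol, geometry, z0_mm)
  if (!is.null(tcm_profile)) {
    pw <- projection_weights(tcm_profile, sched,
                             rotation_time_s = protocol$rotation_time_s)
    weights <- pw
    mas_per_proj <- pw$mas_per_projection
  } else {
    weights <- NULL
    mas_per_proj <- protocol$tube_current_ma * protocol$rotation_time_s /
      protocol$projections_per_rotation
  }
  tal <- run_scan(phantom, geometry, protocol, spectrum, bowtie,
                  n_photons_per_projection, base_seed = base_seed,
                  weights = weights, z0_mm = z0_mm)
  total_mas <- mas_per_proj * nrow(sched)
  report <- organ_dose_from_tally(tal, nf = nf,
                                  mas_scale = total_mas / calibration_mas)
  list(report = report, tally = tal, weights = weights,
       total_mas = total_mas)
}
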