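# Dosimetry formulas: CTDI100/CTDIw, free-in-air normalization, organ
# dose aggregation, glass-dosimeter (RPLD) equations, and comparison
# statistics.

#' CTDI100 from a chamber tally
#'
#' CTDI100 = (1/NT) * integral of D(z) over the 100 mm chamber, i.e.
#' mean chamber dose x 100 / NT for a scalar mean dose, or the
#' trapezoidal integral divided by NT for a profile.
#'
#' @param dose mean chamber dose (mGy) or a data.frame with columns
#'   `z_mm`, `dose` giving the dose profile along the chamber.
#' @param beam_width_mm total nominal collimation N x T, mm.
#' @param chamber_length_mm integration length, mm (default 100).
#' @return CTDI100, same units as `dose`.
#' @export
ctdi100_from_tally <- function(dose, beam_width_mm,
                               chamber_length_mm = 100) {
  stopifnot(beam_width_mm > 0)
  if (is.data.frame(dose)) {
    z <- dose$z_mm
    extent <- diff(range(z))
    if (abs(extent - chamber_length_mm) > chamber_length_mm * 0.25)
      stop("profile extent does not match the chamber length")
    integral <- sum(diff(z) * (head(dose$dose, -1) + tail(dose$dose, -1)) / 2)
    integral / beam_width_mm
  } else {
    dose * chamber_length_mm / beam_width_mm
  }
}

#' Weighted CTDI
#'
#' CTDIw = (1/3) CTDI100,center + (2/3) mean(CTDI100,periphery).
#'
#' @param center CTDI100 at the phantom center, mGy.
#' @param periphery CTDI100 at the four peripheral bores, mGy.
#' @export
ctdi_w <- function(center, periphery) {
  stopifnot(center >= 0, all(periphery >= 0), length(periphery) == 4)
  center / 3 + 2 / 3 * mean(periphery)
}

#' Normalization factor from measured and simulated CTDI_air
#'
#' NF = measured / simulated, converting per-source-photon tallies under
#' the calibration protocol to absolute dose; downstream doses scale
#' further by (protocol mAs / calibration mAs).
#'
#' @param ctdi_air_measured measured free-in-air CTDI, mGy.
#' @param ctdi_air_simulated simulated value in tally units (e.g. mGy
#'   per source photon, scaled however the caller keeps it — the ratio's
#'   units document themselves).
#' @export
normalization_factor <- function(ctdi_air_measured, ctdi_air_simulated) {
  if (ctdi_air_simulated <= 0) stop("simulated CTDI_air must be positive")
  ctdi_air_measured / ctdi_air_simulated
}

#' Signed percentage relative difference
#'
#' (simulated - measured) / measured x 100.
#'
#' @param simulated,measured doses, same units.
#' @export
relative_difference <- function(simulated, measured) {
  if (any(measured == 0)) stop("measured dose must be nonzero")
  (simulated - measured) / measured * 100
}

#' Percentage dose reduction of a TCM run relative to fixed current
#'
#' (fixed - tcm) / fixed x 100.
#'
#' @param dose_fixed dose under fixed tube current.
#' @param dose_tcm dose under TCM.
#' @export
dose_reduction_percent <- function(dose_fixed, dose_tcm) {
  if (any(dose_fixed <= 0)) stop("fixed-current dose must be positive")
  (dose_fixed - dose_tcm) / dose_fixed * 100
}

#' RPLD correction factor
#'
#' C = K_ic / K_RPLD: ionization-chamber air kerma over the dosimeter's
#' reading under identical free-in-air irradiation.
#'
#' @param k_ic average chamber air kerma, mGy.
#' @param k_rpld average RPLD air kerma, mGy.
#' @export
rpld_correction_factor <- function(k_ic, k_rpld) {
  if (any(k_rpld <= 0)) stop("k_rpld must be positive")
  k_ic / k_rpld
}

#' Organ dose from RPLD readings
#'
#' Mean over dosimeters of (M_i - M_b) * C * (muen/rho)_tissue /
#' (muen/rho)_air, the standard point-dosimeter organ dose equation.
#' When `muen_ratio_tissue_air` is NULL it is evaluated from the bundled
#' tables at the effective energy of the given HVL.
#'
#' @param readings RPLD readings M_i, mGy.
#' @param background background reading M_b, mGy.
#' @param correction correction factor C.
#' @param muen_ratio_tissue_air tissue-to-air mass energy-absorption
#'   ratio; NULL to derive from `hvl_al_mm`.
#' @param hvl_al_mm beam first HVL used to derive the ratio (default
#'   7.56 mm Al).
#' @param tissue catalog material used as "tissue".
#' @export
rpld_organ_dose <- function(readings, background = 0, correction = 1,
                            muen_ratio_tissue_air = NULL,
                            hvl_al_mm = 7.56, tissue = "soft_tissue") {
  if (!length(readings)) stop("no readings")
  if (any(readings < background))
    warning("readings below background")
  if (is.null(muen_ratio_tissue_air))
    muen_ratio_tissue_air <- muen_ratio(tissue, "air",
                                        effective_energy(hvl_al_mm))
  mean((readings - background) * correction * muen_ratio_tissue_air)
}

#' Organ dose report from a scan tally
#'
#' Per-organ absorbed dose = (region energy / region mass) x NF x mAs
#' scale, with the per-organ relative Monte Carlo uncertainty.
#'
#' @param tally a `ct_scan_tally` (or `ct_tally`).
#' @param nf normalization factor (measured / simulated CTDI_air, in
#'   mGy per (Gy/source-photon) at the calibration mAs).
#' @param mas_scale protocol mAs relative to the calibration mAs (e.g.
#'   effective mAs per projection x projections / calibration mAs).
#' @return object of class `dose_report`: data.frame with columns
#'   `organ`, `dose_mgy`, `rel_uncertainty`.
#' @export
organ_dose_from_tally <- function(tally, nf = 1, mas_scale = 1) {
  rd <- region_dose(tally)
  rd <- rd[-1, , drop = FALSE]  # drop the "total" row
  if (any(!is.finite(rd$dose_gy_per_photon)))
    stop("zero-mass or unlabeled organ in tally")
  out <- data.frame(organ = rd$region,
                    dose_mgy = rd$dose_gy_per_photon * nf * mas_scale,
                    rel_uncertainty = rd$rel_uncertainty,
                    row.names = NULL)
  class(out) <- c("dose_report", "data.frame")
  out
}

#' Compare two dose reports (e.g. simulation vs measurement)
#'
#' @param simulated,measured `dose_report`s or data.frames with columns
#'   `organ`, `dose_mgy`.
#' @return data.frame with per-organ doses and signed RD%.
#' @export
compare_doses <- function(simulated, measured) {
  m <- merge(simulated[, c("organ", "dose_mgy")],
             measured[, c("organ", "dose_mgy")], by = "organ",
             suffixes = c("_sim", "_meas"), sort = FALSE)
  m$rd_percent <- relative_difference(m$dose_mgy_sim, m$dose_mgy_meas)
  m
}

#' @importFrom utils head tail
NULL
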