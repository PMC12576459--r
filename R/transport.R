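# Driver for the compiled Monte Carlo engine: per-projection runs, whole
# scan schedules, tallies and batch-statistics uncertainties.

.DEFAULT_CUTOFF_KEV <- 5

# Per-material transport tables on the spectrum's bin-center grid:
# total mu/rho and (photoelectric, coherent) branch fractions, columns
# indexed by catalog material id.
.transport_tables <- function(spectrum) {
  centers <- .bin_centers(spectrum)
  cat <- material_catalog()
  n_mat <- max(cat$id)
  mu_tot <- matrix(0, length(centers), n_mat)
  f_pe <- matrix(0, length(centers), n_mat)
  f_coh <- matrix(0, length(centers), n_mat)
  muen <- matrix(0, length(centers), n_mat)
  for (i in seq_len(nrow(cat))) {
    p <- partial_mu_rho(cat$name[i], centers)
    j <- cat$id[i]
    mu_tot[, j] <- p$total
    f_pe[, j] <- p$pe / p$total
    f_coh[, j] <- p$coh / p$total
    muen[, j] <- muen_over_rho(attenuation_table(cat$name[i]), centers)
  }
  list(mu_tot = mu_tot, f_pe = f_pe, f_coh = f_coh, muen = muen,
       e_lo = spectrum$bin_edges[1], e_step = diff(spectrum$bin_edges)[1])
}

.tally_class <- function(raw, phantom, n_photons) {
  masses <- region_masses(phantom)
  br <- raw$batch_region_kev
  region_kev <- rowSums(br)
  names(region_kev) <- c("total", names(phantom$organ_names)[
    order(phantom$organ_names)])[seq_along(region_kev)]
  structure(list(edep_kev = array(raw$edep_kev, dim(phantom$material_id)),
                 region_kev = region_kev, batch_region_kev = br,
                 region_kerma_kev = setNames(rowSums(raw$batch_kerma_kev),
                                             names(region_kev)),
                 batch_kerma_kev = raw$batch_kerma_kev,
                 n_photons = n_photons, emitted_kev = raw$emitted_kev,
                 uncollided = raw$uncollided, missed = raw$missed,
                 seed = raw$seed, region_masses_g = masses,
                 organ_names = phantom$organ_names,
                 spacing_mm = phantom$spacing_mm),
            class = "ct_tally")
}

#' Run one projection of the Monte Carlo simulation
#'
#' Analog transport of `n_photons` photons emitted from the source at
#' one gantry angle / table position, with Woodcock tracking through the
#' phantom and local deposition of transferred energy. Energy below the
#' 5 keV cutoff is deposited on the spot. Identical seeds give
#' bit-identical tallies.
#'
#' @param phantom a `voxel_phantom`.
#' @param geometry a `scanner_geometry`.
#' @param spectrum an `xray_spectrum`.
#' @param bowtie a `bowtie_profile`.
#' @param gantry_angle_deg,table_z_mm source placement.
#' @param n_photons photon histories (>= 1).
#' @param seed integer RNG seed.
#' @param n_batches batches for the uncertainty estimate (default 10).
#' @param cutoff_kev transport cutoff, keV.
#' @param majorant_floor minimum majorant cross-section, 1/cm. Inflating
#'   the majorant in thin media (air) plants extra collision points for
#'   the track-length kerma estimator at no bias; 0 disables.
#' @return a `ct_tally`: per-voxel deposited energy (keV, weighted),
#'   per-region batch tallies for both the analog-deposition and the
#'   track-length kerma estimators, emitted energy, uncollided-primary
#'   count.
#' @export
run_projection <- function(phantom, geometry, spectrum, bowtie,
                           gantry_angle_deg = 0, table_z_mm = 0,
                           n_photons = 10000, seed = 1L,
                           n_batches = 10,
                           cutoff_kev = .DEFAULT_CUTOFF_KEV,
                           majorant_floor = 0.05) {
  stopifnot(n_photons >= 1)
  tt <- .transport_tables(spectrum)
  src <- .engine_source_pack(spectrum, bowtie, geometry,
                             gantry_angle_deg, table_z_mm)
  raw <- cpp_run_projection(
    as.integer(phantom$material_id), as.numeric(phantom$density),
    dim(phantom$material_id), phantom$spacing_mm, phantom$origin_mm,
    as.integer(phantom$organ_label),
    max(0L, phantom$organ_label), tt$mu_tot, tt$f_pe, tt$f_coh,
    tt$muen, tt$e_lo, tt$e_step, src, cutoff_kev,
    as.integer(n_photons), as.integer(n_batches), as.integer(seed),
    majorant_floor)
  if (raw$missed == n_photons)
    warning("beam missed the phantom entirely; zero tally")
  .tally_class(raw, phantom, n_photons)
}

#' Run a full projection schedule
#'
#' Loops the engine over every projection in the schedule with seed =
#' base_seed + projection index, accumulating the (optionally weighted)
#' voxel map, scan-level batch tallies, and the per-projection region
#' sub-tallies needed for exact TCM re-weighting.
#'
#' @inheritParams run_projection
#' @param protocol a `scan_protocol`.
#' @param n_photons_per_projection histories per projection.
#' @param weights per-projection weights (e.g. from
#'   [projection_weights()]); NULL means all 1.
#' @param base_seed seed for projection 1.
#' @param z0_mm table z of the first projection.
#' @return a `ct_scan_tally`.
#' @export
run_scan <- function(phantom, geometry, protocol, spectrum, bowtie,
                     n_photons_per_projection = 10000, base_seed = 1L,
                     weights = NULL, z0_mm = 0, n_batches = 10,
                     cutoff_kev = .DEFAULT_CUTOFF_KEV,
                     majorant_floor = 0.05) {
  sched <- projection_schedule(protocol, geometry, z0_mm)
  n_proj <- nrow(sched)
  w <- if (is.null(weights)) rep(1, n_proj) else
    if (inherits(weights, "projection_weights")) weights$weights else
      weights
  if (length(w) != n_proj)
    stop("weights length must equal the schedule length")
  tt <- .transport_tables(spectrum)
  n_lab <- max(0L, phantom$organ_label)
  edep <- array(0, dim(phantom$material_id))
  proj_region <- matrix(0, n_lab + 1L, n_proj)
  proj_kerma <- matrix(0, n_lab + 1L, n_proj)
  batch_region <- matrix(0, n_lab + 1L, n_batches)
  batch_kerma <- matrix(0, n_lab + 1L, n_batches)
  emitted <- 0; uncollided <- 0; missed <- 0
  for (p in seq_len(n_proj)) {
    src <- .engine_source_pack(spectrum, bowtie, geometry,
                               sched$angle_deg[p], sched$z_mm[p])
    raw <- cpp_run_projection(
      as.integer(phantom$material_id), as.numeric(phantom$density),
      dim(phantom$material_id), phantom$spacing_mm, phantom$origin_mm,
      as.integer(phantom$organ_label), n_lab, tt$mu_tot, tt$f_pe,
      tt$f_coh, tt$muen, tt$e_lo, tt$e_step, src, cutoff_kev,
      as.integer(n_photons_per_projection), as.integer(n_batches),
      as.integer(base_seed + p - 1L), majorant_floor)
    edep <- edep + w[p] * array(raw$edep_kev, dim(edep))
    proj_region[, p] <- rowSums(raw$batch_region_kev)
    proj_kerma[, p] <- rowSums(raw$batch_kerma_kev)
    batch_region <- batch_region + w[p] * raw$batch_region_kev
    batch_kerma <- batch_kerma + w[p] * raw$batch_kerma_kev
    emitted <- emitted + raw$emitted_kev
    uncollided <- uncollided + raw$uncollided
    missed <- missed + raw$missed
  }
  rn <- c("total", names(phantom$organ_names)[
    order(phantom$organ_names)])[seq_len(n_lab + 1L)]
  rownames(proj_region) <- rn
  rownames(proj_kerma) <- rn
  rownames(batch_region) <- rn
  structure(list(edep_kev = edep, proj_region_kev = proj_region,
                 proj_kerma_kev = proj_kerma,
                 batch_region_kev = batch_region,
                 batch_kerma_kev = batch_kerma, weights = w,
                 schedule = sched,
                 n_photons_per_projection = n_photons_per_projection,
                 n_photons = n_photons_per_projection * n_proj,
                 emitted_kev = emitted, uncollided = uncollided,
                 missed = missed, base_seed = base_seed,
                 region_masses_g = region_masses(phantom),
                 organ_names = phantom$organ_names,
                 spacing_mm = phantom$spacing_mm),
            class = "ct_scan_tally")
}

#' Region absorbed dose per source photon
#'
#' Converts region energy tallies to absorbed dose in Gy per source
#' photon (region energy / region mass / photon count), with the
#' relative statistical uncertainty from batch statistics.
#'
#' @param tally a `ct_tally` or `ct_scan_tally`.
#' @param estimator "kerma" (track-length collision-kerma estimator;
#'   low variance, valid under charged-particle equilibrium) or
#'   "analog" (energy actually deposited by sampled interactions;
#'   satisfies region dose = sum of voxel energies / region mass).
#' @return data.frame with columns `region`, `dose_gy_per_photon`,
#'   `rel_uncertainty`.
#' @export
region_dose <- function(tally, estimator = c("kerma", "analog")) {
  estimator <- match.arg(estimator)
  scan <- inherits(tally, "ct_scan_tally")
  proj <- if (estimator == "kerma") tally$proj_kerma_kev else
    tally$proj_region_kev
  kev <- if (scan) rowSums(sweep(proj, 2, tally$weights, `*`)) else
    if (estimator == "kerma") tally$region_kerma_kev else
      tally$region_kev
  regions <- if (scan) rownames(tally$proj_region_kev) else
    names(tally$region_kev)
  masses <- c(NA_real_, tally$region_masses_g[
    match(regions[-1], names(tally$region_masses_g))])
  dose <- kev * .KEV_TO_J / (masses / 1000) / tally$n_photons
  dose[1] <- NA_real_  # "total" row has no single mass
  relu <- estimate_uncertainty(
    if (estimator == "kerma") tally$batch_kerma_kev else
      tally$batch_region_kev)
  data.frame(region = regions, dose_gy_per_photon = dose,
             rel_uncertainty = relu, row.names = NULL)
}

#' Relative statistical uncertainty from batch tallies
#'
#' Standard error of the batch means divided by the grand mean, per
#' region (row).
#'
#' @param batch_tallies matrix, regions x batches (or a vector of batch
#'   values for a single region).
#' @export
estimate_uncertainty <- function(batch_tallies) {
  if (is.vector(batch_tallies)) batch_tallies <- rbind(batch_tallies)
  n <- ncol(batch_tallies)
  if (n < 2) stop("need at least 2 batches")
  m <- rowMeans(batch_tallies)
  se <- sqrt(apply(batch_tallies, 1, var) / n)
  ifelse(m > 0, se / m, 0)
}

#' @export
print.ct_tally <- function(x, ...) {
  cat(sprintf("ct_tally: %d photons, %.4g keV deposited (%.4g emitted)\n",
              x$n_photons, sum(x$region_kev[1]), x$emitted_kev))
  invisible(x)
}

#' @export
print.ct_scan_tally <- function(x, ...) {
  cat(sprintf("ct_scan_tally: %d projections x %d photons\n",
              nrow(x$schedule), x$n_photons_per_projection))
  invisible(x)
}
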