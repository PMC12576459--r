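# Tube current modulation profiles: extraction from DICOM headers,
# per-rotation averaging, and conversion to per-projection weighting
# factors applied at constant total particle count.

#' Extract per-slice tube currents from a DICOM series
#'
#' One (z, mA) sample per reconstructed slice, sorted by z; slices
#' sharing the same z are averaged. The tube current tag (0018,1151) is
#' preferred; when absent on every slice, Exposure (0018,1152) divided
#' by the rotation time is used as a fallback.
#'
#' @param series a directory path or a series from
#'   [read_dicom_series()].
#' @param rotation_time_s rotation time for the Exposure fallback.
#' @return data.frame with columns `z_mm`, `tube_current_ma`.
#' @export
extract_tube_currents <- function(series, rotation_time_s = 0.5) {
  if (is.character(series))
    series <- read_dicom_series(series, read_pixels = FALSE)
  h <- series$headers
  ma <- h$tube_current_ma
  if (all(is.na(ma))) {
    if (all(is.na(h$exposure_mas)))
      stop("no tube current (0018,1151) or exposure (0018,1152) in series")
    ma <- h$exposure_mas / rotation_time_s
  }
  if (anyNA(ma))
    stop("missing tube current on slices: ",
         paste(h$file[is.na(ma)], collapse = ", "))
  agg <- tapply(ma, h$z_mm, mean)
  data.frame(z_mm = as.numeric(names(agg)),
             tube_current_ma = as.numeric(agg), row.names = NULL)
}

#' Average tube current per rotation
#'
#' Folds per-slice samples into rotation windows of one table feed
#' (pitch x beam width) anchored at the first reconstructed slice (or a
#' configurable start), giving the longitudinal TCM profile: rotation
#' index, window-center table position, mean mA. Empty windows are
#' filled by linear interpolation of neighbouring rotations (flagged in
#' the `interpolated` column).
#'
#' @param samples data.frame from [extract_tube_currents()].
#' @param table_feed_mm table feed per rotation, mm (pitch x beam
#'   width).
#' @param scan_start_z_mm window anchor; defaults to the first sample.
#' @return object of class `tcm_profile`: data.frame with columns
#'   `rotation`, `z_mm`, `tube_current_ma`, `n_slices`, `interpolated`.
#' @export
per_rotation_average <- function(samples, table_feed_mm,
                                 scan_start_z_mm = NULL) {
  stopifnot(table_feed_mm > 0)
  if (!nrow(samples)) stop("no tube current samples")
  if (is.null(scan_start_z_mm)) scan_start_z_mm <- min(samples$z_mm)
  span <- max(samples$z_mm) - scan_start_z_mm
  n_rot <- max(1L, ceiling((span + 1e-9) / table_feed_mm))
  k <- pmin(pmax(floor((samples$z_mm - scan_start_z_mm) / table_feed_mm),
                 0), n_rot - 1)
  ma <- rep(NA_real_, n_rot)
  ns <- integer(n_rot)
  for (r in seq_len(n_rot)) {
    sel <- k == r - 1
    ns[r] <- sum(sel)
    if (ns[r] > 0) ma[r] <- mean(samples$tube_current_ma[sel])
  }
  interp <- is.na(ma)
  if (any(interp)) {
    idx <- which(!interp)
    ma <- approx(idx, ma[idx], xout = seq_len(n_rot), rule = 2)$y
  }
  prof <- data.frame(rotation = seq_len(n_rot),
                     z_mm = scan_start_z_mm +
                       (seq_len(n_rot) - 0.5) * table_feed_mm,
                     tube_current_ma = ma, n_slices = ns,
                     interpolated = interp)
  class(prof) <- c("tcm_profile", "data.frame")
  prof
}

#' Per-projection weighting factors from a TCM profile
#'
#' Assigns each scheduled projection a tube current by interpolating the
#' rotation-averaged profile at the projection's table position
#' ("linear", the default) or by taking its rotation's mean
#' ("constant"); projections outside the profile take the nearest
#' rotation's value (overranging mA is not available from image
#' headers). Weights are mA divided by the schedule mean so that
#' mean(weights) is exactly 1 and the total particle count is unchanged;
#' the absolute scale is returned separately as effective mAs per
#' projection.
#'
#' @param profile a `tcm_profile`.
#' @param schedule a [projection_schedule()] data.frame.
#' @param rotation_time_s rotation time, s.
#' @param method "linear" or "constant" z-interpolation of rotation
#'   means.
#' @param z_offset_mm shift applied to schedule z before lookup (use
#'   when schedule z and DICOM z have different origins).
#' @return object of class `projection_weights`: list with `weights`
#'   (mean exactly 1), `ma` (per-projection mA), `mas_per_projection`
#'   (mean mA x rotation time / projections per rotation).
#' @export
projection_weights <- function(profile, schedule, rotation_time_s = 0.5,
                               method = c("linear", "constant"),
                               z_offset_mm = 0) {
  method <- match.arg(method)
  if (!nrow(profile)) stop("empty profile")
  z <- schedule$z_mm + z_offset_mm
  ma <- if (nrow(profile) == 1 || method == "constant") {
    feed <- if (nrow(profile) > 1) diff(profile$z_mm)[1] else Inf
    k <- pmin(pmax(findInterval(z, profile$z_mm - feed / 2), 1),
              nrow(profile))
    profile$tube_current_ma[k]
  } else {
    approx(profile$z_mm, profile$tube_current_ma, xout = z, rule = 2)$y
  }
  ppr <- length(unique(schedule$angle_deg))
  w <- ma / mean(ma)
  w <- w / mean(w)  # exact renormalization
  structure(list(weights = w, ma = ma,
                 mas_per_projection = mean(ma) * rotation_time_s / ppr),
            class = "projection_weights")
}

#' Re-weight a scan tally with projection weights
#'
#' Recomputes region tallies as the exact dot product of the stored
#' per-projection sub-tallies with the weights, leaving the simulated
#' particle count unchanged (weights re-shape; the mAs scale converts to
#' absolute units downstream).
#'
#' @param tally a `ct_scan_tally`.
#' @param weights a `projection_weights` or numeric vector matching the
#'   schedule length.
#' @return the tally with weights replaced (region doses from
#'   [region_dose()] reflect the new weights).
#' @export
apply_weights <- function(tally, weights) {
  w <- if (inherits(weights, "projection_weights")) weights$weights else
    weights
  if (length(w) != ncol(tally$proj_region_kev))
    stop("weight count does not match projection count")
  if (any(w <= 0)) stop("weights must be positive")
  old <- tally$weights
  tally$weights <- w
  # rescale the scan-level batch tallies so uncertainties stay usable
  rescale <- function(proj, batch) {
    tot_old <- rowSums(sweep(proj, 2, old, `*`))
    tot_new <- proj %*% w
    batch * ifelse(tot_old > 0, as.numeric(tot_new) / tot_old, 1)
  }
  tally$batch_region_kev <- rescale(tally$proj_region_kev,
                                    tally$batch_region_kev)
  tally$batch_kerma_kev <- rescale(tally$proj_kerma_kev,
                                   tally$batch_kerma_kev)
  tally
}

#' Write a TCM profile as CSV
#' @param profile a `tcm_profile`.
#' @param path output path.
#' @export
write_tcm_profile_csv <- function(profile, path) {
  write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}
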