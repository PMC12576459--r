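# Synthetic fixtures: standards-conformant CT DICOM series rendered from
# the synthetic abdomen phantom, with per-slice TCM header tags, so
# header mining and phantom building are exercised by the same files.

.ma_shape <- function(shape, z_frac, mean_ma) {
  raw <- switch(shape,
    constant = rep(1, length(z_frac)),
    ramp = 0.5 + z_frac,                       # 0.5x .. 1.5x
    bump = 0.75 + 0.5 * exp(-((z_frac - 0.5) / 0.25)^2),
    stop("unknown mA profile shape: ", shape))
  raw / mean(raw) * mean_ma
}

#' Generate a synthetic CT DICOM series on disk
#'
#' Writes a CT series whose pixel data are rendered from a synthetic
#' abdomen phantom (HU plus Gaussian noise) and whose headers carry a
#' per-slice tube current profile — everything the TCM extraction and
#' phantom construction steps need, with no external data. Headers and
#' UIDs are derived from the seed, so the same spec gives a byte-stable
#' series.
#'
#' @param out_dir output directory (created if missing).
#' @param phantom a `voxel_phantom` with HU data; default a synthetic
#'   abdomen at the requested seed.
#' @param slice_thickness_mm reconstructed slice thickness (default
#'   0.625).
#' @param scan_length_mm length covered by the series; default the
#'   phantom's z extent.
#' @param ma_profile "constant", "ramp", "bump", a numeric vector (one
#'   value per slice), or a function(z_mm) returning mA.
#' @param mean_ma mean tube current for the named shapes.
#' @param kvp tube voltage header value.
#' @param noise_hu standard deviation of added HU noise.
#' @param seed integer seed (UIDs, noise).
#' @return invisibly, a list with `dir`, `z_mm`, `tube_current_ma`.
#' @export
make_fixture_series <- function(out_dir, phantom = NULL,
                                slice_thickness_mm = 0.625,
                                scan_length_mm = NULL,
                                ma_profile = "constant", mean_ma = 300,
                                kvp = 120, noise_hu = 8, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  if (is.null(phantom))
    phantom <- make_synthetic_abdomen(seed = seed)
  if (is.null(phantom$hu)) stop("phantom must carry HU data")
  d <- dim(phantom$hu)
  if (is.null(scan_length_mm))
    scan_length_mm <- d[3] * phantom$spacing_mm[3]
  n_slices <- round(scan_length_mm / slice_thickness_mm)
  z <- (seq_len(n_slices) - 0.5) * slice_thickness_mm
  ma <- if (is.function(ma_profile)) ma_profile(z)
    else if (is.numeric(ma_profile)) {
      stopifnot(length(ma_profile) == n_slices)
      ma_profile
    } else .ma_shape(ma_profile, (z - min(z)) / diff(range(z)), mean_ma)
  study_uid <- paste0(.UID_ROOT, ".", seed, ".1")
  series_uid <- paste0(.UID_ROOT, ".", seed, ".2")
  rot_time <- 0.5
  phantom_z0 <- phantom$origin_mm[3] - phantom$spacing_mm[3] / 2
  for (i in seq_len(n_slices)) {
    k <- min(d[3], max(1L, ceiling((z[i] - phantom_z0) /
                                     phantom$spacing_mm[3])))
    hu <- phantom$hu[, , k] +
      round(matrix(rnorm(d[1] * d[2], 0, noise_hu), d[1], d[2]))
    px <- t(pmax(hu + 1024, 0))  # rows = y, cols = x
    write_dicom_slice(
      file.path(out_dir, sprintf("slice_%04d.dcm", i)),
      pixel = px,
      fields = list(
        sop_instance_uid = paste0(series_uid, ".", i),
        series_uid = series_uid, study_uid = study_uid,
        instance_number = i,
        ipp = c(phantom$origin_mm[1], phantom$origin_mm[2], z[i]),
        pixel_spacing_mm = phantom$spacing_mm[1:2],
        slice_thickness_mm = slice_thickness_mm, kvp = kvp,
        tube_current_ma = ma[i], exposure_mas = ma[i] * rot_time,
        rescale_intercept = -1024, rescale_slope = 1))
  }
  invisible(list(dir = out_dir, z_mm = z, tube_current_ma = ma))
}
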