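# Minimal DICOM Part-10 codec (explicit VR little endian only).
#
# No DICOM library is available in the target environment, so the
# package carries the smallest reader/writer that supports the CT tags
# the pipeline needs: per-slice tube current (0018,1151), exposure
# (0018,1152), geometry (ImagePositionPatient, PixelSpacing,
# SliceThickness), rescale (slope/intercept) and 16-bit pixel data.
# Files produced by the fixture writer are standards-conformant enough
# for any general DICOM tool to read; the reader accepts any explicit
# VR little-endian file with or without the 128-byte preamble.

.UID_ROOT <- "1.2.826.0.1.3680043.10763"
.TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
.SOP_CT <- "1.2.840.10008.5.1.4.1.1.2"

.u16 <- function(x) writeBin(as.integer(x), raw(), size = 2,
                             endian = "little")
.u32 <- function(x) writeBin(as.integer(x), raw(), size = 4,
                             endian = "little")

.pad_even <- function(v, pad = as.raw(0)) {
  if (length(v) %% 2 == 1) c(v, pad) else v
}

.dcm_element <- function(group, elem, vr, value) {
  val <- if (is.raw(value)) value else {
    pad <- if (vr == "UI") as.raw(0) else charToRaw(" ")
    .pad_even(charToRaw(as.character(value)), pad)
  }
  head <- c(.u16(group), .u16(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "UN", "UT", "SQ")) {
    c(head, as.raw(c(0, 0)), .u32(length(val)), val)
  } else {
    c(head, .u16(length(val)), val)
  }
}

.dcm_us <- function(group, elem, x) .dcm_element(group, elem, "US", .u16(x))

#' Write one CT slice as a DICOM file
#'
#' @param path output file path.
#' @param pixel integer matrix (rows x cols) of stored pixel values.
#' @param fields named list of slice fields: `sop_instance_uid`,
#'   `series_uid`, `study_uid`, `instance_number`, `ipp` (length-3 mm),
#'   `pixel_spacing_mm` (length-2), `slice_thickness_mm`, `kvp`,
#'   `tube_current_ma`, `exposure_mas`, `rescale_intercept`,
#'   `rescale_slope`. `tube_current_ma` may be NULL to omit the tag.
#' @export
write_dicom_slice <- function(path, pixel, fields) {
  f <- fields
  ds <- function(x) paste(formatC(x, format = "g", digits = 10),
                          collapse = "\\")
  meta <- c(
    .dcm_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    .dcm_element(0x0002, 0x0002, "UI", .SOP_CT),
    .dcm_element(0x0002, 0x0003, "UI", f$sop_instance_uid),
    .dcm_element(0x0002, 0x0010, "UI", .TS_EXPLICIT_LE),
    .dcm_element(0x0002, 0x0012, "UI", paste0(.UID_ROOT, ".1")))
  body <- c(
    .dcm_element(0x0008, 0x0016, "UI", .SOP_CT),
    .dcm_element(0x0008, 0x0018, "UI", f$sop_instance_uid),
    .dcm_element(0x0008, 0x0060, "CS", "CT"),
    .dcm_element(0x0018, 0x0050, "DS", ds(f$slice_thickness_mm)),
    .dcm_element(0x0018, 0x0060, "DS", ds(f$kvp)))
  if (!is.null(f$tube_current_ma))
    body <- c(body, .dcm_element(0x0018, 0x1151, "IS",
                                 as.character(round(f$tube_current_ma))))
  if (!is.null(f$exposure_mas))
    body <- c(body, .dcm_element(0x0018, 0x1152, "IS",
                                 as.character(round(f$exposure_mas))))
  body <- c(body,
    .dcm_element(0x0020, 0x000D, "UI", f$study_uid),
    .dcm_element(0x0020, 0x000E, "UI", f$series_uid),
    .dcm_element(0x0020, 0x0013, "IS", as.character(f$instance_number)),
    .dcm_element(0x0020, 0x0032, "DS", ds(f$ipp)),
    .dcm_element(0x0020, 0x0037, "DS", ds(c(1, 0, 0, 0, 1, 0))),
    .dcm_element(0x0020, 0x1041, "DS", ds(f$ipp[3])),
    .dcm_us(0x0028, 0x0002, 1),
    .dcm_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
    .dcm_us(0x0028, 0x0010, nrow(pixel)),
    .dcm_us(0x0028, 0x0011, ncol(pixel)),
    .dcm_element(0x0028, 0x0030, "DS", ds(f$pixel_spacing_mm)),
    .dcm_us(0x0028, 0x0100, 16),
    .dcm_us(0x0028, 0x0101, 16),
    .dcm_us(0x0028, 0x0102, 15),
    .dcm_us(0x0028, 0x0103, 1),
    .dcm_element(0x0028, 0x1052, "DS", ds(f$rescale_intercept)),
    .dcm_element(0x0028, 0x1053, "DS", ds(f$rescale_slope)),
    .dcm_element(0x7FE0, 0x0010, "OW",
                 writeBin(as.integer(t(pixel)), raw(), size = 2,
                          endian = "little")))
  grouplen <- .dcm_element(0x0002, 0x0000, "UL", .u32(length(meta)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(grouplen, meta, body), con)
  invisible(path)
}

#' Read a DICOM file (explicit VR little endian)
#'
#' @param path file path.
#' @return named list of decoded elements keyed "gggg,eeee" (strings for
#'   text VRs, integers for US/UL, raw for OB/OW), plus `pixel` as an
#'   integer matrix when pixel data and dimensions are present.
#' @export
read_dicom_file <- function(path) {
  buf <- readBin(path, raw(), file.info(path)$size)
  off <- 0L
  if (length(buf) > 132 &&
      rawToChar(buf[129:132]) == "DICM") off <- 132L
  n <- length(buf)
  out <- list()
  rows <- cols <- NA_integer_
  text_vrs <- c("UI", "CS", "DS", "IS", "LO", "SH", "PN", "DA", "TM",
                "AE", "AS", "LT", "ST", "UT")
  while (off + 8 <= n) {
    grp <- readBin(buf[off + 1:2], "integer", size = 2, endian = "little",
                   signed = FALSE)
    ele <- readBin(buf[off + 3:4], "integer", size = 2, endian = "little",
                   signed = FALSE)
    vr <- rawToChar(buf[off + 5:6])
    if (vr %in% c("OB", "OW", "UN", "UT", "SQ")) {
      len <- readBin(buf[off + 9:12], "integer", size = 4,
                     endian = "little")
      voff <- off + 12L
    } else {
      len <- readBin(buf[off + 7:8], "integer", size = 2,
                     endian = "little", signed = FALSE)
      voff <- off + 8L
    }
    if (len < 0 || voff + len > n)
      stop("malformed DICOM element at offset ", off, " in ", path)
    val <- buf[voff + seq_len(len)]
    key <- sprintf("%04x,%04x", grp, ele)
    out[[key]] <- if (vr %in% text_vrs) {
      v <- val
      while (length(v) && (v[length(v)] == as.raw(0) ||
                           v[length(v)] == charToRaw(" ")))
        v <- v[-length(v)]
      rawToChar(v)
    } else if (vr %in% c("US", "UL")) {
      readBin(val, "integer", n = len / (if (vr == "US") 2 else 4),
              size = if (vr == "US") 2 else 4, endian = "little",
              signed = vr != "US")
    } else val
    if (key == "0028,0010") rows <- out[[key]]
    if (key == "0028,0011") cols <- out[[key]]
    off <- voff + len
  }
  if (!is.null(out[["7fe0,0010"]]) && !is.na(rows)) {
    px <- readBin(out[["7fe0,0010"]], "integer", n = rows * cols,
                  size = 2, endian = "little", signed = TRUE)
    out$pixel <- matrix(px, nrow = rows, ncol = cols, byrow = TRUE)
  }
  out
}

.ds_num <- function(x) as.numeric(strsplit(x, "\\\\")[[1]])

#' Read a CT DICOM series from a directory
#'
#' Reads every `.dcm` file, checks the series is geometrically
#' consistent (single series UID, uniform pixel spacing and orientation),
#' sorts slices by z, applies RescaleSlope/Intercept, and returns the HU
#' volume plus a per-slice header table.
#'
#' @param dir directory containing the series.
#' @param read_pixels read pixel data (set FALSE for header mining only).
#' @return list with `volume` (HU array x,y,z), `spacing_mm`,
#'   `origin_mm`, and `headers` (data.frame: file, instance, z_mm,
#'   tube_current_ma, exposure_mas).
#' @export
read_dicom_series <- function(dir, read_pixels = TRUE) {
  files <- list.files(dir, pattern = "\\.dcm$", full.names = TRUE)
  if (!length(files)) stop("no .dcm files in ", dir)
  slices <- lapply(files, read_dicom_file)
  series_uid <- unique(vapply(slices, function(s)
    s[["0020,000e"]] %||% "", ""))
  if (length(series_uid) != 1) stop("mixed series in ", dir)
  get_z <- function(s) {
    if (!is.null(s[["0020,0032"]])) .ds_num(s[["0020,0032"]])[3]
    else if (!is.null(s[["0020,1041"]])) as.numeric(s[["0020,1041"]])
    else stop("slice has neither ImagePositionPatient nor SliceLocation")
  }
  z <- vapply(slices, get_z, 0)
  ma <- vapply(slices, function(s) {
    v <- s[["0018,1151"]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }, 0)
  expo <- vapply(slices, function(s) {
    v <- s[["0018,1152"]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }, 0)
  o <- order(z)
  slices <- slices[o]; z <- z[o]; ma <- ma[o]; expo <- expo[o]
  files <- files[o]
  headers <- data.frame(
    file = basename(files),
    instance = vapply(slices, function(s)
      as.integer(s[["0020,0013"]] %||% NA), 1L),
    z_mm = z, tube_current_ma = ma, exposure_mas = expo)
  ps <- unique(vapply(slices, function(s) s[["0028,0030"]], ""))
  if (length(ps) != 1) stop("non-uniform PixelSpacing")
  orient <- unique(vapply(slices, function(s)
    s[["0020,0037"]] %||% "", ""))
  if (length(orient) != 1) stop("mixed slice orientations")
  spacing_xy <- .ds_num(ps)
  dz <- if (length(z) > 1) stats::median(diff(z)) else
    as.numeric(slices[[1]][["0018,0050"]])
  vol <- NULL
  origin <- c(0, 0, z[1])
  if (read_pixels) {
    if (is.null(slices[[1]]$pixel)) stop("series has no pixel data")
    ipp <- .ds_num(slices[[1]][["0020,0032"]])
    origin <- ipp
    slope <- as.numeric(slices[[1]][["0028,1053"]] %||% "1")
    intercept <- as.numeric(slices[[1]][["0028,1052"]] %||% "0")
    nxy <- dim(slices[[1]]$pixel)
    vol <- array(NA_real_, c(nxy[2], nxy[1], length(slices)))
    for (k in seq_along(slices))
      vol[, , k] <- t(slices[[k]]$pixel) * slope + intercept
  }
  list(volume = vol, spacing_mm = c(spacing_xy[1], spacing_xy[2], dz),
       origin_mm = origin, headers = headers,
       series_uid = series_uid)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
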