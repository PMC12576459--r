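# Voxel phantoms: HU->material conversion, CT-derived phantoms,
# coarse-graining, the standard CTDI PMMA phantom, and a synthetic
# labeled abdomen that stands in for an anthropomorphic phantom.
#
# Coordinates: voxel indices are 1-based in R; world coordinates are mm
# at voxel centers; z increases toward the head. Arrays are [nx, ny, nz]
# with x fastest.

.MATERIAL_NOMINAL_HU <- c(air = -1000, lung = -750, adipose = -80,
                          soft_tissue = 40, water = 0, pmma = 120,
                          bone_mix = 300, bone_cortical = 700,
                          aluminum = 2200, carbon_fiber = 250,
                          styrofoam = -980)

#' Construct a voxel phantom
#'
#' @param material_id integer 3-D array of catalog material ids.
#' @param density numeric 3-D array, g/cm3.
#' @param spacing_mm voxel spacing (dx, dy, dz), mm.
#' @param origin_mm world coordinate of the center of voxel (1,1,1), mm.
#' @param organ_label integer 3-D array of region labels (0 =
#'   unlabeled), or NULL.
#' @param organ_names named integer vector mapping label values to
#'   region names.
#' @param hu optional 3-D array of the Hounsfield units the phantom was
#'   built from (needed for HU-based coarse-graining).
#' @return object of class `voxel_phantom`.
#' @export
voxel_phantom <- function(material_id, density, spacing_mm, origin_mm,
                          organ_label = NULL, organ_names = integer(),
                          hu = NULL) {
  stopifnot(length(dim(material_id)) == 3,
            identical(dim(material_id), dim(density)),
            length(spacing_mm) == 3, all(spacing_mm > 0),
            length(origin_mm) == 3)
  if (is.null(organ_label))
    organ_label <- array(0L, dim(material_id))
  stopifnot(identical(dim(organ_label), dim(material_id)))
  air_id <- .material_row("air")$id
  if (any(density[material_id != air_id] <= 0))
    stop("non-air voxels must have positive density")
  structure(list(material_id = material_id, density = density,
                 spacing_mm = as.numeric(spacing_mm),
                 origin_mm = as.numeric(origin_mm),
                 organ_label = organ_label,
                 organ_names = organ_names, hu = hu),
            class = "voxel_phantom")
}

#' @export
print.voxel_phantom <- function(x, ...) {
  d <- dim(x$material_id)
  cat(sprintf("voxel_phantom: %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing_mm[1], x$spacing_mm[2],
              x$spacing_mm[3]))
  if (length(x$organ_names))
    cat("regions:", paste(names(x$organ_names), collapse = ", "), "\n")
  invisible(x)
}

#' Total phantom mass in grams
#' @param phantom a `voxel_phantom`.
#' @export
phantom_mass <- function(phantom) {
  vox_cm3 <- prod(phantom$spacing_mm) / 1000
  sum(phantom$density) * vox_cm3
}

#' Mass of each labeled region, grams
#' @param phantom a `voxel_phantom`.
#' @export
region_masses <- function(phantom) {
  vox_cm3 <- prod(phantom$spacing_mm) / 1000
  lab <- phantom$organ_label
  labs <- sort(unique(lab[lab > 0]))
  m <- vapply(labs, function(l) sum(phantom$density[lab == l]) * vox_cm3,
              0)
  names(m) <- names(phantom$organ_names)[match(labs, phantom$organ_names)]
  setNames(m, ifelse(is.na(names(m)), paste0("label", labs), names(m)))
}

#' Hounsfield-unit calibration table
#'
#' Piecewise mapping from CT number to a catalog material and a density
#' linear in HU, in the style of stoichiometric CT calibrations used to
#' build simulation phantoms. The bundled table is an editable CSV with
#' columns `hu_lo`, `hu_hi`, `material`, `dens_a`, `dens_b`
#' (density = a + b * HU).
#'
#' @param path CSV path; default the bundled table.
#' @export
schneider_calibration <- function(path = NULL) {
  if (is.null(path)) path <- .extdata("schneider_bins.csv")
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(nrow(df) > 0, all(df$hu_lo[-1] == df$hu_hi[-nrow(df)]))
  df$material_id <- vapply(df$material,
                           function(m) as.integer(.material_row(m)$id), 1L)
  class(df) <- c("schneider_calibration", "data.frame")
  df
}

#' Convert Hounsfield units to material and density
#'
#' Bin lookup in the calibration plus the bin's linear density function.
#' HU outside the calibrated range are clamped with a warning.
#'
#' @param hu Hounsfield units (vectorized).
#' @param calib a [schneider_calibration()].
#' @return data.frame with columns `material_id`, `density`.
#' @export
hu_to_material <- function(hu, calib = schneider_calibration()) {
  if (nrow(calib) == 0) stop("empty calibration")
  lo <- calib$hu_lo[1]; hi <- calib$hu_hi[nrow(calib)]
  if (any(hu < lo | hu >= hi)) {
    warning("HU outside calibration range clamped")
    hu <- pmin(pmax(hu, lo), hi - 1e-9)
  }
  bin <- findInterval(hu, c(calib$hu_lo, calib$hu_hi[nrow(calib)]),
                      all.inside = TRUE)
  dens <- calib$dens_a[bin] + calib$dens_b[bin] * hu
  data.frame(material_id = calib$material_id[bin],
             density = pmax(dens, 1e-5))
}

#' Build a voxel phantom from a CT DICOM series
#'
#' Applies RescaleSlope/Intercept to recover HU, checks geometric
#' consistency, and assigns per-voxel material and density via the HU
#' calibration. Slices are sorted by z regardless of on-disk order.
#'
#' @param series a series read with [read_dicom_series()].
#' @param calib a [schneider_calibration()].
#' @export
build_from_ct <- function(series, calib = schneider_calibration()) {
  hu <- series$volume
  mm <- hu_to_material(as.vector(hu), calib)
  voxel_phantom(array(mm$material_id, dim(hu)),
                array(mm$density, dim(hu)),
                spacing_mm = series$spacing_mm,
                origin_mm = series$origin_mm, hu = hu)
}

#' Coarse-grain a voxel phantom
#'
#' Averages HU and density in blocks (default 4 x 4 x 1) and re-bins the
#' block-mean HU through the calibration to pick the block material, so
#' material and density stay consistent. Dimensions not divisible by the
#' factors are padded with air (with a warning). Block labels are the
#' modal nonzero label of the block.
#'
#' @param phantom a `voxel_phantom` carrying an `hu` array.
#' @param factors integer length-3 block size.
#' @param calib a [schneider_calibration()].
#' @export
coarse_grain <- function(phantom, factors = c(4, 4, 1),
                         calib = schneider_calibration()) {
  stopifnot(all(factors >= 1))
  if (is.null(phantom$hu))
    stop("coarse_grain needs a phantom with HU data (from build_from_ct)")
  d <- dim(phantom$hu)
  newd <- ceiling(d / factors)
  pad <- newd * factors - d
  hu <- phantom$hu
  dens <- phantom$density
  lab <- phantom$organ_label
  if (any(pad > 0)) {
    warning("dims not divisible by factors; padding with air")
    hu2 <- array(-1000, newd * factors)
    dn2 <- array(0.001205, newd * factors)
    lb2 <- array(0L, newd * factors)
    hu2[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- hu
    dn2[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- dens
    lb2[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- lab
    hu <- hu2; dens <- dn2; lab <- lb2
  }
  block_reduce <- function(a, f, fun) {
    dd <- dim(a)
    m <- array(a, c(f[1], dd[1] / f[1], f[2], dd[2] / f[2],
                    f[3], dd[3] / f[3]))
    apply(m, c(2, 4, 6), fun)
  }
  hu_m <- block_reduce(hu, factors, mean)
  dens_m <- block_reduce(dens, factors, mean)
  lab_m <- block_reduce(lab, factors, function(v) {
    v <- v[v > 0]
    if (!length(v)) return(0L)
    as.integer(names(which.max(table(v))))
  })
  mat_m <- array(hu_to_material(as.vector(hu_m), calib)$material_id,
                 dim(hu_m))
  voxel_phantom(mat_m, dens_m,
                spacing_mm = phantom$spacing_mm * factors,
                origin_mm = phantom$origin_mm +
                  (factors - 1) / 2 * phantom$spacing_mm,
                organ_label = array(as.integer(lab_m), dim(lab_m)),
                organ_names = phantom$organ_names, hu = hu_m)
}

#' Standard CTDI body phantom
#'
#' 32 cm diameter PMMA cylinder with five air-filled bore channels
#' (center plus 12/3/6/9 o'clock, centers 1 cm below the surface).
#' Labels 1-5 mark the central 100 mm of each bore (the pencil-chamber
#' active length) for tallying.
#'
#' @param diameter_cm,length_cm phantom dimensions.
#' @param spacing_mm voxel spacing.
#' @param bore_radius_mm bore channel radius.
#' @param chamber_length_mm labeled chamber length centered in z.
#' @return a `voxel_phantom`; attribute `bores` holds the bore center
#'   (x, y) positions in mm.
#' @export
make_ctdi_phantom <- function(diameter_cm = 32, length_cm = 15,
                              spacing_mm = c(4, 4, 5),
                              bore_radius_mm = 6.55,
                              chamber_length_mm = 100) {
  R <- diameter_cm * 10 / 2
  L <- length_cm * 10
  margin <- 2 * spacing_mm[1]
  nx <- ceiling((2 * R + 2 * margin) / spacing_mm[1])
  ny <- ceiling((2 * R + 2 * margin) / spacing_mm[2])
  nz <- ceiling(L / spacing_mm[3])
  cx <- (seq_len(nx) - (nx + 1) / 2) * spacing_mm[1]
  cy <- (seq_len(ny) - (ny + 1) / 2) * spacing_mm[2]
  cz <- (seq_len(nz) - (nz + 1) / 2) * spacing_mm[3]
  air <- .material_row("air"); pmma <- .material_row("pmma")
  X <- array(cx, c(nx, ny, nz))
  Y <- array(rep(cy, each = nx), c(nx, ny, nz))
  Z <- array(rep(cz, each = nx * ny), c(nx, ny, nz))
  inside <- X^2 + Y^2 <= R^2
  mat <- array(as.integer(air$id), c(nx, ny, nz))
  dens <- array(air$density, c(nx, ny, nz))
  mat[inside] <- as.integer(pmma$id)
  dens[inside] <- pmma$density
  rb <- R - 10
  bores <- rbind(center = c(0, 0), o12 = c(0, rb), o3 = c(rb, 0),
                 o6 = c(0, -rb), o9 = c(-rb, 0))
  lab <- array(0L, c(nx, ny, nz))
  for (b in seq_len(nrow(bores))) {
    in_bore <- (X - bores[b, 1])^2 + (Y - bores[b, 2])^2 <=
      bore_radius_mm^2
    mat[in_bore] <- as.integer(air$id)
    dens[in_bore] <- air$density
    lab[in_bore & abs(Z) <= chamber_length_mm / 2] <- b
  }
  ph <- voxel_phantom(mat, dens, spacing_mm,
                      origin_mm = c(cx[1], cy[1], cz[1]),
                      organ_label = lab,
                      organ_names = setNames(1:5, rownames(bores)))
  attr(ph, "bores") <- bores
  ph
}

#' Free-in-air phantom for CTDI_air calibration
#'
#' An all-air grid with a small labeled chamber region at the isocenter,
#' mirroring a free-in-air pencil-chamber measurement.
#'
#' @param extent_mm half-extent of the grid in x and y, mm.
#' @param length_mm grid length in z, mm.
#' @param spacing_mm voxel spacing.
#' @param chamber_radius_mm,chamber_length_mm labeled chamber size.
#' @export
make_air_phantom <- function(extent_mm = 60, length_mm = 140,
                             spacing_mm = c(5, 5, 5),
                             chamber_radius_mm = 10,
                             chamber_length_mm = 100) {
  air <- .material_row("air")
  nx <- ceiling(2 * extent_mm / spacing_mm[1])
  ny <- ceiling(2 * extent_mm / spacing_mm[2])
  nz <- ceiling(length_mm / spacing_mm[3])
  cx <- (seq_len(nx) - (nx + 1) / 2) * spacing_mm[1]
  cy <- (seq_len(ny) - (ny + 1) / 2) * spacing_mm[2]
  cz <- (seq_len(nz) - (nz + 1) / 2) * spacing_mm[3]
  X <- array(cx, c(nx, ny, nz))
  Y <- array(rep(cy, each = nx), c(nx, ny, nz))
  Z <- array(rep(cz, each = nx * ny), c(nx, ny, nz))
  lab <- array(0L, c(nx, ny, nz))
  lab[X^2 + Y^2 <= chamber_radius_mm^2 &
        abs(Z) <= chamber_length_mm / 2] <- 1L
  voxel_phantom(array(as.integer(air$id), c(nx, ny, nz)),
                array(air$density, c(nx, ny, nz)), spacing_mm,
                origin_mm = c(cx[1], cy[1], cz[1]), organ_label = lab,
                organ_names = c(chamber = 1L))
}

.default_abdomen_organs <- function() {
  data.frame(
    name = c("liver", "stomach", "gallbladder", "spleen", "pancreas",
             "kidneys", "kidneys"),
    cx = c(-55, 48, -22, 78, 0, 48, -48),
    cy = c(10, 28, 62, -28, 8, -48, -48),
    cz = c(50, 50, 100, 40, 100, 118, 118),
    rx = c(58, 36, 14, 20, 42, 22, 22),
    ry = c(42, 26, 11, 17, 13, 16, 16),
    rz = c(38, 30, 22, 24, 13, 34, 34))
}

#' Synthetic labeled abdomen phantom
#'
#' An elliptic-cylinder soft-tissue body with six labeled ellipsoidal
#' abdominal organs (liver, stomach, gallbladder, spleen, pancreas,
#' kidneys as a pair), a vertebral column of cortical bone, and air-filled
#' lung bases at the cranial end. Stands in for an anthropomorphic
#' phantom so the full pipeline runs without patient data. Overlaps are
#' resolved by a fixed precedence (lung, bone, then organs in catalog
#' order; first label wins), so labels are disjoint by construction. The
#' seed jitters organ centers by up to 3 mm.
#'
#' @param body_halfaxes_mm body ellipse half-axes (x, y), mm.
#' @param length_mm phantom length, mm.
#' @param spacing_mm voxel spacing, mm.
#' @param organs data.frame of organ ellipsoids (name, cx, cy, cz, rx,
#'   ry, rz in mm; z measured from the cranial end).
#' @param seed integer; same seed gives an identical phantom.
#' @return a `voxel_phantom` with HU data (for fixture rendering).
#' @export
make_synthetic_abdomen <- function(body_halfaxes_mm = c(150, 100),
                                   length_mm = 175,
                                   spacing_mm = c(2.72, 2.72, 5),
                                   organs = .default_abdomen_organs(),
                                   seed = 1L) {
  set.seed(seed)
  jit <- matrix(runif(3 * nrow(organs), -2, 2), ncol = 3)
  a <- body_halfaxes_mm[1]; b <- body_halfaxes_mm[2]
  margin <- 6
  nx <- ceiling((2 * a + 2 * margin) / spacing_mm[1])
  ny <- ceiling((2 * b + 2 * margin) / spacing_mm[2])
  nz <- ceiling(length_mm / spacing_mm[3])
  cx <- (seq_len(nx) - (nx + 1) / 2) * spacing_mm[1]
  cy <- (seq_len(ny) - (ny + 1) / 2) * spacing_mm[2]
  cz <- (seq_len(nz) - 0.5) * spacing_mm[3]
  X <- array(cx, c(nx, ny, nz))
  Y <- array(rep(cy, each = nx), c(nx, ny, nz))
  Z <- array(rep(cz, each = nx * ny), c(nx, ny, nz))
  cat <- material_catalog()
  id <- function(n) as.integer(cat$id[cat$name == n])
  dn <- function(n) cat$density[cat$name == n]
  mat <- array(id("air"), c(nx, ny, nz))
  dens <- array(dn("air"), c(nx, ny, nz))
  hu <- array(-1000, c(nx, ny, nz))
  body <- (X / a)^2 + (Y / b)^2 <= 1
  mat[body] <- id("soft_tissue"); dens[body] <- dn("soft_tissue")
  hu[body] <- .MATERIAL_NOMINAL_HU["soft_tissue"]
  # lung bases at the cranial end (z near 0)
  for (sx in c(-1, 1)) {
    lung <- body & ((X - sx * 55) / 35)^2 + ((Y + 10) / 30)^2 +
      ((Z + 5) / 15)^2 <= 1
    mat[lung] <- id("lung"); dens[lung] <- dn("lung")
    hu[lung] <- .MATERIAL_NOMINAL_HU["lung"]
  }
  # vertebral column
  vert <- body & X^2 + (Y + 60)^2 <= 16^2
  mat[vert] <- id("bone_cortical"); dens[vert] <- dn("bone_cortical")
  hu[vert] <- .MATERIAL_NOMINAL_HU["bone_cortical"]
  lab <- array(0L, c(nx, ny, nz))
  organ_names <- setNames(seq_along(unique(organs$name)),
                          unique(organs$name))
  for (i in seq_len(nrow(organs))) {
    l <- organ_names[[organs$name[i]]]
    ell <- ((X - organs$cx[i] - jit[i, 1]) / organs$rx[i])^2 +
      ((Y - organs$cy[i] - jit[i, 2]) / organs$ry[i])^2 +
      ((Z - organs$cz[i] - jit[i, 3]) / organs$rz[i])^2 <= 1
    sel <- ell & lab == 0L & mat == id("soft_tissue")
    lab[sel] <- as.integer(l)
  }
  voxel_phantom(mat, dens, spacing_mm,
                origin_mm = c(cx[1], cy[1], cz[1]), organ_label = lab,
                organ_names = organ_names, hu = hu)
}

#' Stamp the patient table into a phantom grid
#'
#' Extends the grid in -y and fills a carbon-fiber shell / foam core
#' table slab spanning the full x width (clipped to the table width) and
#' z length.
#'
#' @param phantom a `voxel_phantom`.
#' @param table a [table_model()].
#' @export
add_table <- function(phantom, table = table_model()) {
  if (is.null(table)) return(phantom)
  d <- dim(phantom$material_id)
  dy <- phantom$spacing_mm[2]
  n_gap <- ceiling(table$gap_mm / dy)
  n_shell <- max(1L, round(table$shell_mm / dy))
  n_core <- max(1L, round(table$core_mm / dy))
  n_add <- n_gap + 2L * n_shell + n_core
  cat <- material_catalog()
  air <- .material_row("air")
  newd <- c(d[1], d[2] + n_add, d[3])
  mat <- array(as.integer(air$id), newd)
  dens <- array(air$density, newd)
  lab <- array(0L, newd)
  hu <- if (!is.null(phantom$hu)) array(-1000, newd) else NULL
  sel <- seq_len(d[2]) + n_add
  mat[, sel, ] <- phantom$material_id
  dens[, sel, ] <- phantom$density
  lab[, sel, ] <- phantom$organ_label
  if (!is.null(hu)) hu[, sel, ] <- phantom$hu
  cxs <- phantom$origin_mm[1] + (seq_len(d[1]) - 1) * phantom$spacing_mm[1]
  in_width <- abs(cxs) <= table$width_mm / 2
  fill <- function(rows, material) {
    r <- .material_row(material)
    mat[in_width, rows, ] <<- as.integer(r$id)
    dens[in_width, rows, ] <<- r$density
    if (!is.null(hu))
      hu[in_width, rows, ] <<- .MATERIAL_NOMINAL_HU[[material]]
  }
  fill(n_core + n_shell + seq_len(n_shell), table$shell_material)  # top
  fill(n_shell + seq_len(n_core), table$core_material)
  fill(seq_len(n_shell), table$shell_material)                     # bottom
  voxel_phantom(mat, dens, phantom$spacing_mm,
                origin_mm = phantom$origin_mm -
                  c(0, n_add * dy, 0),
                organ_label = lab, organ_names = phantom$organ_names,
                hu = hu)
}
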