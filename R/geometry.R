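# CT gantry model: source trajectory, projection schedule, fan-beam
# collimation, bowtie filter, patient table.
#
# Conventions: the gantry rotates in the x-y plane, z runs along the
# table toward the head. Gantry angle 0 degrees is 12 o'clock (+y), with
# rotation clockwise when viewed from the feet (x = sin, y = cos). The
# collimator is a perfect aperture: photons are only emitted inside the
# collimated fan/cone. Distances in the geometry object are cm (matching
# scanner data sheets); world coordinates handed to the transport engine
# are mm.

#' Scanner geometry
#'
#' @param sid_cm source-to-isocenter distance, cm.
#' @param sdd_cm source-to-detector distance, cm.
#' @param fan_angle_deg full fan angle, degrees.
#' @param beam_width_mm total collimated beam width at isocenter, mm.
#' @param start_angle_deg gantry angle of the first projection
#'   (0 = 12 o'clock).
#' @param table table model as returned by [table_model()], or NULL for
#'   no table.
#' @return object of class `scanner_geometry`.
#' @export
scanner_geometry <- function(sid_cm = 62.6, sdd_cm = 110,
                             fan_angle_deg = 47, beam_width_mm = 80,
                             start_angle_deg = 0, table = table_model()) {
  stopifnot(sid_cm < sdd_cm, fan_angle_deg > 0, fan_angle_deg < 90,
            beam_width_mm > 0)
  structure(list(sid_cm = sid_cm, sdd_cm = sdd_cm,
                 fan_angle_deg = fan_angle_deg,
                 beam_width_mm = beam_width_mm,
                 start_angle_deg = start_angle_deg, table = table),
            class = "scanner_geometry")
}

#' Patient table model
#'
#' Carbon-fiber shell over a foam core, stamped into the phantom voxel
#' grid below the patient.
#'
#' @param shell_material,core_material catalog material names.
#' @param shell_mm shell thickness, mm.
#' @param core_mm core thickness, mm.
#' @param width_mm table width, mm.
#' @param gap_mm air gap between phantom surface and table top, mm.
#' @export
table_model <- function(shell_material = "carbon_fiber",
                        core_material = "styrofoam", shell_mm = 2,
                        core_mm = 50, width_mm = 450, gap_mm = 0) {
  structure(list(shell_material = shell_material,
                 core_material = core_material, shell_mm = shell_mm,
                 core_mm = core_mm, width_mm = width_mm, gap_mm = gap_mm),
            class = "ct_table_model")
}

#' Scan protocol
#'
#' @param kvp tube voltage, kV.
#' @param mode "axial" or "helical".
#' @param tube_current_ma fixed tube current, mA (ignored when a TCM
#'   profile drives the run).
#' @param rotation_time_s gantry rotation time, s.
#' @param pitch table feed per rotation / beam width (helical mode).
#' @param scan_length_mm scanned length, mm (helical mode).
#' @param projections_per_rotation number of discrete source positions
#'   per rotation (default 40, i.e. 9-degree steps).
#' @export
scan_protocol <- function(kvp = 120, mode = c("helical", "axial"),
                          tube_current_ma = 300, rotation_time_s = 0.5,
                          pitch = 0.508, scan_length_mm = 175,
                          projections_per_rotation = 40) {
  mode <- match.arg(mode)
  stopifnot(pitch > 0, projections_per_rotation > 0,
            360 %% projections_per_rotation == 0 ||
              abs(360 / projections_per_rotation -
                    round(360 / projections_per_rotation, 6)) < 1e-9)
  structure(list(kvp = kvp, mode = mode,
                 tube_current_ma = tube_current_ma,
                 rotation_time_s = rotation_time_s, pitch = pitch,
                 scan_length_mm = scan_length_mm,
                 projections_per_rotation = projections_per_rotation,
                 angular_step_deg = 360 / projections_per_rotation),
            class = "scan_protocol")
}

#' Projection schedule
#'
#' Ordered (gantry angle, table z) pairs for every simulated projection.
#' Axial mode: one full rotation at fixed z. Helical mode: the angle
#' advances by the angular step and z by (pitch x beam width) /
#' projections-per-rotation each step; the projection count is
#' ceil(scan_length / (pitch x beam width) x projections_per_rotation) so
#' the schedule covers the full scan length (175 mm at pitch 0.508 with
#' an 80 mm beam gives 173 projections).
#'
#' @param protocol a `scan_protocol`.
#' @param geometry a `scanner_geometry`.
#' @param z0_mm table z of the first projection, mm (default 0).
#' @return data.frame with columns `projection`, `angle_deg`, `z_mm`.
#' @export
projection_schedule <- function(protocol, geometry, z0_mm = 0) {
  ppr <- protocol$projections_per_rotation
  step <- protocol$angular_step_deg
  if (protocol$mode == "axial") {
    n <- ppr
    dz <- 0
  } else {
    if (protocol$scan_length_mm <= 0)
      stop("scan_length must be positive in helical mode")
    feed <- protocol$pitch * geometry$beam_width_mm
    n <- ceiling(protocol$scan_length_mm / feed * ppr)
    dz <- feed / ppr
  }
  k <- seq_len(n) - 1L
  data.frame(projection = k + 1L,
             angle_deg = (geometry$start_angle_deg + k * step) %% 360,
             z_mm = z0_mm + k * dz)
}

#' Source position for a gantry angle and table position
#'
#' @param gantry_angle_deg gantry angle, degrees (0 = 12 o'clock).
#' @param table_z_mm table position, mm.
#' @param geometry a `scanner_geometry`.
#' @return numeric xyz position in mm.
#' @export
source_position <- function(gantry_angle_deg, table_z_mm, geometry) {
  a <- gantry_angle_deg * pi / 180
  r <- geometry$sid_cm * 10
  c(x = r * sin(a), y = r * cos(a), z = table_z_mm)
}

#' Bowtie filter profile
#'
#' Equivalent aluminum thickness versus fan angle.
#'
#' @param fan_angle_deg grid of fan angles, degrees (>= 0 when
#'   symmetric).
#' @param al_mm equivalent Al thickness at each angle, mm.
#' @param symmetric mirror the profile about the central ray.
#' @export
bowtie_profile <- function(fan_angle_deg, al_mm, symmetric = TRUE) {
  stopifnot(length(fan_angle_deg) == length(al_mm), all(al_mm >= 0),
            all(diff(fan_angle_deg) > 0))
  if (which.min(al_mm) != which.min(abs(fan_angle_deg)))
    stop("bowtie thickness must be minimal at the central ray")
  structure(list(fan_angle_deg = fan_angle_deg, al_mm = al_mm,
                 symmetric = symmetric),
            class = "bowtie_profile")
}

#' Bundled default body bowtie profile
#' @export
default_bowtie <- function() {
  df <- read.csv(.extdata("bowtie_body.csv"))
  bowtie_profile(df$fan_angle_deg, df$al_mm, symmetric = TRUE)
}

#' A flat (zero-thickness) bowtie, i.e. no bowtie filter
#' @export
flat_bowtie <- function() bowtie_profile(c(0, 30), c(0, 0))

#' Bowtie thickness at given fan angles
#' @param bowtie a `bowtie_profile`.
#' @param fan_angle_deg fan angles, degrees (signed).
#' @return equivalent Al thickness, mm (linear interpolation, clamped at
#'   the profile ends).
#' @export
bowtie_thickness <- function(bowtie, fan_angle_deg) {
  th <- if (bowtie$symmetric) abs(fan_angle_deg) else fan_angle_deg
  approx(bowtie$fan_angle_deg, bowtie$al_mm, xout = th, rule = 2)$y
}

#' Estimate a bowtie profile from fixed-tube measurements
#'
#' With the tube parked and a pencil chamber raised through the fan in
#' fixed increments, each exposure ratio relative to the central ray
#' gives the equivalent Al thickness t = -ln(ratio) / mu_eff at fan angle
#' theta = atan(offset / SID).
#'
#' @param offsets_mm chamber offsets from the central ray at the
#'   isocenter plane, mm.
#' @param exposure_ratios exposure relative to the central ray, in
#'   (0, 1].
#' @param mu_al_eff effective linear attenuation coefficient of aluminum
#'   at the beam quality, 1/cm.
#' @param geometry a `scanner_geometry`.
#' @param symmetric mirror about the center.
#' @export
bowtie_from_fixed_tube_measurements <- function(offsets_mm, exposure_ratios,
                                                mu_al_eff, geometry,
                                                symmetric = TRUE) {
  if (any(exposure_ratios > 1)) stop("exposure ratio > 1 (amplification)")
  if (any(exposure_ratios <= 0)) stop("exposure ratio must be positive")
  theta <- atan(offsets_mm / (geometry$sid_cm * 10)) * 180 / pi
  t_mm <- -log(exposure_ratios) / mu_al_eff * 10
  o <- order(theta)
  bowtie_profile(theta[o], t_mm[o], symmetric = symmetric)
}

#' Sample initial photons for one projection
#'
#' Draws photon starting states exactly as the transport engine does:
#' position at the source point, direction uniform in the fan angle and
#' uniform in the cone subtending the beam width at isocenter, energy
#' from the spectrum, and the bowtie applied as a multiplicative
#' statistical weight exp(-mu_Al(E) t(theta)).
#'
#' @param n number of photons.
#' @param spectrum an `xray_spectrum`.
#' @param bowtie a `bowtie_profile`.
#' @param geometry a `scanner_geometry`.
#' @param gantry_angle_deg,table_z_mm projection source placement.
#' @param seed integer RNG seed for the engine stream.
#' @return data.frame with columns x,y,z (mm), ux,uy,uz, energy_kev,
#'   weight.
#' @export
initial_photons <- function(n, spectrum, bowtie, geometry,
                            gantry_angle_deg = 0, table_z_mm = 0,
                            seed = 1L) {
  src <- .engine_source_pack(spectrum, bowtie, geometry,
                             gantry_angle_deg, table_z_mm)
  m <- cpp_initial_photons(as.integer(n), src, as.integer(seed))
  colnames(m) <- c("x", "y", "z", "ux", "uy", "uz", "energy_kev", "weight")
  as.data.frame(m)
}

# Pack spectrum/bowtie/geometry into the flat list the C++ engine takes.
.engine_source_pack <- function(spectrum, bowtie, geometry,
                                gantry_angle_deg, table_z_mm) {
  centers <- .bin_centers(spectrum)
  al <- attenuation_table("aluminum")
  theta_grid <- seq(-geometry$fan_angle_deg / 2,
                    geometry$fan_angle_deg / 2, length.out = 201)
  list(
    pos = source_position(gantry_angle_deg, table_z_mm, geometry),
    gantry_angle_deg = gantry_angle_deg,
    sid_mm = geometry$sid_cm * 10,
    fan_half_rad = geometry$fan_angle_deg / 2 * pi / 180,
    cone_half_rad = atan(geometry$beam_width_mm / 2 /
                           (geometry$sid_cm * 10)),
    e_lo = spectrum$bin_edges[1],
    e_step = diff(spectrum$bin_edges)[1],
    cdf = cumsum(spectrum$fluence) / sum(spectrum$fluence),
    mu_al_grid = mu_over_rho(al, centers) * 2.70,       # 1/cm
    bowtie_theta = theta_grid,
    bowtie_tcm = bowtie_thickness(bowtie, theta_grid) / 10  # cm
  )
}
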