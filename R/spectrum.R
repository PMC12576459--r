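# X-ray tube spectrum model.
#
# A semi-empirical 120 kVp-class tungsten spectrum: Kramers-type
# bremsstrahlung shaped by inherent + target-angle-dependent self
# filtration, plus tungsten K characteristic lines folded into their 0.5
# keV bins. The model is deliberately simple: the one measured constraint
# a scanner provides is the first half-value layer, and
# calibrate_filtration() forces the spectrum to reproduce it exactly, so
# the baseline shape only needs to be physically reasonable.

.W_K_LINES <- data.frame(energy_kev = c(57.98, 59.32, 67.20, 69.10),
                         amplitude  = c(0.54, 1.00, 0.30, 0.08))
.W_K_EDGE <- 69.525
.INHERENT_AL_MM <- 1.2
.TARGET_REF_AL_MM <- 1.0

#' Generate a binned x-ray tube spectrum
#'
#' Photon-fluence spectrum in uniform 0.5 keV bins spanning (5, kvp] keV.
#' Bremsstrahlung follows the Kramers form (kvp - E)/E; tungsten K lines
#' are added for tube voltages above the K edge; inherent filtration and
#' target self-attenuation (scaled by the target angle) plus any added
#' filtration attenuate each bin by the aluminum attenuation law.
#'
#' @param kvp tube voltage, kV (40-150).
#' @param target_angle anode target angle, degrees (default 10).
#' @param added_filtration_al added aluminum filtration, mm (>= 0).
#' @return object of class `xray_spectrum` with fields `bin_edges`
#'   (keV), `fluence` (relative, one per bin), `kvp`, `target_angle`,
#'   `added_filtration_al`.
#' @export
generate_spectrum <- function(kvp = 120, target_angle = 10,
                              added_filtration_al = 0) {
  if (kvp < 40 || kvp > 150) stop("unsupported kvp (must be 40-150)")
  if (added_filtration_al < 0) stop("negative filtration")
  if (target_angle <= 0 || target_angle >= 90) stop("bad target angle")
  edges <- seq(5, kvp, by = 0.5)
  centers <- edges[-length(edges)] + 0.25
  al <- attenuation_table("aluminum")
  fl <- (kvp - centers) / centers          # Kramers bremsstrahlung
  fl[fl < 0] <- 0
  if (kvp > .W_K_EDGE) {
    brem_total <- sum(fl)
    for (i in seq_len(nrow(.W_K_LINES))) {
      b <- findInterval(.W_K_LINES$energy_kev[i], edges,
                        rightmost.closed = TRUE)
      fl[b] <- fl[b] + 0.08 * brem_total *
        .W_K_LINES$amplitude[i] / sum(.W_K_LINES$amplitude)
    }
  }
  t_mm <- .INHERENT_AL_MM +
    .TARGET_REF_AL_MM * tan(10 * pi / 180) / tan(target_angle * pi / 180) +
    added_filtration_al
  fl <- fl * exp(-mu_over_rho(al, centers) * 2.70 * t_mm / 10)
  structure(list(bin_edges = edges, fluence = fl / sum(fl), kvp = kvp,
                 target_angle = target_angle,
                 added_filtration_al = added_filtration_al),
            class = "xray_spectrum")
}

.bin_centers <- function(spectrum) {
  e <- spectrum$bin_edges
  e[-length(e)] + diff(e) / 2
}

#' Mean photon energy of a spectrum (keV)
#' @param spectrum an `xray_spectrum`.
#' @export
mean_energy <- function(spectrum) {
  weighted.mean(.bin_centers(spectrum), spectrum$fluence)
}

# Air-kerma-weighted transmitted intensity behind t mm of attenuator.
.kerma_transmitted <- function(spectrum, attenuator, air, t_mm) {
  e <- .bin_centers(spectrum)
  k0 <- spectrum$fluence * e * muen_over_rho(air, e)
  sum(k0 * exp(-mu_over_rho(attenuator, e) * attenuator$density * t_mm / 10))
}

#' First (or subsequent) half-value layer of a spectrum
#'
#' Thickness of attenuator halving the air-kerma-weighted transmitted
#' intensity, matching what a pencil ionization chamber measures. Solved
#' by bisection to a relative kerma tolerance of 1e-8.
#'
#' @param spectrum an `xray_spectrum`.
#' @param attenuator an `attenuation_table` (default bundled aluminum).
#' @param fraction transmitted-kerma fraction defining the layer: 0.5 for
#'   the first HVL, 0.25 for the thickness giving one quarter, etc.
#' @return thickness in mm.
#' @export
first_hvl <- function(spectrum, attenuator = NULL, fraction = 0.5) {
  stopifnot(inherits(spectrum, "xray_spectrum"), sum(spectrum$fluence) > 0)
  if (is.null(attenuator)) attenuator <- attenuation_table("aluminum")
  air <- attenuation_table("air")
  k0 <- .kerma_transmitted(spectrum, attenuator, air, 0)
  target <- fraction * k0
  lo <- 0; hi <- 100
  if (.kerma_transmitted(spectrum, attenuator, air, hi) > target)
    stop("search interval does not bracket the value layer")
  repeat {
    mid <- (lo + hi) / 2
    k <- .kerma_transmitted(spectrum, attenuator, air, mid)
    if (abs(k - target) / k0 < 1e-8 || (hi - lo) < 1e-10) return(mid)
    if (k > target) lo <- mid else hi <- mid
  }
}

#' Calibrate added filtration to a measured first HVL
#'
#' Finds the added aluminum filtration for which the generated spectrum's
#' first HVL equals the measured value (the one printed spectrum
#' constraint a scanner QA report provides). Bisection on added
#' filtration in [0, 20] mm Al.
#'
#' @param kvp tube voltage, kV.
#' @param target_angle anode angle, degrees.
#' @param target_hvl measured first HVL, mm Al (default 7.56).
#' @param tol HVL tolerance, mm (default 0.01).
#' @return added filtration, mm Al.
#' @export
calibrate_filtration <- function(kvp = 120, target_angle = 10,
                                 target_hvl = 7.56, tol = 0.01) {
  f <- function(t) first_hvl(generate_spectrum(kvp, target_angle, t)) -
    target_hvl
  lo <- 0; hi <- 20
  flo <- f(lo); fhi <- f(hi)
  if (flo > 0) {
    if (abs(flo) <= tol) return(0)
    stop("target HVL below the unfiltered spectrum's HVL")
  }
  if (fhi < 0) stop("target HVL not achievable with <= 20 mm Al")
  repeat {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) <= tol / 2 || (hi - lo) < 1e-6) return(mid)
    if (fm < 0) lo <- mid else hi <- mid
  }
}

#' HVL-calibrated spectrum
#'
#' Convenience wrapper: calibrates the added filtration to the measured
#' first HVL and returns the resulting spectrum.
#'
#' @inheritParams calibrate_filtration
#' @export
calibrated_spectrum <- function(kvp = 120, target_angle = 10,
                                target_hvl = 7.56) {
  generate_spectrum(kvp, target_angle,
                    calibrate_filtration(kvp, target_angle, target_hvl))
}

#' Effective energy from an aluminum HVL
#'
#' The monoenergetic energy whose linear attenuation coefficient in
#' aluminum equals ln(2)/HVL, obtained by monotone log-log inversion of
#' the bundled aluminum table (restricted to >= 10 keV where mu is
#' monotone decreasing).
#'
#' @param hvl_al_mm first HVL in mm Al.
#' @return effective energy, keV.
#' @export
effective_energy <- function(hvl_al_mm) {
  stopifnot(hvl_al_mm > 0)
  al <- attenuation_table("aluminum")
  target <- log(2) / (hvl_al_mm / 10) / al$density  # mu/rho, cm2/g
  e <- al$energy_kev[al$energy_kev >= 10]
  mr <- al$mu_rho[al$energy_kev >= 10]
  if (target > max(mr) || target < min(mr))
    stop("HVL implies mu/rho outside the aluminum table range")
  # invert log-log piecewise-linear interpolation
  idx <- max(which(mr >= target))
  if (mr[idx] == target) return(e[idx])
  s <- (log(mr[idx + 1]) - log(mr[idx])) / (log(e[idx + 1]) - log(e[idx]))
  exp(log(e[idx]) + (log(target) - log(mr[idx])) / s)
}

#' Sample photon energies from a spectrum
#'
#' Inverse-CDF sampling over bins with uniform sampling inside the chosen
#' bin. Uses R's RNG stream (set a seed for reproducibility).
#'
#' @param spectrum an `xray_spectrum`.
#' @param n number of draws.
#' @return energies in keV.
#' @export
sample_energy <- function(spectrum, n = 1) {
  fl <- spectrum$fluence
  if (sum(fl) <= 0) stop("all-zero spectrum")
  cdf <- cumsum(fl) / sum(fl)
  u <- runif(n)
  b <- findInterval(u, cdf) + 1L
  lo <- spectrum$bin_edges[b]
  lo + runif(n) * diff(spectrum$bin_edges)[b]
}

#' Write / read a spectrum as two-column CSV (bin center keV, fluence)
#' @param spectrum an `xray_spectrum`.
#' @param path file path.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  write.csv(data.frame(energy_kev = .bin_centers(spectrum),
                       fluence = spectrum$fluence),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @param kvp tube voltage recorded on import.
#' @export
read_spectrum_csv <- function(path, kvp = NULL) {
  df <- read.csv(path)
  dE <- diff(df$energy_kev)
  stopifnot(all(abs(dE - dE[1]) < 1e-9))
  edges <- c(df$energy_kev - dE[1] / 2, df$energy_kev[nrow(df)] + dE[1] / 2)
  if (is.null(kvp)) kvp <- max(edges)
  structure(list(bin_edges = edges, fluence = df$fluence / sum(df$fluence),
                 kvp = kvp, target_angle = NA_real_,
                 added_filtration_al = NA_real_),
            class = "xray_spectrum")
}
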