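#' @useDynLib ctdosim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx rexp runif setNames weighted.mean
#' @importFrom utils read.csv write.csv
NULL

# Classical electron radius^2 in cm^2 and electron rest energy in keV.
.RE2_CM2 <- 7.940787e-26
.MEC2_KEV <- 510.99895
.AVOGADRO <- 6.02214076e23
.KEV_TO_J <- 1.602176634e-16

.ctdosim_env <- new.env(parent = emptyenv())

.extdata <- function(...) {
  system.file("extdata", ..., package = "ctdosim", mustWork = TRUE)
}

#' Material catalog
#'
#' The catalog of materials bundled with the package: reference density
#' (g/cm3), mean electrons-per-nucleon Z/A, effective atomic number, and
#' either the name of a bundled attenuation grid or a mixture recipe
#' (mass fractions of other catalog entries).
#'
#' @return A data.frame with one row per material.
#' @export
material_catalog <- function() {
  if (is.null(.ctdosim_env$catalog)) {
    .ctdosim_env$catalog <- read.csv(.extdata("materials.csv"),
                                     stringsAsFactors = FALSE)
  }
  .ctdosim_env$catalog
}

.material_row <- function(material) {
  cat <- material_catalog()
  i <- match(material, cat$name)
  if (is.na(i)) stop("unknown material: ", material)
  cat[i, , drop = FALSE]
}

#' Photon attenuation table for a material
#'
#' Loads the bundled NIST-style grid of mass attenuation (mu/rho) and mass
#' energy-absorption (muen/rho) coefficients for a catalog material, or
#' builds one by mass-fraction mixing for mixture materials. Interpolation
#' between grid energies is log-log.
#'
#' @param material catalog material name (e.g. "aluminum", "air",
#'   "soft_tissue"), or a data.frame with columns `energy_kev`, `mu_rho`,
#'   `muen_rho` for a user-supplied table.
#' @param density reference density g/cm3; defaults to the catalog value.
#' @param name table name when `material` is a data.frame.
#' @return An object of class `attenuation_table`.
#' @export
attenuation_table <- function(material, density = NULL, name = NULL) {
  if (is.data.frame(material)) {
    tab <- material
    nm <- if (is.null(name)) "custom" else name
    if (is.null(density)) stop("density required for a custom table")
    z_a <- 0.55
    zeff <- 7.5
  } else {
    row <- .material_row(material)
    nm <- row$name
    if (is.null(density)) density <- row$density
    z_a <- row$z_a
    zeff <- row$zeff
    if (nzchar(row$components) && !is.na(row$components)) {
      tab <- .mix_tables(row$components)
    } else {
      tab <- read.csv(.extdata("attenuation", paste0(row$table, ".csv")))
    }
  }
  stopifnot(all(diff(tab$energy_kev) > 0),
            all(tab$mu_rho > 0), all(tab$muen_rho > 0))
  structure(list(name = nm, energy_kev = tab$energy_kev,
                 mu_rho = tab$mu_rho, muen_rho = tab$muen_rho,
                 density = density, z_a = z_a, zeff = zeff),
            class = "attenuation_table")
}

.mix_tables <- function(components) {
  parts <- strsplit(strsplit(components, ";")[[1]], ":")
  names <- vapply(parts, `[`, "", 1L)
  w <- as.numeric(vapply(parts, `[`, "", 2L))
  w <- w / sum(w)
  tabs <- lapply(names, function(n) {
    row <- .material_row(n)
    read.csv(.extdata("attenuation", paste0(row$table, ".csv")))
  })
  e <- tabs[[1]]$energy_kev
  mu <- 0; muen <- 0
  for (k in seq_along(tabs)) {
    mu <- mu + w[k] * .loglog_interp(tabs[[k]]$energy_kev, tabs[[k]]$mu_rho, e)
    muen <- muen + w[k] * .loglog_interp(tabs[[k]]$energy_kev, tabs[[k]]$muen_rho, e)
  }
  data.frame(energy_kev = e, mu_rho = mu, muen_rho = muen)
}

# Log-log interpolation with log-linear extrapolation at the ends.
.loglog_interp <- function(x, y, xout) {
  lx <- log(x); ly <- log(y); lo <- log(xout)
  n <- length(x)
  idx <- findInterval(lo, lx, all.inside = TRUE)
  s <- (ly[idx + 1L] - ly[idx]) / (lx[idx + 1L] - lx[idx])
  exp(ly[idx] + s * (lo - lx[idx]))
}

#' Mass attenuation coefficient at given energies
#'
#' @param table an `attenuation_table`.
#' @param energy_kev photon energies, keV.
#' @return mu/rho in cm2/g (vectorized).
#' @export
mu_over_rho <- function(table, energy_kev) {
  stopifnot(inherits(table, "attenuation_table"), all(energy_kev > 0))
  .loglog_interp(table$energy_kev, table$mu_rho, energy_kev)
}

#' Mass energy-absorption coefficient at given energies
#' @inheritParams mu_over_rho
#' @return muen/rho in cm2/g.
#' @export
muen_over_rho <- function(table, energy_kev) {
  stopifnot(inherits(table, "attenuation_table"), all(energy_kev > 0))
  .loglog_interp(table$energy_kev, table$muen_rho, energy_kev)
}

#' Linear attenuation coefficient (1/cm) at the table's reference density
#' @inheritParams mu_over_rho
#' @export
mu_linear <- function(table, energy_kev) {
  mu_over_rho(table, energy_kev) * table$density
}

#' Ratio of mass energy-absorption coefficients of two materials
#'
#' Used as the tissue-to-air conversion factor in point-dosimeter dose
#' equations, evaluated at the beam's effective energy.
#'
#' @param material_num,material_den catalog material names (numerator,
#'   denominator).
#' @param energy_kev energy at which to evaluate, keV.
#' @export
muen_ratio <- function(material_num, material_den, energy_kev) {
  tn <- attenuation_table(material_num)
  td <- attenuation_table(material_den)
  muen_over_rho(tn, energy_kev) / muen_over_rho(td, energy_kev)
}

#' Total Klein-Nishina cross-section per electron
#'
#' Closed-form free-electron Compton cross-section, cm2/electron.
#'
#' @param energy_kev photon energy, keV.
#' @export
klein_nishina_total <- function(energy_kev) {
  k <- energy_kev / .MEC2_KEV
  term1 <- (1 + k) / k^2 * (2 * (1 + k) / (1 + 2 * k) - log(1 + 2 * k) / k)
  term2 <- log(1 + 2 * k) / (2 * k)
  term3 <- -(1 + 3 * k) / (1 + 2 * k)^2
  2 * pi * .RE2_CM2 * (term1 + term2 + term3)
}

#' Mean energy-transfer fraction of a Klein-Nishina scatter
#'
#' Average fraction of the photon energy handed to the recoil electron
#' in a free-electron Compton event, by quadrature over the
#' Klein-Nishina angular density.
#'
#' @param energy_kev photon energies, keV.
#' @export
kn_transfer_fraction <- function(energy_kev) {
  mu <- seq(-1, 1, length.out = 2001)
  vapply(energy_kev, function(E) {
    k <- E / .MEC2_KEV
    r <- 1 / (1 + k * (1 - mu))              # E'/E
    pdf <- r^2 * (r + 1 / r - (1 - mu^2))    # ~ dsigma/dmu
    sum(pdf * (1 - r)) / sum(pdf)
  }, 0)
}

#' Partial interaction coefficients for transport
#'
#' Splits the tabulated total mu/rho into photoelectric, incoherent
#' (Compton) and coherent (Rayleigh) channels. Incoherent comes from the
#' closed-form Klein-Nishina cross-section times electrons per gram. The
#' photoelectric coefficient is then chosen so that the expected energy
#' deposited by sampled interactions reproduces the tabulated mass
#' energy-absorption coefficient (pe + incoh x mean KN transfer fraction
#' = muen/rho), clamped to the physical range; the coherent channel is
#' the remainder. This "kerma-consistent" split keeps analog deposition
#' and the muen-based track-length estimator in agreement without
#' requiring bound-electron cross-section tables.
#'
#' @param material catalog material name.
#' @param energy_kev photon energies, keV.
#' @return data.frame with columns `energy_kev`, `total`, `pe`, `incoh`,
#'   `coh` (all cm2/g).
#' @export
partial_mu_rho <- function(material, energy_kev) {
  tab <- attenuation_table(material)
  total <- mu_over_rho(tab, energy_kev)
  muen <- muen_over_rho(tab, energy_kev)
  incoh <- .AVOGADRO * tab$z_a * klein_nishina_total(energy_kev)
  incoh <- pmin(incoh, total)
  pe <- pmin(pmax(muen - incoh * kn_transfer_fraction(energy_kev), 0),
             total - incoh)
  coh <- total - incoh - pe
  data.frame(energy_kev = energy_kev, total = total, pe = pe,
             incoh = incoh, coh = coh)
}
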