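# Shared fixtures, built in code. The calibrated spectrum and the
# coarse synthetic abdomen are memoized per test run.

.fx <- new.env()

fx_spectrum <- function() {
  if (is.null(.fx$spectrum)) .fx$spectrum <- calibrated_spectrum()
  .fx$spectrum
}

# monoenergetic-style spectrum: all fluence in the bin containing e_kev
fx_line_spectrum <- function(e_kev) {
  sp <- generate_spectrum(120, 10, 0)
  sp$fluence[] <- 0
  sp$fluence[findInterval(e_kev, sp$bin_edges, rightmost.closed = TRUE)] <- 1
  sp
}

# homogeneous slab: `thick_mm` of `material` along y, wide in x/z
fx_slab <- function(material = "water", thick_mm = 50, ny = 25,
                    density = NULL) {
  row <- material_catalog()[material_catalog()$name == material, ]
  if (is.null(density)) density <- row$density
  dy <- thick_mm / ny
  mat <- array(as.integer(row$id), c(5, ny, 5))
  voxel_phantom(mat, array(density, dim(mat)),
                spacing_mm = c(20, dy, 20),
                origin_mm = c(-40, -thick_mm / 2 + dy / 2, -40))
}

# pencil-beam geometry (degenerate fan/cone), no table
fx_pencil_geom <- function() {
  scanner_geometry(fan_angle_deg = 0.01, beam_width_mm = 0.01,
                   table = NULL)
}

# small abdomen for end-to-end runs (coarse grid, fast)
fx_abdomen_small <- function(seed = 1L) {
  key <- paste0("abd", seed)
  if (is.null(.fx[[key]]))
    .fx[[key]] <- make_synthetic_abdomen(spacing_mm = c(5.44, 5.44, 5),
                                         seed = seed)
  .fx[[key]]
}

# chi-square goodness of fit of draws against expected bin probabilities
fx_chisq_p <- function(counts, probs) {
  probs <- probs / sum(probs)
  keep <- probs * sum(counts) >= 10
  if (any(!keep)) {
    counts <- c(counts[keep], sum(counts[!keep]))
    probs <- c(probs[keep], sum(probs[!keep]))
  }
  if (any(probs == 0)) {
    if (any(counts[probs == 0] > 0)) return(0)
    counts <- counts[probs > 0]
    probs <- probs[probs > 0]
  }
  suppressWarnings(stats::chisq.test(counts, p = probs / sum(probs))$p.value)
}

# log-log interpolation used by test oracles, independent of the package
fx_loglog <- function(x, y, xo) {
  i <- findInterval(xo, x)
  exp(log(y[i]) + (log(y[i + 1]) - log(y[i])) *
        (log(xo) - log(x[i])) / (log(x[i + 1]) - log(x[i])))
}

fx_extdata <- function(...) {
  system.file("extdata", ..., package = "ctdosim", mustWork = TRUE)
}
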