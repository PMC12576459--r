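test_that("CTDI100: scalar conversion and quadrature of a profile", {
  expect_equal(ctdi100_from_tally(8, 80), 10)     # 8 x 100/80
  expect_equal(ctdi100_from_tally(0, 80), 0)
  # triangular profile peaking mid-chamber: trapezoid integral / NT
  z <- seq(-50, 50, by = 5)
  prof <- data.frame(z_mm = z, dose = 10 - abs(z) / 5)
  integral <- sum(diff(z) * (head(prof$dose, -1) + tail(prof$dose, -1)) / 2)
  expect_equal(ctdi100_from_tally(prof, 80), integral / 80)
  expect_error(ctdi100_from_tally(prof, 0))
  expect_error(ctdi100_from_tally(data.frame(z_mm = c(0, 10),
                                             dose = c(1, 1)), 80),
               "chamber length")
})

test_that("CTDIw: worked examples and permutation invariance", {
  expect_equal(round(ctdi_w(3.59, c(7.75, 7.70, 6.87, 7.71)), 2), 6.20)
  expect_equal(round(ctdi_w(3.67, c(7.92, 7.86, 7.41, 7.88)), 2), 6.40)
  expect_equal(ctdi_w(5, rep(5, 4)), 5)  # convexity fixed point
  p <- c(7.1, 6.9, 7.4, 7.0)
  expect_equal(ctdi_w(3.5, p), ctdi_w(3.5, rev(p)))
  expect_equal(ctdi_w(3.5, p), ctdi_w(3.5, p[c(3, 1, 4, 2)]))
})

test_that("normalization factor and round-trip", {
  expect_equal(normalization_factor(10, 2), 5)
  expect_equal(normalization_factor(7, 7), 1)
  sim <- 2.3e-16
  nf <- normalization_factor(12, sim)
  expect_equal(sim * nf, 12, tolerance = 1e-15)
  expect_error(normalization_factor(10, 0), "positive")
})

test_that("relative difference: value, sign, errors", {
  expect_equal(relative_difference(6.40, 6.20), 3.2258, tolerance = 1e-4)
  expect_equal(relative_difference(5, 5), 0)
  expect_lt(relative_difference(4.9, 5), 0)
  expect_error(relative_difference(1, 0), "nonzero")
})

test_that("dose reduction: worked examples", {
  expect_equal(round(dose_reduction_percent(33.3, 11.6), 1), 65.2)
  expect_equal(round(dose_reduction_percent(32.3, 12.8), 1), 60.4)
  expect_equal(dose_reduction_percent(10, 10), 0)
  expect_error(dose_reduction_percent(0, 1), "positive")
})

test_that("RPLD correction factor and organ dose equation", {
  expect_equal(rpld_correction_factor(1, 1), 1)
  expect_equal(rpld_correction_factor(1.00, 3.125), 0.32)
  c0 <- rpld_correction_factor(2.5, 7.3)
  expect_equal(c0 * 7.3, 2.5, tolerance = 1e-12)
  expect_error(rpld_correction_factor(1, 0), "positive")
  expect_equal(rpld_organ_dose(10, 0, 1, muen_ratio_tissue_air = 1.06),
               10.6)
  expect_equal(rpld_organ_dose(c(5, 5, 5), background = 5, correction = 1,
                               muen_ratio_tissue_air = 1.06), 0)
  # default ratio comes from the bundled tables at the effective energy
  auto <- rpld_organ_dose(10, 0, 1)
  expect_gt(auto, 10.4); expect_lt(auto, 10.7)
  expect_warning(rpld_organ_dose(1, background = 2, correction = 1,
                                 muen_ratio_tissue_air = 1), "background")
  expect_error(rpld_organ_dose(numeric(0)), "readings")
})

test_that("organ dose report: linearity, single-voxel organ, self-consistency", {
  ph <- fx_abdomen_small()
  tal <- run_projection(ph, scanner_geometry(table = NULL), fx_spectrum(),
                        default_bowtie(), 0, 0, 3e4, seed = 41)
  r1 <- organ_dose_from_tally(tal, nf = 1e15, mas_scale = 1)
  r2 <- organ_dose_from_tally(tal, nf = 1e15, mas_scale = 2)
  expect_equal(r2$dose_mgy, 2 * r1$dose_mgy, tolerance = 1e-12)
  expect_setequal(r1$organ, names(ph$organ_names))
  # analog estimator invariant: region dose = voxel energy / region mass
  mat <- array(5L, c(3, 3, 3)); dens <- array(1, c(3, 3, 3))
  lab <- array(0L, c(3, 3, 3)); lab[2, 2, 2] <- 1L
  ph1 <- voxel_phantom(mat, dens, c(10, 10, 10), c(-10, -10, -10),
                       organ_label = lab, organ_names = c(one = 1L))
  t1 <- run_projection(ph1, fx_pencil_geom(), fx_spectrum(),
                       flat_bowtie(), 0, 0, 2e4, seed = 43)
  d <- region_dose(t1, estimator = "analog")
  mass_kg <- 1 * 1e-3  # one 1 cm^3 voxel of water
  expect_equal(d$dose_gy_per_photon[d$region == "one"],
               t1$edep_kev[2, 2, 2] * ctdosim:::.KEV_TO_J / mass_kg /
                 t1$n_photons, tolerance = 1e-12)
  # comparison table recomputable from stored doses
  sim <- data.frame(organ = c("liver", "kidneys"), dose_mgy = c(32.4, 30.1))
  meas <- data.frame(organ = c("liver", "kidneys"), dose_mgy = c(33.3, 32.3))
  cmp <- compare_doses(sim, meas)
  expect_equal(cmp$rd_percent,
               (cmp$dose_mgy_sim - cmp$dose_mgy_meas) /
                 cmp$dose_mgy_meas * 100)
  expect_equal(round(cmp$rd_percent[1], 2), -2.7)
})
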