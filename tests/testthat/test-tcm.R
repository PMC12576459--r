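test_that("tube current extraction: passthrough, sorting, fallbacks", {
  dir <- withr::local_tempdir()
  ph <- fx_abdomen_small()
  make_fixture_series(dir, phantom = ph, slice_thickness_mm = 2.5,
                      ma_profile = "constant", mean_ma = 100, seed = 2)
  s <- extract_tube_currents(dir)
  expect_equal(nrow(s), 70)
  expect_true(all(s$tube_current_ma == 100))
  expect_true(all(diff(s$z_mm) > 0))
  # ramp stays monotone through extraction
  dir2 <- withr::local_tempdir()
  make_fixture_series(dir2, phantom = ph, slice_thickness_mm = 2.5,
                      ma_profile = "ramp", mean_ma = 100, seed = 2)
  s2 <- extract_tube_currents(dir2)
  expect_true(all(diff(s2$tube_current_ma) >= 0))
})

test_that("per-rotation averaging: window count, means, interpolation", {
  # 280 slices x 0.625 mm over 175 mm; feed 40.64 mm -> 5 windows
  z <- (seq_len(280) - 0.5) * 0.625
  samples <- data.frame(z_mm = z, tube_current_ma = rep(100, 280))
  prof <- per_rotation_average(samples, 0.508 * 80, scan_start_z_mm = 0)
  expect_equal(nrow(prof), ceiling(175 / 40.64))
  expect_equal(nrow(prof), 5)
  expect_true(all(prof$tube_current_ma == 100))
  # step profile: a window straddling the step averages between levels
  ma_step <- ifelse(z < 87.5, 100, 200)
  prof2 <- per_rotation_average(data.frame(z_mm = z,
                                           tube_current_ma = ma_step),
                                40.64, 0)
  straddle <- prof2$tube_current_ma[3]  # window [81.28, 121.92)
  expect_gt(straddle, 100); expect_lt(straddle, 200)
  expect_equal(prof2$tube_current_ma[1], 100)
  expect_equal(prof2$tube_current_ma[5], 200)
  # empty interior window is interpolated and flagged
  sp <- data.frame(z_mm = c(5, 90), tube_current_ma = c(100, 300))
  prof3 <- per_rotation_average(sp, 40.64, 0)
  expect_true(prof3$interpolated[2])
  expect_gt(prof3$tube_current_ma[2], 100)
  expect_lt(prof3$tube_current_ma[2], 300)
  expect_error(per_rotation_average(samples[0, ], 40.64), "samples")
})

test_that("projection weights: normalization, scale separation, edges", {
  geom <- scanner_geometry()
  sched <- projection_schedule(scan_protocol(mode = "helical"), geom)
  prof <- data.frame(rotation = 1:5, z_mm = (1:5 - 0.5) * 40.64,
                     tube_current_ma = c(100, 120, 140, 120, 100))
  class(prof) <- c("tcm_profile", "data.frame")
  pw <- projection_weights(prof, sched, rotation_time_s = 0.5)
  expect_length(pw$weights, 173)
  expect_equal(mean(pw$weights), 1, tolerance = 1e-12)
  expect_true(all(pw$weights > 0))
  # constant profile -> all weights exactly 1
  pc <- prof; pc$tube_current_ma <- rep(80, 5)
  pwc <- projection_weights(pc, sched)
  expect_true(all(pwc$weights == 1))
  expect_equal(pwc$mas_per_projection, 80 * 0.5 / 40)
  # doubling mA: weights unchanged, scale doubled
  p2 <- prof; p2$tube_current_ma <- prof$tube_current_ma * 2
  pw2 <- projection_weights(p2, sched)
  expect_equal(pw2$weights, pw$weights, tolerance = 1e-12)
  expect_equal(pw2$mas_per_projection, 2 * pw$mas_per_projection)
})

test_that("two-rotation profile: hand-computable piecewise weights", {
  geom <- scanner_geometry()
  prot <- scan_protocol(mode = "helical", scan_length_mm = 2 * 40.64)
  sched <- projection_schedule(prot, geom)
  expect_equal(nrow(sched), 80)
  prof <- data.frame(rotation = 1:2, z_mm = c(20.32, 60.96),
                     tube_current_ma = c(100, 300))
  class(prof) <- c("tcm_profile", "data.frame")
  pw <- projection_weights(prof, sched)
  expect_equal(mean(pw$weights), 1, tolerance = 1e-12)
  # clamped ends take the nearest rotation's mean
  expect_equal(pw$ma[1], 100)
  expect_equal(pw$ma[80], 300)
  expect_lt(mean(pw$weights[1:40]), 1)   # first rotation below average
  expect_gt(mean(pw$weights[41:80]), 1)
  expect_true(all(diff(pw$ma) >= 0))
  # piecewise-constant option: exactly two levels
  pwc <- projection_weights(prof, sched, method = "constant")
  expect_setequal(unique(pwc$ma), c(100, 300))
})

test_that("apply_weights is exact, bilinear, and permutation-consistent", {
  ph <- fx_abdomen_small()
  geom <- scanner_geometry()
  prot <- scan_protocol(mode = "helical", scan_length_mm = 40.64)
  tal <- run_scan(ph, geom, prot, fx_spectrum(), default_bowtie(),
                  n_photons_per_projection = 300, base_seed = 3)
  n_proj <- nrow(tal$schedule)
  set.seed(8)
  w <- runif(n_proj, 0.5, 1.5); w <- w / mean(w)
  tw <- apply_weights(tal, w)
  # exact dot product of stored sub-tallies with the weights
  expect_equal(unname(rowSums(sweep(tw$proj_kerma_kev, 2, w, `*`))),
               as.numeric(tw$proj_kerma_kev %*% w), tolerance = 1e-15)
  d1 <- region_dose(tw)$dose_gy_per_photon[-1]
  manual <- (tal$proj_kerma_kev[-1, , drop = FALSE] %*% w) *
    ctdosim:::.KEV_TO_J / (tal$region_masses_g / 1000) / tal$n_photons
  expect_equal(d1, as.numeric(manual), tolerance = 1e-12)
  # all weights 1 reproduces the unweighted result
  t1 <- apply_weights(tal, rep(1, n_proj))
  expect_equal(region_dose(t1)$dose_gy_per_photon,
               region_dose(tal)$dose_gy_per_photon, tolerance = 1e-12)
  # permuting weights together with sub-tallies leaves doses unchanged
  perm <- sample(n_proj)
  tp <- tal
  tp$proj_kerma_kev <- tal$proj_kerma_kev[, perm]
  tp$proj_region_kev <- tal$proj_region_kev[, perm]
  expect_equal(region_dose(apply_weights(tp, w[perm]))$dose_gy_per_photon,
               region_dose(apply_weights(tal, w))$dose_gy_per_photon,
               tolerance = 1e-12)
  expect_error(apply_weights(tal, w[-1]), "count")
})

test_that("weight mean is exactly 1 over generated profiles", {
  geom <- scanner_geometry()
  sched <- projection_schedule(scan_protocol(mode = "helical"), geom)
  set.seed(19)
  for (i in 1:5) {
    prof <- data.frame(rotation = 1:5, z_mm = (1:5 - 0.5) * 40.64,
                       tube_current_ma = runif(5, 50, 400))
    class(prof) <- c("tcm_profile", "data.frame")
    pw <- projection_weights(prof, sched)
    expect_equal(sum(pw$weights), nrow(sched), tolerance = 1e-9)
  }
})
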