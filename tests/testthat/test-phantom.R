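test_that("HU conversion: scale endpoints, monotone density, purity", {
  calib <- schneider_calibration()
  lo <- hu_to_material(-1000, calib)
  expect_equal(material_catalog()$name[material_catalog()$id ==
                                         lo$material_id], "air")
  expect_equal(lo$density, 0.0012, tolerance = 0.05)
  mid <- hu_to_material(0, calib)
  expect_equal(material_catalog()$name[material_catalog()$id ==
                                         mid$material_id], "soft_tissue")
  expect_equal(mid$density, 1.03, tolerance = 0.04)
  sweep <- hu_to_material(seq(-1000, 1500, by = 1), calib)$density
  expect_true(all(diff(sweep) >= -1e-12))
  # pure function: same HU, same output
  expect_identical(hu_to_material(c(57, 57), calib),
                   hu_to_material(c(57, 57), calib))
  expect_warning(hu_to_material(5000, calib), "clamped")
})

test_that("coarse-graining conserves mass and rebins block-mean HU", {
  ph <- make_synthetic_abdomen(spacing_mm = c(0.68, 0.68, 5),
                               body_halfaxes_mm = c(30, 20),
                               length_mm = 20, seed = 2)
  # crop to dims divisible by the factors so no padding is involved
  d4 <- floor(dim(ph$material_id) / c(4, 4, 1)) * c(4, 4, 1)
  ix <- seq_len(d4[1]); iy <- seq_len(d4[2]); iz <- seq_len(d4[3])
  ph <- voxel_phantom(ph$material_id[ix, iy, iz],
                      ph$density[ix, iy, iz], ph$spacing_mm,
                      ph$origin_mm, ph$organ_label[ix, iy, iz],
                      ph$organ_names, hu = ph$hu[ix, iy, iz])
  cg <- coarse_grain(ph, c(4, 4, 1))
  expect_equal(cg$spacing_mm, c(2.72, 2.72, 5))
  expect_equal(dim(cg$material_id), c(dim(ph$material_id)[1] / 4,
                                      dim(ph$material_id)[2] / 4,
                                      dim(ph$material_id)[3]))
  expect_equal(phantom_mass(cg), phantom_mass(ph), tolerance = 1e-9)
  # uniform phantom: only dims/spacing change
  u <- voxel_phantom(array(4L, c(8, 8, 2)), array(1.07, c(8, 8, 2)),
                     c(1, 1, 5), c(0, 0, 0),
                     hu = array(40, c(8, 8, 2)))
  cu <- coarse_grain(u, c(4, 4, 1))
  expect_true(all(cu$material_id == 4L))
  expect_true(all(cu$density == 1.07))
  expect_warning(coarse_grain(
    voxel_phantom(array(5L, c(6, 6, 1)), array(1, c(6, 6, 1)),
                  c(1, 1, 5), c(0, 0, 0), hu = array(0, c(6, 6, 1))),
    c(4, 4, 1)), "padding")
})

test_that("CTDI phantom: geometry, density, mass oracle", {
  ph <- make_ctdi_phantom(spacing_mm = c(2, 2, 5))
  pmma_id <- material_catalog()$id[material_catalog()$name == "pmma"]
  expect_true(all(ph$density[ph$material_id == pmma_id] == 1.19))
  bores <- attr(ph, "bores")
  expect_equal(nrow(bores), 5)
  r <- sqrt(rowSums(bores[-1, ]^2))
  expect_equal(unname(r), rep(150, 4))  # 1 cm below the 160 mm surface
  expect_equal(sort(unique(as.vector(ph$organ_label))), 0:5)
  # analytic mass: PMMA cylinder minus five air bores
  m_oracle <- (pi * 16^2 * 15 * 1.19) -
    5 * (pi * 0.655^2 * 15 * (1.19 - 0.001205))
  expect_equal(phantom_mass(ph), m_oracle, tolerance = 0.01)
})

test_that("synthetic abdomen: labels disjoint, reproducible, volume oracle", {
  ph <- fx_abdomen_small()
  expect_setequal(names(ph$organ_names),
                  c("liver", "stomach", "gallbladder", "spleen",
                    "pancreas", "kidneys"))
  expect_equal(sort(unique(as.vector(ph$organ_label))), 0:6)
  ph2 <- make_synthetic_abdomen(spacing_mm = c(5.44, 5.44, 5), seed = 1)
  expect_identical(ph$organ_label, ph2$organ_label)
  expect_identical(ph$density, ph2$density)
  ph3 <- make_synthetic_abdomen(spacing_mm = c(5.44, 5.44, 5), seed = 9)
  expect_false(identical(ph$organ_label, ph3$organ_label))
  # voxelized organ volumes vs analytic ellipsoids (finer grid)
  phf <- make_synthetic_abdomen(seed = 4)
  organs <- ctdosim:::.default_abdomen_organs()
  vox_cm3 <- prod(phf$spacing_mm) / 1000
  for (org in unique(organs$name)) {
    rows <- organs[organs$name == org, ]
    v_analytic <- sum(4 / 3 * pi * rows$rx * rows$ry * rows$rz) / 1000
    v_vox <- sum(phf$organ_label == phf$organ_names[[org]]) * vox_cm3
    expect_equal(v_vox, v_analytic, tolerance = 0.05, label = org)
  }
})

test_that("table stamping attenuates the 6 o'clock beam", {
  ph <- make_air_phantom(spacing_mm = c(5, 5, 10), length_mm = 100)
  pht <- add_table(ph, table_model())
  expect_gt(prod(dim(pht$material_id)), prod(dim(ph$material_id)))
  sp <- fx_line_spectrum(60.25)
  geom <- scanner_geometry(table = NULL)
  d0 <- region_dose(run_projection(pht, geom, sp, flat_bowtie(), 0, 0,
                                   1e5, seed = 5))
  d180 <- region_dose(run_projection(pht, geom, sp, flat_bowtie(), 180, 0,
                                     1e5, seed = 5))
  expect_lt(d180$dose_gy_per_photon[d180$region == "chamber"],
            0.95 * d0$dose_gy_per_photon[d0$region == "chamber"])
})
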