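grad561 <- gradient_spec(Gz = 56.1, readout_axis = "z")

test_that("field-to-displacement conversion reproduces hand-derived values", {
  # 477.7 Hz / (42.5774 MHz/T * 56.1 mT/m) = 0.2000 mm
  expect_equal(hz_to_mm(477.7, grad561), 0.2, tolerance = 1e-3)
  # 185 Hz -> 0.0775 mm
  expect_equal(hz_to_mm(185, grad561), 0.0775, tolerance = 1e-3)
  # zero in, zero out
  g <- image_volume(array(0, c(6, 6, 6)), rep(1, 3))
  fm <- field_map(array(0, c(6, 6, 6)), rep(1, 3))
  expect_true(all(b0_displacement_map(fm, grad561)$displacement == 0))
})

test_that("displacement map is homogeneous in the field and inverse in G", {
  offs <- array(rnorm(6^3, sd = 100), c(6, 6, 6))
  fm1 <- field_map(offs, rep(1, 3))
  fm3 <- field_map(3 * offs, rep(1, 3))
  m1 <- b0_displacement_map(fm1, grad561)$displacement
  m3 <- b0_displacement_map(fm3, grad561)$displacement
  expect_equal(m3, 3 * m1, tolerance = 1e-12)

  gr2 <- gradient_spec(Gz = 2 * 56.1)
  m_half <- b0_displacement_map(fm1, gr2)$displacement
  expect_equal(m_half, m1 / 2, tolerance = 1e-12)
})

test_that("unit metadata is mandatory for displacement conversion", {
  fm_ppm <- field_map(array(1, c(4, 4, 4)), rep(1, 3), unit = "ppm")
  expect_error(b0_displacement_map(fm_ppm, grad561), "Hz")
})

test_that("readout unwarping is exact for zero and integer-voxel maps", {
  vol <- smooth_volume_fixture(n = 12, spacing = 0.2)
  fm0 <- field_map(array(0, dim(vol$data)), vol$spacing, vol$origin)
  map0 <- b0_displacement_map(fm0, grad561)
  expect_identical(apply_b0_correction(vol, map0)$data, vol$data)

  # uniform 0.2 mm displacement on a 0.2 mm grid: exact 1-voxel shift
  fm1 <- field_map(array(477.7, dim(vol$data)), vol$spacing, vol$origin)
  map1 <- b0_displacement_map(fm1, grad561)
  out <- apply_b0_correction(vol, map1)
  expect_equal(out$data[, , 5], vol$data[, , 6], tolerance = 1e-5)
  expect_equal(out$data[4, 9, 2], vol$data[4, 9, 3], tolerance = 1e-5)
})

test_that("unwarping inverts the forward distortion at the landmarks", {
  geom <- phantom_geometry()
  ph <- mid_phantom()
  shim <- shim_config(c(z2 = 400))
  dist <- distort_volume(ph$mr, field = shim, grad = grad561)
  fm <- make_shim_field(shim, ph$mr)
  corr <- apply_b0_correction(dist, b0_displacement_map(fm, grad561))
  det <- detect_grid_landmarks(corr, geom)
  dd <- suppressWarnings(landmark_displacements(ph$landmarks, det))
  expect_lt(median(dd$euclidean), 0.25 * ph$mr$spacing[1])
})

test_that("correction requires matching geometry and readout axis", {
  vol <- smooth_volume_fixture(n = 10)
  fm <- field_map(array(0, c(5, 5, 5)), rep(0.4, 3))
  map <- b0_displacement_map(fm, grad561)
  expect_error(apply_b0_correction(vol, map), "geometry")
  volx <- image_volume(vol$data, vol$spacing, vol$origin,
                       encoding = c(x = "frequency", y = "phase",
                                    z = "slice"))
  fm2 <- field_map(array(0, dim(vol$data)), vol$spacing, vol$origin)
  expect_error(apply_b0_correction(volx, b0_displacement_map(fm2, grad561)),
               "axis")
})

test_that("displacement summaries match hand-computed values", {
  s <- summarize_displacements(c(0.1, 0.1, 0.3, 0.3), threshold = 0.2)
  expect_equal(s$fraction_below_threshold, 0.5)
  expect_equal(s$median, 0.2)
  expect_equal(s$max, 0.3)

  s2 <- summarize_displacements(rep(0.1, 20), threshold = 0.2)
  expect_equal(s2$median, 0.1)
  expect_equal(s2$max, 0.1)
  expect_equal(s2$fraction_below_threshold, 1)
  expect_equal(s2$n_outliers, 0)

  # a single extreme value is excluded from the outlier-trimmed max
  s3 <- summarize_displacements(c(rep(0.05, 30), 5), threshold = 0.2)
  expect_equal(s3$max, 5)
  expect_equal(s3$max_excl_outliers, 0.05)
  expect_equal(s3$n_outliers, 1)
})

test_that("per-region stats skip empty regions and keep names", {
  g <- image_volume(array(0, c(10, 10, 10)), rep(1, 3))
  fm <- field_map(array(100, c(10, 10, 10)), rep(1, 3))
  map <- b0_displacement_map(fm, grad561)
  regions <- list(all = array(TRUE, c(10, 10, 10)),
                  none = array(FALSE, c(10, 10, 10)))
  expect_warning(st <- voi_displacement_stats(map, regions, 0.2), "empty")
  expect_equal(st$region, "all")
  expect_equal(st$median, hz_to_mm(100, grad561), tolerance = 1e-9)
})

test_that("even-order fields give non-decreasing max displacement across
           nested shells", {
  g <- image_volume(array(0, c(40, 40, 56)), rep(0.7, 3))
  fm <- make_shim_field(shim_config(c(z2 = 400, x2y2 = 0)), g)
  map <- b0_displacement_map(fm, grad561)
  masks <- nested_voi_masks(standard_vois(), g)
  st <- voi_displacement_stats(map, masks, 0.2)
  expect_true(all(diff(st$max) >= -1e-12))
  expect_gt(st$max[3], st$max[1])
})
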