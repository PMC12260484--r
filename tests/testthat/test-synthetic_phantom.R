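test_that("phantom geometry invariants and lattice pitch", {
  geom <- phantom_geometry()
  expect_equal(geom$pitch, 3.2)  # 2.5 mm gap + 0.7 mm wall
  expect_error(phantom_geometry(gap = -1), "positive")
  expect_error(phantom_geometry(outer_extent = c(4, 4, 4)), "2 lattice cells")
  # spacing must resolve the wall
  expect_error(build_phantom_pair(geom, spacing = 1), "too coarse")
})

test_that("truth landmarks sit on the lattice, neighbors one pitch apart", {
  ph <- coarse_phantom()
  lms <- ph$landmarks
  # neighbor along x of L0_0_0 is L1_0_0, exactly 3.2 mm away
  p0 <- unlist(lms[lms$id == "L0_0_0", c("x", "y", "z")])
  p1 <- unlist(lms[lms$id == "L1_0_0", c("x", "y", "z")])
  expect_equal(sqrt(sum((p1 - p0)^2)), 3.2, tolerance = 1e-12)
  expect_equal(p0, c(x = 0, y = 0, z = 0), tolerance = 1e-12)
  # all coordinates are integer multiples of the pitch
  expect_true(all(abs(as.matrix(lms[, c("x", "y", "z")]) / 3.2 -
                      round(as.matrix(lms[, c("x", "y", "z")]) / 3.2)) < 1e-9))
})

test_that("phantom rendering is deterministic and seed-reproducible", {
  geom <- phantom_geometry()
  a <- build_phantom_pair(geom, spacing = 0.7, noise_sd = 0)
  b <- build_phantom_pair(geom, spacing = 0.7, noise_sd = 0)
  expect_identical(a$ct$data, b$ct$data)
  expect_identical(a$mr$data, b$mr$data)

  n1 <- build_phantom_pair(geom, spacing = 0.7, noise_sd = 0.05, seed = 42)
  n2 <- build_phantom_pair(geom, spacing = 0.7, noise_sd = 0.05, seed = 42)
  n3 <- build_phantom_pair(geom, spacing = 0.7, noise_sd = 0.05, seed = 43)
  expect_identical(n1$mr$data, n2$mr$data)
  expect_false(identical(n1$mr$data, n3$mr$data))
})

test_that("CT and MR contrasts are complementary on the same geometry", {
  ph <- coarse_phantom()
  expect_identical(ph$ct$spacing, ph$mr$spacing)
  expect_identical(ph$ct$origin, ph$mr$origin)
  inner <- voi_voxel_mask(voi(c(0, 0, 0), c(8, 8, 8)), ph$ct)
  # walls bright in CT <-> dark in MR
  expect_lt(cor(as.numeric(ph$ct$data[inner]),
                as.numeric(ph$mr$data[inner])), -0.9)
})

test_that("shim fields evaluate the polynomial basis on normalized coords", {
  geom <- image_volume(array(0, c(9, 9, 9)), rep(1, 3))
  zero <- make_shim_field(shim_config(c(z2 = 0, x = 0)), geom)
  expect_true(all(zero$offsets == 0))

  # z2 term: 0 at isocenter, A at the normalized edge, A/4 halfway
  cfg <- shim_config(c(z2 = 400), half_fov = c(4, 4, 4))
  expect_equal(shim_offsets(cfg, cbind(0, 0, 0)), 0)
  expect_equal(shim_offsets(cfg, cbind(0, 0, 4)), 400)
  expect_equal(shim_offsets(cfg, cbind(0, 0, 2)), 100)

  expect_error(shim_config(c(w2 = 1)), "unknown shim basis")
})

test_that("GNL fields are zero at isocenter and odd-polynomial in p-hat", {
  geom <- image_volume(array(0, c(9, 9, 9)), rep(1, 3))
  zf <- make_gnl_field(gnl_config(), geom)
  expect_true(all(zf$vectors == 0))

  cfg <- gnl_config(a3 = 0.5, half_fov = c(4, 4, 4))
  expect_equal(gnl_displacement(cfg, cbind(0, 0, 0))[1, ],
               c(x = 0, y = 0, z = 0))
  expect_equal(gnl_displacement(cfg, cbind(4, 0, 0))[1, "x"], c(x = 0.5))
  expect_equal(gnl_displacement(cfg, cbind(2, 0, 0))[1, "x"], c(x = 0.0625))

  # monotone magnitude along axis-aligned profiles
  f <- make_gnl_field(cfg, geom)
  prof <- abs(f$vectors[, 5, 5, 1])
  half <- (length(prof) + 1) / 2
  expect_true(all(diff(prof[half:length(prof)]) >= -1e-12))
  expect_true(all(diff(prof[1:half]) <= 1e-12))
})

test_that("distort_volume with zero fields is the identity", {
  ph <- coarse_phantom()
  out <- distort_volume(ph$mr, field = shim_config(c(constant = 0)),
                        grad = gradient_spec(),
                        gnl = gnl_config())
  expect_identical(out$data, ph$mr$data)
})

test_that("a uniform off-resonance shifts the image rigidly along readout", {
  # 477.7 Hz at Gz = 56.1 mT/m is 0.2 mm: exactly one voxel on a 0.2 mm
  # grid, so the warp is an integer shift with values preserved
  vol <- smooth_volume_fixture(n = 14, spacing = 0.2)
  grad <- gradient_spec(Gz = 56.1)
  out <- distort_volume(vol, field = shim_config(c(constant = 477.7)),
                        grad = grad)
  shift_vox <- hz_to_mm(477.7, grad) / 0.2
  expect_equal(shift_vox, 1, tolerance = 1e-3)
  # out(p) = in(p - dr): interior slice k holds input slice k - 1
  expect_equal(out$data[, , 5], vol$data[, , 4], tolerance = 1e-5)
  # x and y untouched
  expect_equal(out$data[3, 7, 5], vol$data[3, 7, 4], tolerance = 1e-5)
})

test_that("distort_volume errors on a readout-axis mismatch", {
  vol <- image_volume(array(runif(8^3), c(8, 8, 8)), rep(0.5, 3),
                      encoding = c(x = "frequency", y = "phase",
                                   z = "slice"))
  expect_error(distort_volume(vol, field = shim_config(c(z = 10)),
                              grad = gradient_spec(readout_axis = "z")),
               "readout axis")
})

test_that("distort_landmarks matches the analytic displacement model", {
  ph <- coarse_phantom()
  grad <- gradient_spec()
  lms <- ph$landmarks

  same <- distort_landmarks(lms)
  expect_equal(as.data.frame(same)[, c("x", "y", "z")],
               as.data.frame(lms)[, c("x", "y", "z")])

  # uniform field: every landmark shifts by the same z amount
  u <- distort_landmarks(lms, field = shim_config(c(constant = 238.85)),
                         grad = grad)
  dz <- u$z - lms$z
  expect_equal(dz, rep(hz_to_mm(238.85, grad), nrow(lms)), tolerance = 1e-9)
  expect_equal(u$x, lms$x)

  # mixed field: shift equals B0 term (readout only) + GNL term, computed
  # here independently term by term
  shim <- shim_config(c(z2 = 300, x = 50))
  gnl <- gnl_config(a3 = c(0.3, 0.2, 0.4))
  m <- distort_landmarks(lms, field = shim, grad = grad, gnl = gnl)
  pts <- landmark_points(lms)
  expect_b0 <- hz_to_mm(shim_offsets(shim, pts), grad)
  expect_gnl <- gnl_displacement(gnl, pts)
  expect_equal(m$x - lms$x, unname(expect_gnl[, 1]), tolerance = 1e-12)
  expect_equal(m$y - lms$y, unname(expect_gnl[, 2]), tolerance = 1e-12)
  expect_equal(m$z - lms$z, unname(expect_b0 + expect_gnl[, 3]),
               tolerance = 1e-12)
})

test_that("displacement model is additive when evaluated at the undistorted
           position", {
  ph <- coarse_phantom()
  grad <- gradient_spec()
  lms <- ph$landmarks
  shim <- shim_config(c(z2 = 250, yz = 40))
  gnl <- gnl_config(a3 = 0.4)
  both <- distort_landmarks(lms, field = shim, grad = grad, gnl = gnl)
  only_b0 <- distort_landmarks(lms, field = shim, grad = grad)
  only_gnl <- distort_landmarks(lms, gnl = gnl)
  expect_equal(both$z - lms$z,
               (only_b0$z - lms$z) + (only_gnl$z - lms$z), tolerance = 1e-12)
  expect_equal(both$x - lms$x, only_gnl$x - lms$x, tolerance = 1e-12)
})

test_that("landmarks outside a discrete field domain are flagged and
           excluded", {
  small <- image_volume(array(0, c(11, 11, 11)), rep(0.5, 3))
  fm <- make_shim_field(shim_config(c(z = 100)), small)
  lms <- landmark_set(data.frame(id = c("in", "out"),
                                 x = c(0, 40), y = c(0, 40), z = c(0, 40)))
  expect_warning(out <- distort_landmarks(lms, field = fm,
                                          grad = gradient_spec()),
                 "outside")
  expect_equal(nrow(out), 1L)
  expect_identical(out$id, "in")
})

test_that("GNL distortion moves image landmarks by the analytic field", {
  geom <- phantom_geometry()
  ph <- mid_phantom()
  gnl <- gnl_config(a3 = 0.5)
  dist <- distort_volume(ph$ct, gnl = gnl)
  truth <- distort_landmarks(ph$landmarks, gnl = gnl)
  det <- detect_grid_landmarks(dist, geom)
  dd <- suppressWarnings(landmark_displacements(truth, det))
  # localization within a quarter voxel of the analytic prediction
  expect_lt(median(dd$euclidean), 0.25 * 0.4)
})

test_that("map-based shimming beats first-order shimming for every seed", {
  geom <- image_volume(array(0, c(24, 24, 32)), rep(1, 3))
  vmask <- voi_voxel_mask(voi(c(0, 0, 2), c(16, 16, 25)), geom)
  for (seed in 1:20) {
    # shimming optimizes over the target volume, so fit within the VOI
    sc <- simulate_shim_scenarios(geom, seed = seed, mask = vmask)
    m1 <- max(abs(sc$shim1$offsets[vmask]))
    m2 <- max(abs(sc$shim2$offsets[vmask]))
    expect_lt(m2, m1)
  }
})

test_that("optional signal-loss attenuation dims steep-field regions only", {
  vol <- image_volume(array(1, c(12, 12, 12)), rep(0.5, 3))
  grad <- gradient_spec()
  # uniform field: no spatial gradient, no attenuation anywhere
  u <- distort_volume(vol, field = shim_config(c(constant = 100)),
                      grad = grad, signal_loss = 5)
  expect_equal(max(abs(u$data[3:10, 3:10, 3:10] - 1)), 0, tolerance = 1e-9)
  # steep linear field: interior intensity drops when the effect is on
  steep <- shim_config(c(z = 2000), half_fov = c(3, 3, 3))
  off <- distort_volume(vol, field = steep, grad = grad)
  on <- distort_volume(vol, field = steep, grad = grad, signal_loss = 5)
  expect_lt(mean(on$data[4:9, 4:9, 4:9]), mean(off$data[4:9, 4:9, 4:9]))
})
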