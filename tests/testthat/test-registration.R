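test_that("rigid transforms compose, invert and convert angles correctly", {
  tf <- rigid_transform(c(10, -5, 20), c(1, 2, -3), center = c(1, 1, 1))
  ti <- invert_rigid(tf)
  pts <- matrix(rnorm(30), 10, 3)
  back <- transform_points(ti, transform_points(tf, pts))
  expect_equal(back, pts, tolerance = 1e-12)
  comp <- compose_rigid(ti, tf)
  expect_equal(transform_points(comp, pts), pts, tolerance = 1e-12)
  R <- rotation_matrix(c(10, -5, 20))
  expect_equal(det(R), 1, tolerance = 1e-12)
  expect_equal(t(R) %*% R, diag(3), tolerance = 1e-12)
})

test_that("self-registration returns the identity pose", {
  ph <- coarse_phantom()
  tf <- rigid_register(ph$ct, ph$ct, levels = 2)
  expect_lt(max(abs(tf$translation)), 0.02)
  expect_lt(max(abs(tf$angles)), 0.05)
})

test_that("known rigid transforms are recovered on the phantom", {
  ph <- mid_phantom()
  tf0 <- rigid_transform(translation = c(0.4, -0.6, 0.3))
  moving <- apply_rigid(ph$ct, tf0)
  tf <- rigid_register(moving, ph$ct)
  # the fitted transform is the inverse of the applied one
  expect_lt(max(abs(tf$translation + c(0.4, -0.6, 0.3))), 0.1)
  expect_lt(max(abs(tf$angles)), 0.2)

  tfr <- rigid_transform(angles = c(0, 0, 2))
  tr <- rigid_register(apply_rigid(ph$ct, tfr), ph$ct)
  expect_lt(abs(tr$angles[3] + 2), 0.2)
  expect_lt(max(abs(tr$translation)), 0.1)
})

test_that("registration rejects non-overlapping volumes", {
  a <- image_volume(array(runif(8^3), c(8, 8, 8)), rep(1, 3),
                    origin = c(0, 0, 0))
  b <- image_volume(array(runif(8^3), c(8, 8, 8)), rep(1, 3),
                    origin = c(100, 100, 100))
  expect_error(rigid_register(a, b), "overlap")
})

test_that("field resampling preserves mm vectors and is exact at identity", {
  g <- image_volume(array(0, c(20, 20, 20)), rep(0.4, 3))
  const <- displacement_field(array(rep(c(0.1, -0.2, 0.3),
                                        each = 20^3), c(20, 20, 20, 3)),
                              rep(0.4, 3), g$origin)
  up <- resample_field(const, 0.25)
  expect_equal(range(up$vectors[, , , 1]), c(0.1, 0.1), tolerance = 1e-12)
  expect_equal(range(up$vectors[, , , 3]), c(0.3, 0.3), tolerance = 1e-12)

  expect_identical(resample_field(const, c(0.4, 0.4, 0.4))$vectors,
                   const$vectors)

  # smooth field round trip against the analytic generator
  cfg <- gnl_config(a3 = 0.5, half_fov = c(4, 4, 4))
  f <- make_gnl_field(cfg, g)
  rt <- resample_field(resample_field(f, 0.14), geometry = g)
  inner <- 3:18  # interior: no extrapolation edge effects
  expect_lt(max(abs(rt$vectors[inner, inner, inner, ] -
                    f$vectors[inner, inner, inner, ])), 0.01)
})

test_that("apply_field is exact for zero and integer-voxel uniform fields", {
  vol <- smooth_volume_fixture(n = 12, spacing = 0.2)
  zf <- zero_field(vol)
  expect_identical(apply_field(vol, zf)$data, vol$data)

  uf <- zero_field(vol)
  uf$vectors[, , , 1] <- 0.2
  out <- apply_field(vol, uf)
  expect_equal(out$data[5, , ], vol$data[6, , ], tolerance = 1e-9)

  small <- zero_field(image_volume(array(0, c(5, 5, 5)), rep(0.2, 3)))
  expect_error(apply_field(vol, small), "geometry")
})

test_that("warping by a field and back recovers the landmarks", {
  geom <- phantom_geometry()
  ph <- mid_phantom()
  cfg <- gnl_config(a3 = 0.4)
  f <- make_gnl_field(cfg, ph$ct)
  dist <- distort_volume(ph$ct, gnl = cfg)
  rest <- apply_field(dist, f)
  det <- detect_grid_landmarks(rest, geom)
  dd <- suppressWarnings(landmark_displacements(ph$landmarks, det))
  expect_lt(median(dd$euclidean), 0.25 * 0.4)
})

test_that("FFD self-registration stays at (near) zero deformation", {
  ph <- coarse_phantom()
  res <- ffd_register(ph$ct, ph$ct, ffd_model(max_iterations = 60))
  mag <- sqrt(res$field$vectors[, , , 1]^2 + res$field$vectors[, , , 2]^2 +
              res$field$vectors[, , , 3]^2)
  expect_lt(max(mag), 0.1 * 0.5)
  expect_error(ffd_register(ph$ct,
                            image_volume(array(1, dim(ph$ct$data)),
                                         ph$ct$spacing, ph$ct$origin)),
               "degenerate")
})

test_that("FFD recovers a known smooth warp on the phantom", {
  geom <- phantom_geometry()
  ph <- coarse_phantom()
  gnl <- gnl_config(a3 = 0.5)
  dist <- distort_volume(ph$mr, gnl = gnl)
  msk <- gridwarp:::registration_mask(ph$ct, 0.8)
  res <- ffd_register(harmonize_contrast(dist), ph$ct,
                      ffd_model(max_iterations = 250), mask = msk)
  pts <- landmark_points(ph$landmarks)
  err <- sqrt(rowSums((sample_field(res$field, pts) -
                       gnl_displacement(gnl, pts))^2))
  expect_lt(median(err), 0.1)
  # recovered field no rougher than the truth (regularizer sanity)
  truth <- make_gnl_field(gnl, ph$ct)
  expect_lt(bending_energy(res$field),
            bending_energy(truth) + 1e-4)
})

test_that("increasing the bending weight shrinks the deformation", {
  ph <- coarse_phantom()
  gnl <- gnl_config(a3 = 0.5)
  dist <- distort_volume(ph$mr, gnl = gnl)
  h <- harmonize_contrast(dist)
  mags <- vapply(c(0.01, 50), function(w) {
    res <- ffd_register(h, ph$ct,
                        ffd_model(bending_weight = w, max_iterations = 80))
    max(sqrt(res$field$vectors[, , , 1]^2 + res$field$vectors[, , , 2]^2 +
             res$field$vectors[, , , 3]^2))
  }, numeric(1))
  expect_lt(mags[2], mags[1])
})
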