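test_that("NIfTI round trip preserves data, spacing, origin and roles", {
  vol <- image_volume(array(runif(1000), c(10, 10, 10)),
                      spacing = c(0.2, 0.2, 0.2), origin = c(-1, -1, -1))
  path <- tempfile(fileext = ".nii.gz")
  on.exit(unlink(c(path, sidecar_path <- sub("\\.nii\\.gz$", ".json", path))))
  write_volume(vol, path)
  back <- read_volume(path)
  expect_equal(back$data, vol$data, tolerance = 1e-6)
  expect_equal(back$spacing, vol$spacing, tolerance = 1e-6)
  expect_equal(back$origin, vol$origin, tolerance = 1e-6)
  expect_identical(back$encoding, vol$encoding)
})

test_that("read_volume rejects non-3D payloads and missing role metadata", {
  arr4 <- array(0, c(4, 4, 4, 2))
  p4 <- tempfile(fileext = ".nii.gz")
  on.exit(unlink(p4))
  RNifti::writeNifti(RNifti::asNifti(arr4), p4)
  expect_error(read_volume(p4, encoding = c(x = "phase", y = "slice",
                                            z = "frequency")),
               "not a 3D")
  # 3D payload but no sidecar and no explicit roles: must not guess
  p3 <- tempfile(fileext = ".nii.gz")
  on.exit(unlink(p3), add = TRUE)
  RNifti::writeNifti(RNifti::asNifti(array(0, c(4, 4, 4))), p3)
  expect_error(read_volume(p3), "encoding-role")
})

test_that("image_volume validates geometry and encoding invariants", {
  expect_error(image_volume(array(0, c(4, 4)), c(1, 1, 1)), "3D")
  expect_error(image_volume(array(0, c(4, 4, 4)), c(1, -1, 1)), "positive")
  expect_error(image_volume(array(0, c(4, 4, 4)), c(1, 1, 1),
                            encoding = c(x = "phase", y = "phase",
                                         z = "phase")),
               "frequency")
  expect_error(image_volume(array(0, c(4, 4, 4)), c(1, 1, 1),
                            encoding = c(x = "frequency", y = "frequency",
                                         z = "slice")),
               "frequency")
})

test_that("resampling preserves constants, is exact at identity spacing, and
           round-trips smooth content", {
  const <- image_volume(array(7.5, c(12, 12, 12)), rep(0.2, 3))
  out <- resample_volume(const, c(0.3, 0.25, 0.14))
  expect_true(all(out$data == 7.5))

  vol <- smooth_volume_fixture()
  expect_identical(resample_volume(vol, vol$spacing)$data, vol$data)

  # quadratic content: analytic oracle at the final voxel centers
  g <- image_volume(array(0, c(21, 21, 21)), rep(0.2, 3))
  pts <- voxel_centers(g)
  quad <- function(p) 2 + p[, 1]^2 - 0.5 * p[, 2]^2 + p[, 3]^2 / 3
  vol <- image_volume(array(quad(pts), c(21, 21, 21)), rep(0.2, 3),
                      origin = g$origin)
  rt <- resample_volume(resample_volume(vol, 0.14), 0.2)
  pts_rt <- voxel_centers(rt)
  expected <- quad(pts_rt)
  dr <- diff(range(vol$data))
  expect_lt(max(abs(rt$data - expected)), 0.01 * dr)
})

test_that("VOI voxel masks follow the half-open voxel-center convention", {
  geom <- image_volume(array(0, c(11, 11, 11)), rep(0.2, 3))
  # voxel centers at -1.0, -0.8, ..., 1.0; VOI 0.4 mm wide centered on the
  # center voxel -> exactly 2 centers per axis inside [c - 0.2, c + 0.2)
  v <- voi(c(0, 0, 0), c(0.4, 0.4, 0.4))
  expect_equal(sum(voi_voxel_mask(v, geom)), 8)

  expect_warning(m <- voi_voxel_mask(voi(c(50, 50, 50), c(1, 1, 1)), geom),
                 "intersect")
  expect_false(any(m))

  full <- voi(c(0, 0, 0), c(2.4, 2.4, 2.4))
  expect_true(all(voi_voxel_mask(full, geom)))
})

test_that("VOI difference masks subtract exactly and partition", {
  geom <- image_volume(array(0, c(12, 12, 12)), rep(0.2, 3))
  outer <- voi(c(0.1, 0.1, 0.1), c(0.8, 0.8, 0.8))   # 4^3 = 64 voxels
  inner <- voi(c(0.1, 0.1, 0.1), c(0.4, 0.4, 0.4))   # 2^3 = 8 voxels
  expect_equal(sum(voi_voxel_mask(outer, geom)), 64)
  expect_equal(sum(voi_difference_mask(outer, inner, geom)), 56)

  expect_false(any(voi_difference_mask(outer, outer, geom)))

  disjoint <- voi(c(-0.9, -0.9, -0.9), c(0.2, 0.2, 0.2))
  expect_equal(voi_difference_mask(outer, disjoint, geom),
               voi_voxel_mask(outer, geom))

  # union property: difference + inner == outer when inner inside outer
  expect_equal(voi_difference_mask(outer, inner, geom) |
                 voi_voxel_mask(inner, geom),
               voi_voxel_mask(outer, geom))
})

test_that("crop_volume keeps the requested physical box", {
  vol <- smooth_volume_fixture()
  cr <- crop_volume(vol, c(0, 0, 0), c(1, 1, 1))
  expect_true(all(abs(voxel_centers(cr, 1)) <= 0.5 + 1e-9))
  # values are untouched, just subset
  expect_true(all(cr$data %in% vol$data))
  expect_error(crop_volume(vol, c(100, 0, 0), c(0.5, 0.5, 0.5)),
               "intersect")
})

test_that("sample_volume interpolates linearly in physical space", {
  vol <- smooth_volume_fixture()
  pts <- voxel_centers(vol)[c(100, 500, 1000), ]
  expect_equal(sample_volume(vol, pts),
               as.numeric(vol$data)[c(100, 500, 1000)])
  # linear function is reproduced exactly between centers
  lin <- image_volume(array(voxel_centers(vol)[, 1], dim(vol$data)),
                      vol$spacing, vol$origin)
  probe <- cbind(c(0.11, -0.23), c(0.05, 0.0), c(0.0, 0.1))
  expect_equal(sample_volume(lin, probe), probe[, 1], tolerance = 1e-12)
})
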