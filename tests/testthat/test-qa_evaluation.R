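test_that("landmark displacement tables match hand-computed offsets", {
  a <- landmark_set(data.frame(id = "p", x = 0, y = 0, z = 0))
  b <- landmark_set(data.frame(id = "p", x = 0.1, y = 0.2, z = 0.2))
  d <- landmark_displacements(a, b)
  expect_equal(d$euclidean, 0.3, tolerance = 1e-12)
  expect_equal(c(d$dx, d$dy, d$dz), c(0.1, 0.2, 0.2))

  same <- landmark_displacements(b, b)
  expect_true(all(same[, c("dx", "dy", "dz", "euclidean")] == 0))

  # per-axis antisymmetry under argument swap
  rev <- landmark_displacements(b, a)
  expect_equal(rev$dx, -d$dx)
  expect_equal(rev$dz, -d$dz)
  expect_equal(rev$euclidean, d$euclidean)
})

test_that("landmark pairing is by id with warnings for unmatched points", {
  a <- landmark_set(data.frame(id = c("p", "q"), x = 0:1, y = 0:1, z = 0:1))
  b <- landmark_set(data.frame(id = c("q", "r"), x = 1:2, y = 1:2, z = 1:2))
  expect_warning(d <- landmark_displacements(a, b), "unmatched")
  expect_identical(d$id, "q")
  c_set <- landmark_set(data.frame(id = "zz", x = 0, y = 0, z = 0))
  expect_error(suppressWarnings(landmark_displacements(a, c_set)),
               "no matching")
})

test_that("threshold fractions come out as hand counts", {
  s <- summarize_displacements(c(0.1, 0.15, 0.25, 0.3), threshold = 0.2)
  expect_equal(s$fraction_below_threshold, 0.5)
})

test_that("grid landmark detection is sub-voxel accurate on both contrasts", {
  geom <- phantom_geometry()
  ph <- mid_phantom()
  for (img in list(ph$ct, ph$mr)) {
    det <- detect_grid_landmarks(img, geom)
    expect_gte(nrow(det), 8)
    dd <- suppressWarnings(landmark_displacements(ph$landmarks, det))
    expect_lt(median(dd$euclidean), 0.1)
    expect_lt(max(dd$euclidean), 0.25)
  }
  flat <- image_volume(array(1, c(30, 30, 30)), rep(0.4, 3))
  expect_error(detect_grid_landmarks(flat, geom), "constant")
})

test_that("multi-level Otsu separates discrete modes exactly", {
  mk <- function(vals) image_volume(array(vals, c(4, 5, 5)), rep(1, 3))
  v2 <- mk(rep(c(0, 10), each = 50))
  s2 <- otsu_segment(v2, 2, "brightest")
  expect_gt(s2$provenance$thresholds, 0)
  expect_lt(s2$provenance$thresholds, 10)
  expect_equal(sum(s2$mask), 50)
  expect_true(all(v2$data[s2$mask] == 10))

  # three delta modes: the middle class is exactly the mid-valued voxels
  v3 <- mk(rep(c(0, 5, 10), length.out = 100))
  s3 <- otsu_segment(v3, 3, "middle")
  expect_identical(array(v3$data == 5, dim(v3$data)), s3$mask)
  expect_length(s3$provenance$thresholds, 2L)

  expect_error(otsu_segment(mk(rep(1, 100))), "constant")
})

test_that("Otsu wall/gap split matches the analytic gap fraction", {
  ph <- coarse_phantom()
  ext <- c(18, 18, 28)
  inner <- voi_voxel_mask(voi(c(0, 0, 0), ext), ph$mr)
  s <- otsu_segment(ph$mr, 3, "brightest")
  mid <- otsu_segment(ph$mr, 3, "middle")
  # partial-volume voxels (middle class) straddle the wall faces; half of
  # their volume belongs to the gap side
  est <- (sum(s$mask & inner) + 0.5 * sum(mid$mask & inner)) / sum(inner)
  # analytic: gaps are the complement of the wall planes that fall inside
  # the evaluated box (0.7 mm per plane, planes every 3.2 mm about 0)
  nplanes <- function(L) sum(abs(seq(-3, 3) * 3.2) <= L / 2)
  fx <- nplanes(ext[1]) * 0.7 / ext[1]
  fy <- nplanes(ext[2]) * 0.7 / ext[2]
  fz <- sum(abs(seq(-5, 5) * 3.2) <= ext[3] / 2) * 0.7 / ext[3]
  gap_frac <- (1 - fx) * (1 - fy) * (1 - fz)
  expect_lt(abs(est - gap_frac) / gap_frac, 0.10)
})

test_that("morphological cleanup follows ball-element truth tables", {
  m <- array(FALSE, c(7, 7, 7))
  m[3:5, 3:5, 3:5] <- TRUE
  m[4, 4, 4] <- FALSE  # 1-voxel hole
  msk <- structure(list(mask = m, spacing = c(1, 1, 1),
                        origin = c(0, 0, 0),
                        provenance = list(method = "manual")),
                   class = "segmentation_mask")
  expect_identical(morph_cleanup(msk, 0, 0)$mask, m)
  closed <- morph_cleanup(msk, 1, 0)$mask
  expect_true(closed[4, 4, 4])

  # dilation of a single voxel by a radius-1 ball: center + 6 neighbors
  single <- array(FALSE, c(5, 5, 5))
  single[3, 3, 3] <- TRUE
  dil <- morph_cleanup(single, 0, 1)
  expect_equal(sum(dil), 7)
  expect_true(dil[2, 3, 3] && dil[3, 4, 3] && dil[3, 3, 2])
  expect_error(morph_cleanup(single, -1, 0), ">= 0")
})

test_that("Dice coefficient: exact counts, symmetry, bounds", {
  d <- c(4, 4, 4)
  a <- array(FALSE, d); a[1:4, 1, 1] <- TRUE
  b <- array(FALSE, d); b[3:6 - 2, 2, 1] <- TRUE  # 4 voxels, overlap 0
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, b), 0)
  b2 <- array(FALSE, d); b2[3:4, 1, 1] <- TRUE; b2[1:2, 2, 1] <- TRUE
  expect_equal(dice(a, b2), 0.5)  # |X|=4, |Y|=4, overlap 2
  expect_equal(dice(b2, a), dice(a, b2))
  expect_error(dice(array(FALSE, d), array(FALSE, d)), "empty")
  expect_error(dice(a, array(TRUE, c(2, 2, 2))), "dimensions")
})

test_that("qa_report writes machine-readable JSON and prints a table", {
  st <- cbind(stage = "demo",
              summarize_displacements(c(0.05, 0.1, 0.3), 0.2))
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  rep <- qa_report(st, dice_values = c(rigid = 0.8, corrected = 0.95),
                   threshold = 0.2, file = f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$threshold_mm, 0.2)
  expect_equal(back$dice$corrected, 0.95)
  expect_equal(back$stats$median, st$median)
  out <- capture.output(print(rep))
  expect_true(any(grepl("corrected", out)))
  expect_true(any(grepl("\\|", out)))
})

test_that("landmark CSV round trip preserves ids and mm coordinates", {
  lms <- landmark_set(data.frame(id = c("a", "b"), x = c(0.1, -1),
                                 y = c(2, 0), z = c(-3, 0.5)))
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  write_landmarks(lms, f)
  back <- read_landmarks(f, source = "truth")
  expect_equal(back$id, lms$id)
  expect_equal(back$x, lms$x)
  expect_equal(back$y, lms$y)
  expect_equal(back$z, lms$z)
})
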