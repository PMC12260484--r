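# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]]))
    .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# coarse phantom pair (0.5 mm): fast, still resolves the 0.7 mm walls
coarse_phantom <- function() {
  fixture("coarse_phantom",
          function() build_phantom_pair(phantom_geometry(), spacing = 0.5))
}

# mid-resolution pair (0.4 mm) for registration tests
mid_phantom <- function() {
  fixture("mid_phantom",
          function() build_phantom_pair(phantom_geometry(), spacing = 0.4))
}

# full-resolution pair (0.2 mm) for the acceptance round trips
fine_phantom <- function() {
  fixture("fine_phantom",
          function() build_phantom_pair(phantom_geometry(), spacing = 0.2))
}

landmark_points <- function(lms) as.matrix(lms[, c("x", "y", "z")])

# tiny volume with arbitrary smooth content
smooth_volume_fixture <- function(n = 16, spacing = 0.2) {
  g <- image_volume(array(0, c(n, n, n)), rep(spacing, 3))
  pts <- voxel_centers(g)
  vals <- 1 + 0.3 * pts[, 1] + 0.2 * pts[, 2] - 0.1 * pts[, 3] +
    0.05 * pts[, 1] * pts[, 3]
  image_volume(array(vals, c(n, n, n)), rep(spacing, 3))
}
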