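#' Digital grid phantom geometry
#'
#' Parameters of the cubic lattice phantom the package emulates: a block of
#' thin orthogonal walls separated by fluid-fillable gaps. The default
#' mirrors a 3D-printed QA phantom: 22 x 22 x 35.6 mm outer extent, 0.7 mm
#' walls and 2.5 mm gaps, i.e. a lattice period (pitch) of 3.2 mm. An
#' optional asymmetric wedge near the center aids orientation checks.
#'
#' @param outer_extent mm triple, overall grid size.
#' @param wall_thickness wall thickness, mm.
#' @param gap gap between walls, mm.
#' @param marker logical: include the central asymmetric wedge.
#' @return An object of class `phantom_geometry`.
#' @export
phantom_geometry <- function(outer_extent = c(22, 22, 35.6),
                             wall_thickness = 0.7, gap = 2.5,
                             marker = TRUE) {
  outer_extent <- rep_len(as.numeric(outer_extent), 3L)
  if (wall_thickness <= 0 || gap <= 0)
    stop("wall thickness and gap must be positive", call. = FALSE)
  pitch <- wall_thickness + gap
  if (any(outer_extent < 2 * pitch))
    stop("extents must accommodate at least 2 lattice cells per axis",
         call. = FALSE)
  structure(list(outer_extent = outer_extent,
                 wall_thickness = wall_thickness, gap = gap,
                 pitch = pitch, marker = isTRUE(marker)),
            class = "phantom_geometry")
}

#' @export
print.phantom_geometry <- function(x, ...) {
  cat("<phantom_geometry> ", paste(x$outer_extent, collapse = " x "),
      " mm, wall ", x$wall_thickness, " mm, gap ", x$gap,
      " mm (pitch ", x$pitch, " mm)\n", sep = "")
  invisible(x)
}

# Lattice wall-plane positions along one axis, symmetric about 0.
lattice_planes <- function(geom, axis) {
  k <- floor((geom$outer_extent[axis] / 2) / geom$pitch)
  seq(-k, k) * geom$pitch
}

# Soft (one-voxel antialiased) indicator of being within `half` of any plane.
soft_plane_indicator <- function(coords, planes, half, spacing) {
  d <- abs(outer(coords, planes, "-"))
  dmin <- apply(d, 1, min)
  pmin(1, pmax(0, (half + spacing / 2 - dmin) / spacing))
}

soft_box_indicator <- function(coords, half, spacing) {
  pmin(1, pmax(0, (half + spacing / 2 - abs(coords)) / spacing))
}

# Evaluate seeded code without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Build a matched CT-like / MR-like phantom image pair with truth landmarks
#'
#' Renders the grid phantom on a voxel grid centered on the isocenter. The
#' CT-like image is bright on the plastic walls (the phantom is scanned
#' empty, so gaps are air); the MR-like image is bright in the
#' solution-filled gaps and dark on the walls. Both share identical physical
#' geometry, and wall edges are antialiased over one voxel so that lattice
#' intersections can be localized with sub-voxel precision. Truth landmarks
#' are the analytic lattice-intersection coordinates; neighboring landmarks
#' are one pitch (`gap + wall`) apart.
#'
#' @param geom a [phantom_geometry()].
#' @param spacing isotropic voxel size in mm (must resolve the wall:
#'   `spacing <= wall_thickness`).
#' @param noise_sd Gaussian intensity noise SD added to both images
#'   (intensities are 0..1); 0 = noise-free.
#' @param seed integer seed driving the noise; same seed, same images.
#' @param margin mm of empty background added around the grid.
#' @param encoding encoding roles of both volumes (z frequency by default).
#' @return List with elements `ct`, `mr` (both [image_volume()]) and
#'   `landmarks` (a [landmark_set()] with ids `L<i>_<j>_<k>` indexed by
#'   signed lattice position).
#' @examples
#' ph <- build_phantom_pair(phantom_geometry(), spacing = 0.4)
#' nrow(ph$landmarks)
#' @export
build_phantom_pair <- function(geom = phantom_geometry(), spacing = 0.2,
                               noise_sd = 0, seed = NULL, margin = 2,
                               encoding = c(x = "phase", y = "slice",
                                            z = "frequency")) {
  if (spacing > geom$wall_thickness)
    stop("spacing (", spacing, " mm) too coarse to resolve the ",
         geom$wall_thickness, " mm wall", call. = FALSE)
  fov <- geom$outer_extent + 2 * margin
  n <- as.integer(floor(fov / spacing)) + 1L
  origin <- -(n - 1) / 2 * spacing
  cx <- origin[1] + (seq_len(n[1]) - 1) * spacing
  cy <- origin[2] + (seq_len(n[2]) - 1) * spacing
  cz <- origin[3] + (seq_len(n[3]) - 1) * spacing

  half_w <- geom$wall_thickness / 2
  wx <- soft_plane_indicator(cx, lattice_planes(geom, 1), half_w, spacing)
  wy <- soft_plane_indicator(cy, lattice_planes(geom, 2), half_w, spacing)
  wz <- soft_plane_indicator(cz, lattice_planes(geom, 3), half_w, spacing)
  bx <- soft_box_indicator(cx, geom$outer_extent[1] / 2, spacing)
  by <- soft_box_indicator(cy, geom$outer_extent[2] / 2, spacing)
  bz <- soft_box_indicator(cz, geom$outer_extent[3] / 2, spacing)

  # union of the three wall-plane families
  ax <- array(wx, n)
  ay <- array(rep(wy, each = n[1]), n)
  az <- array(rep(wz, each = n[1] * n[2]), n)
  wall <- 1 - (1 - ax) * (1 - ay) * (1 - az)
  inside <- array(bx, n) * array(rep(by, each = n[1]), n) *
    array(rep(bz, each = n[1] * n[2]), n)

  if (geom$marker) {
    # asymmetric solid wedge filling half of the first-octant central cell
    lo <- half_w
    hi <- geom$pitch - half_w
    inx <- cx > lo & cx < hi
    iny <- cy > lo & cy < hi
    inz <- cz > lo & cz < hi
    if (any(inx) && any(iny) && any(inz)) {
      sub <- outer(cx[inx], cy[iny],
                   function(a, b) (a - lo) + (b - lo) < 0.8 * geom$gap)
      wedge <- array(0, n)
      wedge[inx, iny, inz] <- array(rep(sub, sum(inz)),
                                    c(sum(inx), sum(iny), sum(inz)))
      wall <- pmax(wall, wedge)
    }
  }

  ct_data <- wall * inside
  mr_data <- (1 - wall) * inside
  if (noise_sd > 0) {
    with_seed(seed, {
      ct_data <- ct_data + array(rnorm(prod(n), 0, noise_sd), n)
      mr_data <- mr_data + array(rnorm(prod(n), 0, noise_sd), n)
    })
  }

  px <- lattice_planes(geom, 1)
  py <- lattice_planes(geom, 2)
  pz <- lattice_planes(geom, 3)
  ik <- expand.grid(i = seq_along(px) - (length(px) + 1) %/% 2,
                    j = seq_along(py) - (length(py) + 1) %/% 2,
                    k = seq_along(pz) - (length(pz) + 1) %/% 2)
  lms <- data.frame(id = sprintf("L%d_%d_%d", ik$i, ik$j, ik$k),
                    x = rep(px, times = length(py) * length(pz)),
                    y = rep(rep(py, each = length(px)), times = length(pz)),
                    z = rep(pz, each = length(px) * length(py)),
                    stringsAsFactors = FALSE)

  list(ct = image_volume(ct_data, rep(spacing, 3), origin, encoding),
       mr = image_volume(mr_data, rep(spacing, 3), origin, encoding),
       landmarks = landmark_set(lms, frame = "scanner", source = "truth"))
}
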