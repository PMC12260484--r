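#' Volume of interest (VOI)
#'
#' An axis-aligned box in the scanner frame, defined by its center and
#' per-axis extents in mm. The nested boxes used in the shimming analysis
#' (e.g. 10x10x6.5, 16x16x13 and 16x16x25 mm, centered 2 mm above the
#' isocenter) are constructed with this.
#'
#' @param center mm triple.
#' @param extents positive mm triple (or scalar, recycled).
#' @return An object of class `voi`.
#' @export
voi <- function(center, extents) {
  center <- as.numeric(center)
  extents <- rep_len(as.numeric(extents), 3L)
  if (length(center) != 3L || any(!is.finite(center)))
    stop("`center` must be 3 finite mm values", call. = FALSE)
  if (any(!is.finite(extents)) || any(extents <= 0))
    stop("`extents` must be positive", call. = FALSE)
  structure(list(center = center, extents = extents), class = "voi")
}

#' @export
print.voi <- function(x, ...) {
  cat("<voi> ", paste(x$extents, collapse = " x "), " mm at (",
      paste(x$center, collapse = ", "), ") mm\n", sep = "")
  invisible(x)
}

#' The standard nested VOI triple of the QA protocol
#'
#' VOI1 10x10x6.5 mm, VOI2 16x16x13 mm, VOI3 16x16x25 mm, all centered at
#' `isocenter + c(0, 0, z_offset)`. The +2 mm default z offset keeps the
#' boxes clear of the strong inhomogeneity at the lower phantom edge.
#'
#' @param z_offset mm shift of the common center along z (default 2).
#' @param isocenter mm triple (default the scanner isocenter, the origin).
#' @return Named list of three [voi()] objects.
#' @export
standard_vois <- function(z_offset = 2, isocenter = c(0, 0, 0)) {
  ctr <- isocenter + c(0, 0, z_offset)
  list(VOI1 = voi(ctr, c(10, 10, 6.5)),
       VOI2 = voi(ctr, c(16, 16, 13)),
       VOI3 = voi(ctr, c(16, 16, 25)))
}

#' Voxel mask of a VOI on a volume grid
#'
#' A voxel belongs to the VOI iff its center lies in the half-open box
#' `[center - extent/2, center + extent/2)`. The half-open convention makes
#' masks of adjacent VOIs partition cleanly.
#'
#' @param v a [voi()].
#' @param geometry an `image_volume` (or anything carrying spacing/origin).
#' @return Logical 3D array. Warns and returns an all-`FALSE` mask when the
#'   VOI misses the volume entirely.
#' @export
voi_voxel_mask <- function(v, geometry) {
  d <- vol_dim(geometry)
  inside <- lapply(1:3, function(a) {
    cc <- geometry$origin[a] + (seq_len(d[a]) - 1) * geometry$spacing[a]
    cc >= v$center[a] - v$extents[a] / 2 - 1e-9 &
      cc < v$center[a] + v$extents[a] / 2 - 1e-9
  })
  m <- array(FALSE, d)
  if (all(lengths(lapply(inside, which)) > 0)) {
    m[inside[[1]], inside[[2]], inside[[3]]] <- TRUE
  } else {
    warning("VOI does not intersect the volume; empty mask", call. = FALSE)
  }
  m
}

#' Shell mask between two VOIs (outer minus inner)
#'
#' The region evaluated when growing a VOI: voxels of `outer` not already in
#' `inner` (e.g. VOI2-VOI1, VOI3-VOI2).
#'
#' @param outer,inner [voi()] objects on the same geometry.
#' @param geometry an `image_volume`.
#' @return Logical 3D array `outer & !inner`.
#' @export
voi_difference_mask <- function(outer, inner, geometry) {
  voi_voxel_mask(outer, geometry) & !voi_voxel_mask(inner, geometry)
}

#' Nested shell masks VOI1, VOI2-VOI1, VOI3-VOI2
#' @param vois list of three [voi()]s ordered smallest to largest.
#' @param geometry an `image_volume`.
#' @return Named list of three logical masks.
#' @export
nested_voi_masks <- function(vois, geometry) {
  stopifnot(length(vois) == 3L)
  nm <- names(vois)
  if (is.null(nm)) nm <- c("VOI1", "VOI2", "VOI3")
  out <- list(voi_voxel_mask(vois[[1]], geometry),
              voi_difference_mask(vois[[2]], vois[[1]], geometry),
              voi_difference_mask(vois[[3]], vois[[2]], geometry))
  names(out) <- c(nm[1], paste0(nm[2], "-", nm[1]), paste0(nm[3], "-", nm[2]))
  out
}
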