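#' Compose correction steps and resample once
#'
#' Correction pipelines chain several spatial operations (rigid alignment,
#' dense displacement fields, readout unwarping). Resampling the image at
#' every step compounds interpolation blur and phase bias; instead, the
#' point mapping of every step is composed and the source volume is sampled
#' exactly once.
#'
#' Steps are applied to the output voxel centers in list order; each step
#' maps sample points `p` onwards:
#' * a [rigid_transform()] maps `p -> R (p - c) + c + t`;
#' * a [displacement_field()] maps `p -> p + u(p)` (as [apply_field()]);
#' * a [b0_displacement_map()] maps `p -> p + dr(p) e_readout` (as
#'   [apply_b0_correction()]).
#'
#' @param vol the source `image_volume` (sampled once, trilinearly).
#' @param geometry output grid (an `image_volume` or compatible).
#' @param steps list of step objects in application order.
#' @param background fill value outside `vol`.
#' @return The resampled `image_volume` on `geometry`'s grid.
#' @export
compose_warp <- function(vol, geometry, steps, background = 0) {
  pts <- voxel_centers(geometry)
  for (st in steps) {
    if (inherits(st, "rigid_transform")) {
      pts <- transform_points(st, pts)
    } else if (inherits(st, "displacement_field")) {
      pts <- pts + sample_field(st, pts)
    } else if (inherits(st, "b0_spatial_map")) {
      ax <- match(st$readout_axis, c("x", "y", "z"))
      g <- list(spacing = st$spacing, origin = st$origin,
                data = st$displacement)
      pts[, ax] <- pts[, ax] + sample_volume(g, pts)
    } else if (is.null(st)) {
      # skipped step
    } else {
      stop("unsupported step of class ", paste(class(st), collapse = "/"),
           call. = FALSE)
    }
  }
  vals <- sample_volume(vol, pts, background)
  image_volume(array(vals, vol_dim(geometry)), geometry$spacing,
               geometry$origin, vol$encoding)
}
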