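#' Off-resonance field map
#'
#' Per-voxel static-field inhomogeneity on an image grid. Values must be in
#' hertz: the displacement model divides by `gamma_bar * G_readout`, so an
#' unlabelled unit would silently corrupt every downstream displacement. The
#' unit is therefore mandatory metadata and anything other than `"Hz"` is
#' rejected where displacements are computed.
#'
#' @param offsets numeric 3D array of off-resonance values.
#' @param spacing,origin geometry as in [image_volume()].
#' @param encoding encoding roles as in [image_volume()].
#' @param unit unit string; the package standardizes on `"Hz"`.
#' @return An object of class `field_map`.
#' @export
field_map <- function(offsets, spacing, origin = NULL,
                      encoding = c(x = "phase", y = "slice", z = "frequency"),
                      unit = "Hz") {
  if (!is.array(offsets) || length(dim(offsets)) != 3L)
    stop("`offsets` must be a 3D array", call. = FALSE)
  if (any(!is.finite(offsets)))
    stop("field map contains non-finite values", call. = FALSE)
  g <- image_volume(offsets, spacing, origin, encoding)
  structure(list(offsets = g$data, spacing = g$spacing, origin = g$origin,
                 encoding = g$encoding, unit = unit),
            class = "field_map")
}

#' @export
print.field_map <- function(x, ...) {
  cat("<field_map> ", paste(dim(x$offsets), collapse = " x "),
      " voxels (", x$unit, "), spacing ",
      paste(signif(x$spacing, 4), collapse = "/"), " mm, range [",
      paste(signif(range(x$offsets), 4), collapse = ", "), "]\n", sep = "")
  invisible(x)
}

#' Dense per-voxel displacement field
#'
#' A 3-vector (mm) per voxel, components in fixed scanner order (x, y, z).
#' Carries `frame` metadata recording in which image's frame the field was
#' estimated (the registration's fixed image), so phantom-derived GNL maps
#' can be transferred to subject images without ambiguity.
#'
#' @param vectors 4D numeric array `dim x 3`, last axis = (x, y, z)
#'   components in mm.
#' @param spacing,origin,encoding geometry as in [image_volume()].
#' @param frame free-text label of the defining frame (default "scanner").
#' @param fixed_image optional label of the registration's fixed image.
#' @return An object of class `displacement_field`.
#' @export
displacement_field <- function(vectors, spacing, origin = NULL,
                               encoding = c(x = "phase", y = "slice",
                                            z = "frequency"),
                               frame = "scanner", fixed_image = NULL) {
  dv <- dim(vectors)
  if (length(dv) != 4L || dv[4] != 3L)
    stop("`vectors` must be a dim x 3 4D array (mm)", call. = FALSE)
  if (any(!is.finite(vectors)))
    stop("displacement field contains non-finite values", call. = FALSE)
  g <- image_volume(array(0, dv[1:3]), spacing, origin, encoding)
  storage.mode(vectors) <- "double"
  structure(list(vectors = vectors, spacing = g$spacing, origin = g$origin,
                 encoding = g$encoding, frame = frame,
                 fixed_image = fixed_image),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  mag <- sqrt(x$vectors[, , , 1]^2 + x$vectors[, , , 2]^2 + x$vectors[, , , 3]^2)
  cat("<displacement_field> ", paste(dim(x$vectors)[1:3], collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = "/"),
      " mm\n  |d| max ", signif(max(mag), 4), " mm, frame: ", x$frame,
      if (!is.null(x$fixed_image)) paste0(" (fixed: ", x$fixed_image, ")"),
      "\n", sep = "")
  invisible(x)
}

#' Zero displacement field on a geometry
#' @param geometry an `image_volume` (or compatible).
#' @return A `displacement_field` of zeros.
#' @export
zero_field <- function(geometry) {
  d <- vol_dim(geometry)
  displacement_field(array(0, c(d, 3L)), geometry$spacing, geometry$origin,
                     geometry$encoding)
}

#' Resample a displacement field to a new spacing or onto a target grid
#'
#' Component-wise trilinear interpolation. Vectors are physical mm
#' displacements, so values are *not* rescaled when the voxel size changes.
#' Samples requested outside the field's grid get zero displacement (a field
#' is only informative where it was estimated).
#'
#' @param field a `displacement_field`.
#' @param target_spacing mm triple (scalar recycled); ignored when
#'   `geometry` is given.
#' @param geometry optional `image_volume`: resample onto exactly this grid
#'   (used to put a phantom-derived map onto a subject grid).
#' @return A `displacement_field`.
#' @export
resample_field <- function(field, target_spacing = NULL, geometry = NULL) {
  if (is.null(geometry)) {
    target_spacing <- rep_len(as.numeric(target_spacing), 3L)
    if (any(target_spacing <= 0)) stop("`target_spacing` must be positive",
                                       call. = FALSE)
    d <- dim(field$vectors)[1:3]
    extent <- (d - 1) * field$spacing
    nd <- pmax(1L, as.integer(floor(extent / target_spacing + 1e-9)) + 1L)
    nsp <- target_spacing
    norig <- field$origin
  } else {
    nd <- vol_dim(geometry)
    nsp <- geometry$spacing
    norig <- geometry$origin
  }
  d <- dim(field$vectors)[1:3]
  comp <- lapply(1:3, function(c3) {
    array(cpp_warp_pull(field$vectors[, , , c3], d, field$spacing,
                        field$origin, nd, nsp, norig, 0, 0, 0, 0), nd)
  })
  vec <- array(0, c(nd, 3L))
  for (c3 in 1:3) vec[, , , c3] <- comp[[c3]]
  displacement_field(vec, nsp, norig, field$encoding,
                     frame = field$frame, fixed_image = field$fixed_image)
}

#' Sample a displacement field at physical points
#' @param field a `displacement_field`.
#' @param points n x 3 mm matrix.
#' @return n x 3 matrix of mm displacement vectors (zero outside the grid).
#' @export
sample_field <- function(field, points) {
  points <- as.matrix(points)
  d <- dim(field$vectors)[1:3]
  out <- vapply(1:3, function(c3)
    cpp_sample_points(field$vectors[, , , c3], d, field$spacing,
                      field$origin, points, 0),
    numeric(nrow(points)))
  colnames(out) <- c("x", "y", "z")
  out
}

#' Apply a displacement field to a volume
#'
#' Inverse-warp resampling: the output voxel at position `p` takes the value
#' of the input at `p + field(p)`. This is the convention under which a
#' field returned by [ffd_register()] *corrects* its moving image, and under
#' which a phantom GNL map corrects a subject image.
#'
#' @param vol an `image_volume`.
#' @param field a `displacement_field` on the same grid as `vol` (resample
#'   first with [resample_field()]; a mismatch is an error, not a guess).
#' @param background fill value outside the input grid.
#' @return The warped `image_volume`.
#' @export
apply_field <- function(vol, field, background = 0) {
  if (!same_geometry(vol, field))
    stop("field geometry does not match the volume; resample_field() first",
         call. = FALSE)
  d <- dim(vol$data)
  out <- cpp_warp_pull(vol$data, d, vol$spacing, vol$origin,
                       d, vol$spacing, vol$origin,
                       field$vectors[, , , 1], field$vectors[, , , 2],
                       field$vectors[, , , 3], background)
  image_volume(array(out, d), vol$spacing, vol$origin, vol$encoding)
}

#' Read/write displacement fields as 4D NIfTI
#'
#' Fields are stored as 4D NIfTI with the 3 mm-components (x, y, z scanner
#' order) along the 4th axis, plus a JSON sidecar recording component order,
#' frame and fixed-image labels.
#'
#' @param field a `displacement_field`.
#' @param path `.nii`/`.nii.gz` output path.
#' @return `path` (write) or a `displacement_field` (read).
#' @export
write_field <- function(field, path) {
  img <- RNifti::asNifti(field$vectors)
  RNifti::pixdim(img) <- c(field$spacing, 1)
  xf <- diag(4)
  diag(xf)[1:3] <- field$spacing
  xf[1:3, 4] <- field$origin
  RNifti::sform(img) <- structure(xf, code = 2L)
  RNifti::qform(img) <- structure(xf, code = 2L)
  RNifti::writeNifti(img, path)
  jsonlite::write_json(
    list(component_order = c("x", "y", "z"), unit = "mm",
         encoding = as.list(field$encoding), frame = field$frame,
         fixed_image = field$fixed_image),
    sidecar_path(path), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L || d[4] != 3L)
    stop("not a 3-component 4D displacement field", call. = FALSE)
  spacing <- RNifti::pixdim(img)[1:3]
  origin <- nifti_origin(img)
  meta <- list(encoding = list(x = "phase", y = "slice", z = "frequency"),
               frame = "scanner", fixed_image = NULL)
  sc <- sidecar_path(path)
  if (file.exists(sc))
    meta <- modifyList(meta, jsonlite::read_json(sc, simplifyVector = TRUE))
  displacement_field(array(as.numeric(img), d), spacing, origin,
                     unlist(meta$encoding), frame = meta$frame,
                     fixed_image = meta$fixed_image)
}

#' Read a field map (Hz) from NIfTI
#'
#' The unit must be present in the sidecar (or given explicitly) and must be
#' `"Hz"`; nothing is guessed.
#' @param path NIfTI path.
#' @param unit override for the sidecar unit.
#' @param encoding override for the sidecar encoding roles.
#' @return A `field_map`.
#' @export
read_field_map <- function(path, unit = NULL, encoding = NULL) {
  sc <- sidecar_path(path)
  meta <- if (file.exists(sc)) jsonlite::read_json(sc, simplifyVector = TRUE)
          else list()
  if (is.null(unit)) unit <- meta$unit
  if (is.null(unit))
    stop("field-map unit missing: record `unit` in the sidecar or pass it",
         call. = FALSE)
  if (is.null(encoding) && !is.null(meta$encoding))
    encoding <- unlist(meta$encoding)
  vol <- read_volume(path, encoding = encoding)
  field_map(vol$data, vol$spacing, vol$origin, vol$encoding, unit = unit)
}
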