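#' 3D scalar image volume with physical geometry
#'
#' The central container of the package: a 3D array plus the metadata needed
#' to place every voxel in the scanner frame. Arrays are stored in scanner
#' (x, y, z) axis order; voxel `(i, j, k)` (0-based) has its *center* at
#' `origin + c(i, j, k) * spacing` millimetres. Encoding roles record which
#' scanner axis is the frequency-encoding (readout) axis — the axis along
#' which B0 off-resonance displaces signal in Cartesian sequences.
#'
#' @param data numeric 3D array, scanner (x, y, z) axis order.
#' @param spacing positive numeric length-3, mm per voxel along (x, y, z).
#' @param origin numeric length-3, mm position of the center of voxel
#'   (0,0,0). Default centers the volume on the scanner isocenter.
#' @param encoding named character length-3 mapping scanner axes to encoding
#'   roles; exactly one axis must be `"frequency"`, the others `"phase"` and
#'   `"slice"`.
#' @return An object of class `image_volume`.
#' @examples
#' vol <- image_volume(array(0, c(10, 10, 10)), spacing = c(0.2, 0.2, 0.2))
#' frequency_axis(vol)
#' @export
image_volume <- function(data, spacing, origin = NULL,
                         encoding = c(x = "phase", y = "slice", z = "frequency")) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite values (mm)", call. = FALSE)
  if (is.null(origin))
    origin <- -(dim(data) - 1) / 2 * spacing
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values (mm)", call. = FALSE)
  encoding <- check_encoding(encoding)
  storage.mode(data) <- "double"
  structure(list(data = data, spacing = spacing, origin = origin,
                 encoding = encoding),
            class = "image_volume")
}

check_encoding <- function(encoding) {
  if (is.null(names(encoding)) || !setequal(names(encoding), c("x", "y", "z")))
    stop("`encoding` must be named with scanner axes x, y, z", call. = FALSE)
  encoding <- encoding[c("x", "y", "z")]
  if (sum(encoding == "frequency") != 1L)
    stop("exactly one axis must have encoding role \"frequency\"", call. = FALSE)
  if (!all(encoding %in% c("frequency", "phase", "slice")))
    stop("encoding roles must be frequency/phase/slice", call. = FALSE)
  encoding
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = "/"),
      " mm\n  origin (", paste(signif(x$origin, 4), collapse = ", "),
      ") mm, frequency axis: ", frequency_axis(x), "\n", sep = "")
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

#' Scanner axis carrying the frequency-encoding role
#' @param vol an `image_volume`
#' @return `"x"`, `"y"` or `"z"`.
#' @export
frequency_axis <- function(vol) {
  names(vol$encoding)[vol$encoding == "frequency"]
}

#' Physical coordinates of voxel centers
#'
#' @param vol an `image_volume` (or any object with `spacing`/`origin` and a
#'   3D `data`/`offsets` array).
#' @param axis optional, one of 1:3 or "x"/"y"/"z": return the 1D coordinate
#'   vector along that axis instead of the full point matrix.
#' @return With `axis`: a numeric vector. Otherwise an n-voxel x 3 matrix of
#'   mm coordinates in array order.
#' @export
voxel_centers <- function(vol, axis = NULL) {
  d <- vol_dim(vol)
  if (!is.null(axis)) {
    if (is.character(axis)) axis <- match(axis, c("x", "y", "z"))
    return(vol$origin[axis] + (seq_len(d[axis]) - 1) * vol$spacing[axis])
  }
  cx <- vol$origin[1] + (seq_len(d[1]) - 1) * vol$spacing[1]
  cy <- vol$origin[2] + (seq_len(d[2]) - 1) * vol$spacing[2]
  cz <- vol$origin[3] + (seq_len(d[3]) - 1) * vol$spacing[3]
  cbind(x = rep(cx, times = d[2] * d[3]),
        y = rep(rep(cy, each = d[1]), times = d[3]),
        z = rep(cz, each = d[1] * d[2]))
}

vol_dim <- function(vol) {
  if (!is.null(vol$data)) dim(vol$data)
  else if (!is.null(vol$offsets)) dim(vol$offsets)
  else dim(vol$vectors)[1:3]
}

same_geometry <- function(a, b, tol = 1e-6) {
  identical(vol_dim(a), vol_dim(b)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

#' Read a 3D NIfTI-1 volume with its sidecar metadata
#'
#' Reads a NIfTI-1 file into an [image_volume()]. Encoding roles (which
#' scanner axis is frequency/phase/slice encoded) are *mandatory* metadata:
#' they are taken from a JSON sidecar (same path with `.json` substituted for
#' the NIfTI extension, fields `encoding` and optionally `gradient_spec`) or
#' from the `encoding` argument. They are never inferred from the NIfTI
#' header, which does not carry them.
#'
#' @param path path to a `.nii` or `.nii.gz` file with a 3D scalar payload.
#' @param encoding optional named character vector overriding/replacing the
#'   sidecar (`c(x=,y=,z=)` with one `"frequency"`).
#' @return An `image_volume`; if the sidecar defines `gradient_spec`, it is
#'   attached as attribute `"gradient_spec"`.
#' @export
read_volume <- function(path, encoding = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- array(img, d[1:3])
    d <- d[1:3]
  }
  if (length(d) != 3L)
    stop("NIfTI payload is not a 3D scalar volume (dims: ",
         paste(d, collapse = "x"), ")", call. = FALSE)
  spacing <- RNifti::pixdim(img)[1:3]
  origin <- nifti_origin(img)
  sidecar <- sidecar_path(path)
  grad <- NULL
  if (is.null(encoding)) {
    if (file.exists(sidecar)) {
      meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
      if (!is.null(meta$encoding)) encoding <- unlist(meta$encoding)
      if (!is.null(meta$gradient_spec))
        grad <- do.call(gradient_spec, as.list(meta$gradient_spec))
      if (!is.null(meta$unit)) attr(img, "unit") <- meta$unit
    }
    if (is.null(encoding))
      stop("no encoding-role metadata: provide a JSON sidecar (", sidecar,
           ") or the `encoding` argument; roles are never guessed",
           call. = FALSE)
  }
  vol <- image_volume(array(as.numeric(img), d), spacing = spacing,
                      origin = origin, encoding = encoding)
  if (!is.null(grad)) attr(vol, "gradient_spec") <- grad
  if (!is.null(attr(img, "unit"))) attr(vol, "unit") <- attr(img, "unit")
  vol
}

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

nifti_origin <- function(img) {
  xf <- RNifti::xform(img)
  # NIfTI sform/qform use RAS; the package stores the translation column as
  # the physical position of voxel (0,0,0) directly.
  as.numeric(xf[1:3, 4])
}

#' Write a volume (plus sidecar) as NIfTI-1
#'
#' @param vol an `image_volume` (or `field_map`, written as its offsets).
#' @param path output `.nii` / `.nii.gz` path; a `.json` sidecar with the
#'   encoding roles (and unit, for field maps) is written alongside.
#' @param gradient_spec optional [gradient_spec()] recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, gradient_spec = NULL) {
  dat <- if (!is.null(vol$data)) vol$data else vol$offsets
  img <- RNifti::asNifti(dat)
  RNifti::pixdim(img) <- vol$spacing
  xf <- diag(4)
  diag(xf)[1:3] <- vol$spacing
  xf[1:3, 4] <- vol$origin
  RNifti::sform(img) <- structure(xf, code = 2L)
  RNifti::qform(img) <- structure(xf, code = 2L)
  RNifti::writeNifti(img, path)
  meta <- list(encoding = as.list(vol$encoding))
  if (!is.null(vol$unit)) meta$unit <- vol$unit
  if (!is.null(gradient_spec)) meta$gradient_spec <- unclass(gradient_spec)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}

#' Resample a volume to a new voxel spacing
#'
#' Trilinear (default) interpolation at the new voxel centers. The output
#' grid keeps the first voxel center at the input origin and covers the input
#' physical extent (to within one target voxel). Resampling at the identical
#' spacing returns the input values bit-exactly.
#'
#' @param vol an `image_volume`.
#' @param target_spacing positive numeric length-3 (or scalar, recycled), mm.
#' @param background fill value for samples outside the input grid.
#' @return A resampled `image_volume`.
#' @export
resample_volume <- function(vol, target_spacing, background = 0) {
  target_spacing <- rep_len(as.numeric(target_spacing), 3L)
  if (any(!is.finite(target_spacing)) || any(target_spacing <= 0))
    stop("`target_spacing` must be positive", call. = FALSE)
  d <- dim(vol$data)
  extent <- (d - 1) * vol$spacing
  nd <- pmax(1L, as.integer(floor(extent / target_spacing + 1e-9)) + 1L)
  out <- cpp_warp_pull(vol$data, d, vol$spacing, vol$origin,
                       nd, target_spacing, vol$origin,
                       0, 0, 0, background)
  image_volume(array(out, nd), spacing = target_spacing, origin = vol$origin,
               encoding = vol$encoding)
}

#' Crop a volume to a physical box
#'
#' Keeps the voxels whose centers lie inside the closed box
#' `center ± extent/2` (mm, scanner frame). Used e.g. to crop a CT volume to
#' the MR field of view before registration.
#'
#' @param vol an `image_volume`.
#' @param center,extent mm triples defining the box.
#' @return The cropped `image_volume`.
#' @export
crop_volume <- function(vol, center, extent) {
  idx <- lapply(1:3, function(a) {
    cc <- voxel_centers(vol, a)
    which(cc >= center[a] - extent[a] / 2 - 1e-9 &
          cc <= center[a] + extent[a] / 2 + 1e-9)
  })
  if (any(lengths(idx) == 0L))
    stop("crop box does not intersect the volume", call. = FALSE)
  out <- vol$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  origin <- vol$origin + (vapply(idx, min, 1L) - 1) * vol$spacing
  image_volume(out, spacing = vol$spacing, origin = origin,
               encoding = vol$encoding)
}

#' Sample a volume at arbitrary physical points
#'
#' @param vol an `image_volume` (or `field_map`).
#' @param points n x 3 matrix of mm coordinates.
#' @param background value returned outside the grid.
#' @return Numeric vector of trilinearly interpolated values.
#' @export
sample_volume <- function(vol, points, background = 0) {
  dat <- if (!is.null(vol$data)) vol$data else vol$offsets
  points <- as.matrix(points)
  cpp_sample_points(dat, dim(dat), vol$spacing, vol$origin,
                    points, background)
}
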