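#' Imaging gradient specification
#'
#' Gradient strengths and the readout (frequency-encoding) axis used to
#' convert off-resonance (Hz) into millimetres of displacement. The
#' proton reduced gyromagnetic ratio `gamma_bar` defaults to 42.5774 MHz/T.
#'
#' @param Gx,Gy,Gz gradient strengths, mT/m (defaults: 56.1 on the readout
#'   axis convention of a high-field preclinical protocol).
#' @param readout_axis `"x"`, `"y"` or `"z"`.
#' @param gamma_bar reduced gyromagnetic ratio, MHz/T.
#' @return An object of class `gradient_spec`.
#' @export
gradient_spec <- function(Gx = 56.1, Gy = 56.1, Gz = 56.1,
                          readout_axis = "z", gamma_bar = 42.5774) {
  if (any(c(Gx, Gy, Gz) <= 0)) stop("gradient strengths must be > 0",
                                    call. = FALSE)
  readout_axis <- match.arg(readout_axis, c("x", "y", "z"))
  structure(list(Gx = Gx, Gy = Gy, Gz = Gz, readout_axis = readout_axis,
                 gamma_bar = gamma_bar),
            class = "gradient_spec")
}

readout_strength <- function(grad) {
  switch(grad$readout_axis, x = grad$Gx, y = grad$Gy, z = grad$Gz)
}

#' Convert off-resonance (Hz) to readout displacement (mm)
#'
#' The scalar displacement model: `dr = dB0 / (gamma_bar * G_readout)`.
#' With the MHz/T and mT/m units used here this is
#' `Hz / (gamma_bar * 1e6 * G * 1e-3)` metres, returned in mm.
#'
#' @param hz off-resonance value(s) in Hz.
#' @param grad a [gradient_spec()].
#' @return Displacement(s) in mm, same shape as `hz`.
#' @export
hz_to_mm <- function(hz, grad) {
  hz / (grad$gamma_bar * 1e6 * readout_strength(grad) * 1e-3) * 1e3
}

# ---- shim-residual (B0) field simulator ------------------------------------

shim_basis_terms <- c("constant", "x", "y", "z",
                      "xy", "xz", "yz", "x2y2", "z2",
                      "x3", "y3", "z3", "xyz", "xz2", "yz2")

eval_shim_basis <- function(term, x, y, z) {
  switch(term,
         constant = rep(1, length(x)),
         x = x, y = y, z = z,
         xy = x * y, xz = x * z, yz = y * z,
         x2y2 = x^2 - y^2, z2 = z^2,
         x3 = x^3, y3 = y^3, z3 = z^3,
         xyz = x * y * z, xz2 = x * z^2, yz2 = y * z^2,
         stop("unknown shim basis term: ", term, call. = FALSE))
}

terms_up_to_order <- function(order) {
  switch(order,
         `1` = shim_basis_terms[1:4],
         `2` = shim_basis_terms[1:9],
         `3` = shim_basis_terms)
}

#' Shim configuration: polynomial off-resonance coefficients
#'
#' A residual static-field scenario expressed in a polynomial basis on
#' coordinates normalized to \[-1, 1\] over a reference half-FOV, so each
#' coefficient is "Hz at the FOV edge". Allowed terms: constant, x, y, z,
#' xy, xz, yz, x2y2 (x^2 - y^2), z2, x3, y3, z3, xyz, xz2, yz2.
#'
#' @param coefficients named numeric vector of amplitudes (Hz at normalized
#'   unit), names from the allowed term set.
#' @param label free-text scenario label.
#' @param isocenter mm triple, expansion center.
#' @param half_fov mm triple: the normalization half-FOV (where the
#'   normalized coordinate reaches 1). Default 15 x 15 x 21 mm, a typical
#'   small-bore acquisition FOV.
#' @return An object of class `shim_config`.
#' @export
shim_config <- function(coefficients, label = "",
                        isocenter = c(0, 0, 0), half_fov = c(15, 15, 21)) {
  coefficients <- unlist(coefficients)
  bad <- setdiff(names(coefficients), shim_basis_terms)
  if (length(bad) > 0)
    stop("unknown shim basis term(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(coefficients)))
    stop("shim amplitudes must be finite", call. = FALSE)
  structure(list(coefficients = coefficients, label = label,
                 isocenter = as.numeric(isocenter),
                 half_fov = rep_len(as.numeric(half_fov), 3L)),
            class = "shim_config")
}

#' Evaluate a shim configuration at physical points (Hz)
#' @param cfg a [shim_config()].
#' @param points n x 3 mm matrix.
#' @return Numeric vector of off-resonance values, Hz.
#' @export
shim_offsets <- function(cfg, points) {
  points <- as.matrix(points)
  xh <- (points[, 1] - cfg$isocenter[1]) / cfg$half_fov[1]
  yh <- (points[, 2] - cfg$isocenter[2]) / cfg$half_fov[2]
  zh <- (points[, 3] - cfg$isocenter[3]) / cfg$half_fov[3]
  out <- numeric(nrow(points))
  for (term in names(cfg$coefficients))
    out <- out + cfg$coefficients[[term]] * eval_shim_basis(term, xh, yh, zh)
  out
}

#' Render a shim configuration as a discrete field map
#'
#' Pure evaluation of the polynomial at every voxel center; no randomness.
#'
#' @param cfg a [shim_config()].
#' @param geometry an `image_volume` providing the grid.
#' @return A [field_map()] in Hz.
#' @export
make_shim_field <- function(cfg, geometry) {
  vals <- shim_offsets(cfg, voxel_centers(geometry))
  field_map(array(vals, vol_dim(geometry)), geometry$spacing,
            geometry$origin, geometry$encoding, unit = "Hz")
}

#' Random "rough" off-resonance field for shim-scenario simulation
#'
#' Draws random polynomial coefficients over the full basis plus a smooth
#' off-center Gaussian bump (so the field is not exactly representable in
#' the shim basis), emulating the raw inhomogeneity a scanner exhibits
#' before shimming.
#'
#' @param seed integer seed.
#' @param amplitude approximate Hz scale at the FOV edge.
#' @param isocenter,half_fov normalization as in [shim_config()].
#' @return A function of an `image_volume` geometry returning a
#'   [field_map()] — plus attribute `"points_fun"` evaluating at raw points.
#' @export
rough_field <- function(seed, amplitude = 600,
                        isocenter = c(0, 0, 0), half_fov = c(15, 15, 21)) {
  with_seed(seed, {
    co <- rnorm(length(shim_basis_terms), 0, amplitude / 3)
    names(co) <- shim_basis_terms
    co["constant"] <- rnorm(1, 0, amplitude / 6)
    bump_c <- runif(3, -0.6, 0.6)
    bump_a <- rnorm(1, 0, amplitude / 2)
    bump_w <- runif(1, 0.4, 0.8)
  })
  cfg <- shim_config(co, label = sprintf("rough seed %d", seed),
                     isocenter = isocenter, half_fov = half_fov)
  pf <- function(points) {
    points <- as.matrix(points)
    xh <- sweep(sweep(points, 2, isocenter), 2, half_fov, "/")
    r2 <- (xh[, 1] - bump_c[1])^2 + (xh[, 2] - bump_c[2])^2 +
      (xh[, 3] - bump_c[3])^2
    shim_offsets(cfg, points) + bump_a * exp(-r2 / bump_w^2)
  }
  f <- function(geometry) {
    vals <- pf(voxel_centers(geometry))
    field_map(array(vals, vol_dim(geometry)), geometry$spacing,
              geometry$origin, geometry$encoding, unit = "Hz")
  }
  attr(f, "points_fun") <- pf
  f
}

#' Residual field after best-fit polynomial shimming
#'
#' Emulates active shimming of a given order: least-squares fits the shim
#' basis up to `order` (or an explicit term subset) to the field over the
#' volume (optionally within a mask) and subtracts the fit.
#'
#' @param field a [field_map()] (Hz).
#' @param order 1, 2 or 3 — ignored when `terms` is given.
#' @param terms explicit character vector of basis terms to fit.
#' @param mask optional logical array: fit only over these voxels (the
#'   shim target volume).
#' @param isocenter,half_fov normalization as in [shim_config()].
#' @param stride voxel subsampling stride for the fit (the residual is
#'   evaluated everywhere).
#' @return A [field_map()] of the residual, with the fitted coefficients in
#'   attribute `"fit"`.
#' @export
shim_residual <- function(field, order = 1, terms = NULL, mask = NULL,
                          isocenter = c(0, 0, 0), half_fov = c(15, 15, 21),
                          stride = 2) {
  if (is.null(terms)) terms <- terms_up_to_order(as.character(order))
  pts <- voxel_centers(field)
  xh <- (pts[, 1] - isocenter[1]) / half_fov[1]
  yh <- (pts[, 2] - isocenter[2]) / half_fov[2]
  zh <- (pts[, 3] - isocenter[3]) / half_fov[3]
  X <- vapply(terms, eval_shim_basis, numeric(length(xh)), x = xh, y = yh,
              z = zh)
  y <- as.numeric(field$offsets)
  sel <- seq(1, length(y), by = stride)
  if (!is.null(mask)) sel <- intersect(sel, which(as.logical(mask)))
  beta <- qr.coef(qr(X[sel, , drop = FALSE]), y[sel])
  beta[is.na(beta)] <- 0
  res <- y - as.numeric(X %*% beta)
  out <- field_map(array(res, vol_dim(field)), field$spacing, field$origin,
                   field$encoding, unit = field$unit)
  attr(out, "fit") <- setNames(as.numeric(beta), terms)
  out
}

#' Simulated shimming scenarios from one rough field
#'
#' Builds the three scenario analogs studied on the phantom:
#' scenario 1 = residual after 1st-order (linear) shimming only;
#' scenario 2 = residual after fitting all terms up to 3rd order (map-based
#' shimming); scenario 3 = 1st order plus all 2nd-order terms and z3
#' (pre-set higher-order currents without a field map).
#'
#' @param geometry an `image_volume` grid on which to render the fields.
#' @param seed integer seed for the rough field.
#' @param amplitude Hz scale of the rough field at the FOV edge.
#' @param mask optional shim-target mask passed to [shim_residual()].
#' @return Named list of three [field_map()]s (`shim1`, `shim2`, `shim3`),
#'   with the rough field as attribute `"rough"`.
#' @export
simulate_shim_scenarios <- function(geometry, seed = 1, amplitude = 600,
                                    mask = NULL) {
  rf <- rough_field(seed, amplitude)
  raw <- rf(geometry)
  s1 <- shim_residual(raw, order = 1, mask = mask)
  s2 <- shim_residual(raw, order = 3, mask = mask)
  s3 <- shim_residual(raw, terms = c(terms_up_to_order("2"), "z3"),
                      mask = mask)
  out <- list(shim1 = s1, shim2 = s2, shim3 = s3)
  attr(out, "rough") <- raw
  out
}

# ---- GNL field simulator ---------------------------------------------------

#' Gradient non-linearity configuration
#'
#' Smooth odd-polynomial per-axis displacement model of gradient-coil
#' non-linearity: along axis i the displacement is
#' `d_i = a3_i * p^3 + a5_i * p^5` mm, with `p` the coordinate normalized to
#' \[-1, 1\] over `half_fov` around the isocenter. Displacement is exactly
#' zero at the isocenter and (for same-sign coefficients) grows
#' monotonically with distance, as gradient-coil fields do.
#'
#' @param a3,a5 length-3 (or scalar) mm displacement amplitudes at the
#'   normalized FOV edge, per axis.
#' @param isocenter mm triple.
#' @param half_fov normalization half-FOV, mm (default 15 x 15 x 21).
#' @return An object of class `gnl_config`.
#' @export
gnl_config <- function(a3 = c(0, 0, 0), a5 = c(0, 0, 0),
                       isocenter = c(0, 0, 0), half_fov = c(15, 15, 21)) {
  a3 <- rep_len(as.numeric(a3), 3L)
  a5 <- rep_len(as.numeric(a5), 3L)
  if (any(!is.finite(c(a3, a5)))) stop("coefficients must be finite",
                                       call. = FALSE)
  structure(list(a3 = a3, a5 = a5, isocenter = as.numeric(isocenter),
                 half_fov = rep_len(as.numeric(half_fov), 3L)),
            class = "gnl_config")
}

#' Analytic GNL displacement at physical points
#' @param cfg a [gnl_config()].
#' @param points n x 3 mm matrix.
#' @return n x 3 matrix of mm displacement vectors.
#' @export
gnl_displacement <- function(cfg, points) {
  points <- as.matrix(points)
  out <- matrix(0, nrow(points), 3,
                dimnames = list(NULL, c("x", "y", "z")))
  for (a in 1:3) {
    p <- (points[, a] - cfg$isocenter[a]) / cfg$half_fov[a]
    out[, a] <- cfg$a3[a] * p^3 + cfg$a5[a] * p^5
  }
  out
}

#' Render a GNL configuration as a dense displacement field
#'
#' Separable per-axis evaluation at voxel centers.
#'
#' @param cfg a [gnl_config()].
#' @param geometry an `image_volume` grid.
#' @return A [displacement_field()] (mm), frame `"scanner"`.
#' @export
make_gnl_field <- function(cfg, geometry) {
  d <- vol_dim(geometry)
  vec <- array(0, c(d, 3L))
  for (a in 1:3) {
    p <- (voxel_centers(geometry, a) - cfg$isocenter[a]) / cfg$half_fov[a]
    da <- cfg$a3[a] * p^3 + cfg$a5[a] * p^5
    vec[, , , a] <- switch(a,
                           array(da, d),
                           array(rep(da, each = d[1]), d),
                           array(rep(da, each = d[1] * d[2]), d))
  }
  displacement_field(vec, geometry$spacing, geometry$origin,
                     geometry$encoding, frame = "scanner")
}

# ---- forward distortion model ----------------------------------------------

# Total forward displacement dr(p) (mm, n x 3) at points p: the B0 term acts
# along the readout axis only, the GNL term along all three axes. `field`
# may be a shim_config (analytic) or field_map (interpolated); `gnl` a
# gnl_config or displacement_field.
total_displacement <- function(points, field, grad, gnl) {
  points <- as.matrix(points)
  dr <- matrix(0, nrow(points), 3)
  if (!is.null(field)) {
    if (is.null(grad)) stop("`grad` is required with a B0 field",
                            call. = FALSE)
    hz <- if (inherits(field, "shim_config")) shim_offsets(field, points)
          else if (inherits(field, "field_map")) {
            if (!identical(field$unit, "Hz"))
              stop("field map unit must be Hz, got: ", field$unit,
                   call. = FALSE)
            sample_volume(field, points)
          } else stop("`field` must be a shim_config or field_map",
                      call. = FALSE)
    ax <- match(grad$readout_axis, c("x", "y", "z"))
    dr[, ax] <- dr[, ax] + hz_to_mm(hz, grad)
  }
  if (!is.null(gnl)) {
    dgnl <- if (inherits(gnl, "gnl_config")) gnl_displacement(gnl, points)
            else if (inherits(gnl, "displacement_field")) sample_field(gnl, points)
            else stop("`gnl` must be a gnl_config or displacement_field",
                      call. = FALSE)
    dr <- dr + dgnl
  }
  dr
}

#' Apply the forward distortion model to a volume
#'
#' Simulates acquisition distortion: a feature at undistorted position `v`
#' appears at `v' = v + dr(v)`, where the B0 term
#' `dB0/(gamma_bar * G_readout)` acts only along the frequency-encoding
#' axis and the GNL term along all three axes. Implemented as a first-order
#' inverse warp (the output voxel at `p` samples the input at `p - dr(p)`),
#' the standard artifact-free resampling direction; the displacement is
#' evaluated at the undistorted coordinate, the small-displacement
#' convention under which distortion and correction round-trip.
#'
#' @param vol an `image_volume` to distort.
#' @param field B0 term: a [shim_config()] or [field_map()] in Hz (NULL for
#'   none). A field map on a different grid is interpolated.
#' @param grad a [gradient_spec()]; its readout axis must equal the
#'   volume's frequency-encoding axis.
#' @param gnl GNL term: a [gnl_config()] or [displacement_field()] (NULL
#'   for none).
#' @param background fill value for samples outside the grid.
#' @param signal_loss optional intensity attenuation coefficient
#'   (mm per mm): intensities are scaled by
#'   `max(0, 1 - signal_loss * |spatial gradient of the B0 displacement|)`,
#'   mimicking dephasing signal loss where the off-resonance field varies
#'   steeply within a voxel. 0 (default) disables the effect; no
#'   quantitative model is implied.
#' @return The distorted `image_volume`.
#' @export
distort_volume <- function(vol, field = NULL, grad = NULL, gnl = NULL,
                           background = 0, signal_loss = 0) {
  if (!is.null(field) && !is.null(grad) &&
      grad$readout_axis != frequency_axis(vol))
    stop("gradient readout axis (", grad$readout_axis,
         ") does not match the volume's frequency-encoding axis (",
         frequency_axis(vol), ")", call. = FALSE)
  if (is.null(field) && is.null(gnl)) return(vol)
  dr <- total_displacement(voxel_centers(vol), field, grad, gnl)
  d <- dim(vol$data)
  out <- cpp_warp_pull(vol$data, d, vol$spacing, vol$origin,
                       d, vol$spacing, vol$origin,
                       -dr[, 1], -dr[, 2], -dr[, 3], background)
  out <- array(out, d)
  if (signal_loss > 0 && !is.null(field)) {
    ax <- match(grad$readout_axis, c("x", "y", "z"))
    drb0 <- array(dr[, ax], d)
    gm <- array(0, d)
    for (a in 1:3) {
      if (d[a] < 3) next
      ii <- lapply(d, seq_len)
      lo <- ii; lo[[a]] <- pmax(ii[[a]] - 1L, 1L)
      hi <- ii; hi[[a]] <- pmin(ii[[a]] + 1L, d[a])
      step <- (hi[[a]] - lo[[a]]) * vol$spacing[a]
      step[step == 0] <- vol$spacing[a]
      diff_a <- (drb0[hi[[1]], hi[[2]], hi[[3]]] -
                 drb0[lo[[1]], lo[[2]], lo[[3]]])
      gm <- gm + (sweep(diff_a, a, step, "/"))^2
    }
    out <- out * pmax(0, 1 - signal_loss * sqrt(gm))
  }
  image_volume(out, vol$spacing, vol$origin, vol$encoding)
}

#' Apply the forward distortion model to landmark points
#'
#' Point-wise (push-forward) application of `v' = v + dr(v)` — the ground
#' truth for recovery tests. Analytic configurations are evaluated exactly;
#' discrete maps are interpolated at the landmark coordinates. Landmarks
#' outside a discrete field's domain are flagged and excluded with a
#' warning.
#'
#' @inheritParams distort_volume
#' @param lms a [landmark_set()].
#' @return The displaced `landmark_set` (source `"distorted"`).
#' @export
distort_landmarks <- function(lms, field = NULL, grad = NULL, gnl = NULL) {
  pts <- as.matrix(lms[, c("x", "y", "z")])
  keep <- rep(TRUE, nrow(pts))
  for (f in list(field, gnl)) {
    if (inherits(f, "field_map") || inherits(f, "displacement_field")) {
      d <- vol_dim(f)
      lo <- f$origin - 1e-9
      hi <- f$origin + (d - 1) * f$spacing + 1e-9
      keep <- keep & pts[, 1] >= lo[1] & pts[, 1] <= hi[1] &
        pts[, 2] >= lo[2] & pts[, 2] <= hi[2] &
        pts[, 3] >= lo[3] & pts[, 3] <= hi[3]
    }
  }
  if (!all(keep)) {
    warning(sum(!keep), " landmark(s) outside the field domain excluded",
            call. = FALSE)
    lms <- lms[keep, , drop = FALSE]
    pts <- pts[keep, , drop = FALSE]
  }
  dr <- total_displacement(pts, field, grad, gnl)
  out <- lms
  out$x <- lms$x + dr[, 1]
  out$y <- lms$y + dr[, 2]
  out$z <- lms$z + dr[, 3]
  landmark_set(out, frame = attr(lms, "frame") %||% "scanner",
               source = "distorted")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
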