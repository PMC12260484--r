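#' Rigid transform (rotation + translation about a center)
#'
#' Maps a physical point `p` (mm) to `R (p - center) + center + t`, with `R`
#' the rotation by the three Euler angles (degrees, applied as
#' `Rz %*% Ry %*% Rx`).
#'
#' @param angles length-3 rotation angles in degrees (about x, y, z).
#' @param translation mm triple.
#' @param center mm rotation center.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(angles = c(0, 0, 0), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  structure(list(angles = as.numeric(angles),
                 translation = as.numeric(translation),
                 center = as.numeric(center)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform> rot (", paste(signif(x$angles, 4), collapse = ", "),
      ") deg, trans (", paste(signif(x$translation, 4), collapse = ", "),
      ") mm\n", sep = "")
  invisible(x)
}

rotation_matrix <- function(angles_deg) {
  a <- angles_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Apply a rigid transform to points
#' @param tf a [rigid_transform()].
#' @param points n x 3 mm matrix.
#' @return n x 3 matrix of transformed points.
#' @export
transform_points <- function(tf, points) {
  points <- as.matrix(points)
  R <- rotation_matrix(tf$angles)
  sweep(sweep(points, 2, tf$center) %*% t(R), 2,
        tf$center + tf$translation, "+")
}

#' Invert a rigid transform
#' @param tf a [rigid_transform()].
#' @return The inverse `rigid_transform` (expressed with the same center),
#'   exact for the rotation; angles are re-extracted from the inverse
#'   matrix.
#' @export
invert_rigid <- function(tf) {
  R <- rotation_matrix(tf$angles)
  Ri <- t(R)
  # R (p - c) + c + t = q  =>  p = Ri (q - c - t) + c
  #                          = Ri (q - c) + c + (Ri (-t))  [about same c]
  ang <- angles_from_matrix(Ri)
  rigid_transform(ang, as.numeric(Ri %*% (-tf$translation)), tf$center)
}

#' Compose rigid transforms: `compose_rigid(a, b)(p) = a(b(p))`
#' @param a,b [rigid_transform()] objects (must share the same center).
#' @return The composed `rigid_transform`.
#' @export
compose_rigid <- function(a, b) {
  stopifnot(max(abs(a$center - b$center)) < 1e-9)
  Ra <- rotation_matrix(a$angles)
  Rb <- rotation_matrix(b$angles)
  R <- Ra %*% Rb
  t_new <- as.numeric(Ra %*% b$translation) + a$translation
  rigid_transform(angles_from_matrix(R), t_new, a$center)
}

angles_from_matrix <- function(R) {
  # inverse of Rz Ry Rx (degrees)
  beta <- asin(pmin(1, pmax(-1, -R[3, 1])))
  alpha <- atan2(R[3, 2], R[3, 3])
  gamma <- atan2(R[2, 1], R[1, 1])
  c(alpha, beta, gamma) * 180 / pi
}

#' Resample a volume through a rigid transform
#'
#' `out(p) = vol(tf(p))` on the grid of `geometry` (default: the volume's
#' own grid). This is the resampling direction under which the transform
#' returned by [rigid_register()] aligns the moving image onto the fixed
#' grid.
#'
#' @param vol the `image_volume` to resample.
#' @param tf a [rigid_transform()].
#' @param geometry output grid (an `image_volume`), default `vol`.
#' @param background fill value.
#' @return The resampled `image_volume`.
#' @export
apply_rigid <- function(vol, tf, geometry = vol, background = 0) {
  pts <- transform_points(tf, voxel_centers(geometry))
  vals <- sample_volume(vol, pts, background)
  image_volume(array(vals, vol_dim(geometry)), geometry$spacing,
               geometry$origin, vol$encoding)
}

overlap_extent <- function(a, b) {
  loA <- a$origin; hiA <- a$origin + (vol_dim(a) - 1) * a$spacing
  loB <- b$origin; hiB <- b$origin + (vol_dim(b) - 1) * b$spacing
  all(pmin(hiA, hiB) - pmax(loA, loB) > 0)
}

similarity_loss <- function(mvals, fvals, similarity) {
  if (similarity == "ssd") return(mean((mvals - fvals)^2))
  if (similarity == "ncc") {
    if (sd(mvals) == 0 || sd(fvals) == 0) return(1)
    r <- suppressWarnings(stats::cor(mvals, fvals))
    if (!is.finite(r)) return(1)
    return(1 - r^2)
  }
  # nmi: 32-bin joint histogram; loss = 2 - (H(A)+H(B))/H(A,B)
  nb <- 32L
  fb <- pmin(nb, pmax(1L, as.integer(cut(fvals, nb))))
  mb <- pmin(nb, pmax(1L, findInterval(mvals,
         seq(min(mvals), max(mvals), length.out = nb + 1L),
         all.inside = TRUE)))
  pj <- table(factor(fb, levels = 1:nb), factor(mb, levels = 1:nb)) /
    length(fb)
  px <- rowSums(pj); py <- colSums(pj)
  h <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  hj <- h(as.numeric(pj))
  if (hj == 0) return(1)
  2 - (h(px) + h(py)) / hj
}

#' Rigid registration by multi-resolution similarity optimization
#'
#' Finds the rigid transform `T` maximizing the similarity between
#' `moving(T(p))` and `fixed(p)` over the fixed grid, by deterministic
#' quasi-Newton (L-BFGS-B) optimization of the 6 pose parameters through a
#' 3-level image pyramid. Squared normalized cross-correlation is the
#' default similarity — it tolerates the inverted (but linearly related)
#' contrast of CT versus MR grid-phantom images; SSD and a histogram NMI
#' are also available.
#'
#' @param moving,fixed `image_volume`s with overlapping physical extents.
#' @param init optional initial [rigid_transform()].
#' @param similarity `"ncc"` (default), `"ssd"` or `"nmi"`.
#' @param levels number of pyramid levels (coarsest is
#'   `2^(levels-1)` x the fixed spacing).
#' @param max_iter optimizer iteration cap per level.
#' @param max_points similarity sample cap per level (fixed-grid voxels are
#'   strided down to at most this many; deterministic).
#' @param smooth_sigma Gaussian pre-smoothing (voxels) of both images for
#'   the similarity; reduces the interpolation-induced pose bias on
#'   near-binary images. The returned transform is still applied to the
#'   original images by the caller.
#' @return The fitted `rigid_transform`, with attributes `loss` (final
#'   similarity loss) and `converged` (logical; `FALSE` triggers a
#'   warning and returns the best transform found).
#' @export
rigid_register <- function(moving, fixed, init = NULL,
                           similarity = c("ncc", "ssd", "nmi"),
                           levels = 3, max_iter = 100, max_points = 6e4,
                           smooth_sigma = 1.2) {
  similarity <- match.arg(similarity)
  if (!overlap_extent(moving, fixed))
    stop("moving and fixed volumes do not overlap physically", call. = FALSE)
  center <- fixed$origin + (vol_dim(fixed) - 1) / 2 * fixed$spacing
  par <- c(0, 0, 0, 0, 0, 0)
  if (!is.null(init)) par <- c(init$angles, init$translation)
  conv_ok <- TRUE
  for (lev in seq(levels, 1)) {
    f <- 2^(lev - 1)
    # anti-aliased pyramid: smoothing grows with the decimation factor
    fix_s <- smooth_volume(fixed, smooth_sigma * f)
    mov_l <- smooth_volume(moving, smooth_sigma * f)
    fix_l <- if (f > 1) resample_volume(fix_s, fixed$spacing * f) else fix_s
    pts <- voxel_centers(fix_l)
    fvals <- as.numeric(fix_l$data)
    if (length(fvals) > max_points) {
      # irregular (non-constant-stride) subsample: a constant stride can
      # alias with the lattice period of grid-phantom images
      sel <- unique(round(seq(1, length(fvals), length.out = max_points)))
      pts <- pts[sel, , drop = FALSE]
      fvals <- fvals[sel]
    }
    fn <- function(p) {
      tf <- rigid_transform(p[1:3], p[4:6], center)
      mvals <- sample_volume(mov_l, transform_points(tf, pts))
      similarity_loss(mvals, fvals, similarity)
    }
    res <- optim(par, fn, method = "L-BFGS-B",
                 control = list(maxit = max_iter,
                                ndeps = rep(1e-3, 6), factr = 1e7))
    par <- res$par
    # 52 ("abnormal termination in line search") is how L-BFGS-B reports a
    # finite-difference gradient too flat to improve on: effectively done
    if (lev == 1 && !res$convergence %in% c(0L, 1L, 52L))
      conv_ok <- FALSE
  }
  if (!conv_ok)
    warning("rigid registration did not converge; returning best found",
            call. = FALSE)
  out <- rigid_transform(par[1:3], par[4:6], center)
  attr(out, "loss") <- fn_final_loss(out, moving, fixed, similarity,
                                     max_points)
  attr(out, "converged") <- conv_ok
  out
}

fn_final_loss <- function(tf, moving, fixed, similarity, max_points) {
  pts <- voxel_centers(fixed)
  fvals <- as.numeric(fixed$data)
  sel <- unique(round(seq(1, length(fvals),
                          length.out = min(length(fvals), max_points))))
  mvals <- sample_volume(moving, transform_points(tf, pts[sel, , drop = FALSE]))
  similarity_loss(mvals, fvals[sel], similarity)
}

# ---- free-form deformation -------------------------------------------------

#' Cubic B-spline free-form deformation model settings
#'
#' @param control_spacing mm triple (scalar recycled), B-spline control grid
#'   spacing; 10 mm default.
#' @param bending_weight weight of the discrete bending-energy penalty
#'   (mean squared second difference of the control lattice per mm^2);
#'   0.01 default.
#' @param max_iterations total optimizer iteration cap across pyramid
#'   levels; 1000 default.
#' @param similarity `"ncc"` (squared global correlation; default, handles
#'   the inverted CT/MR contrast) or `"ssd"`.
#' @param levels image pyramid levels (default 2: half resolution, then
#'   full).
#' @param stride fixed-voxel subsampling stride of the similarity at the
#'   finest level.
#' @param smooth_sigma Gaussian pre-smoothing of both images (voxels)
#'   before optimization. Near-binary images make the interpolated
#'   similarity piecewise linear with kinks exactly at the zero-deformation
#'   start; a sub-voxel blur restores a usable gradient there. The
#'   returned warped image is computed from the *unsmoothed* moving image.
#' @return An object of class `ffd_model`.
#' @export
ffd_model <- function(control_spacing = c(10, 10, 10), bending_weight = 0.01,
                      max_iterations = 1000,
                      similarity = c("ncc", "ssd"), levels = 2, stride = 1,
                      smooth_sigma = 0.8) {
  control_spacing <- rep_len(as.numeric(control_spacing), 3L)
  if (any(control_spacing <= 0)) stop("control spacing must be positive",
                                      call. = FALSE)
  similarity <- match.arg(similarity)
  structure(list(control_spacing = control_spacing,
                 bending_weight = bending_weight,
                 max_iterations = max_iterations, similarity = similarity,
                 levels = levels, stride = stride,
                 smooth_sigma = smooth_sigma),
            class = "ffd_model")
}

#' Harmonize an MR-like grid image to CT-like (walls-bright) contrast
#'
#' CT and MR grid-phantom images are complementary near-binary masks
#' (bright walls versus bright gaps), a relationship global correlation
#' metrics cannot exploit. This maps an MR-like image to walls-bright
#' contrast: the bright (fluid) class is found by 2-class Otsu, its
#' morphological closing estimates the phantom support (the thin dark
#' walls are closed over), and intensities are inverted within that
#' support while the background stays at zero. Registration against CT
#' then becomes effectively monomodal.
#'
#' @param vol an MR-like `image_volume`.
#' @param fill_sigma_mm physical scale (mm) of the Gaussian support fill;
#'   must exceed half the lattice gap so the support closes over walls
#'   (default 1.5 mm suits gaps up to ~5 mm).
#' @return The harmonized `image_volume`.
#' @export
harmonize_contrast <- function(vol, fill_sigma_mm = 1.5) {
  s <- otsu_segment(vol, 2, "brightest")
  supp <- fill_support(s$mask, vol$spacing, fill_sigma_mm)
  m <- max(vol$data[supp])
  image_volume((m - vol$data) * supp, vol$spacing, vol$origin,
               vol$encoding)
}

# Scale-aware support fill: Gaussian-blur the class indicator at a physical
# scale larger than the lattice gap and keep everything above a low
# threshold — a fast, spacing-independent stand-in for morphological closing
# of sparse periodic structures.
fill_support <- function(mask, spacing, sigma_mm = 1.5) {
  d <- dim(mask)
  b <- cpp_gaussian_blur(as.numeric(mask), d, sigma_mm / min(spacing))
  array(b > 0.25, d)
}

# Erode a solid support by a physical margin: blur the indicator with
# sigma = margin/2 and keep the deep interior (Phi(2) ~ 0.977).
erode_support <- function(mask, spacing, margin_mm) {
  d <- dim(mask)
  b <- cpp_gaussian_blur(as.numeric(mask), d, margin_mm / 2 / min(spacing))
  array(b > 0.977, d)
}

smooth_volume <- function(vol, sigma) {
  if (is.null(sigma) || sigma <= 0) return(vol)
  d <- dim(vol$data)
  image_volume(array(cpp_gaussian_blur(vol$data, d, sigma), d),
               vol$spacing, vol$origin, vol$encoding)
}

#' Non-rigid registration with a cubic B-spline free-form deformation
#'
#' Optimizes a lattice of B-spline control-point displacements so that the
#' warped moving image `M(p + u(p))` matches the fixed image, under the
#' similarity of the model plus `bending_weight` times a discrete bending
#' penalty, with analytic gradients and a deterministic L-BFGS-B optimizer
#' (bit-reproducible given identical inputs). Images should be rigidly
#' pre-aligned.
#'
#' @param moving,fixed `image_volume`s; constant (degenerate) images error.
#' @param model an [ffd_model()].
#' @param mask optional logical array on the fixed grid: the similarity is
#'   evaluated only over these voxels (e.g. the phantom interior, keeping
#'   support-boundary artifacts of a harmonized moving image out of the
#'   metric).
#' @return List of class `ffd_result`: `field` (the dense
#'   [displacement_field()] at fixed-image resolution; applying it to the
#'   moving image with [apply_field()] reproduces `warped`), `warped` (the
#'   warped moving `image_volume` on the fixed grid), `value` (final loss),
#'   `model`, `converged`.
#' @export
ffd_register <- function(moving, fixed, model = ffd_model(), mask = NULL) {
  if (sd(fixed$data) == 0 || sd(moving$data) == 0)
    stop("degenerate (constant) image cannot be registered", call. = FALSE)
  cs <- model$control_spacing
  extent <- (vol_dim(fixed) - 1) * fixed$spacing
  corigin <- fixed$origin - 2 * cs
  cdim <- as.integer(floor(extent / cs)) + 7L
  coef <- numeric(prod(cdim) * 3)
  metric <- if (model$similarity == "ssd") 0L else 1L
  maxit_level <- max(10L, as.integer(ceiling(model$max_iterations /
                                             model$levels)))
  value <- NA_real_
  conv_ok <- TRUE
  fixed_s <- smooth_volume(fixed, model$smooth_sigma)
  moving_s <- smooth_volume(moving, model$smooth_sigma)
  # contrast check: the optimizer maximizes *positive* correlation, so the
  # moving intensities are flipped if the modalities are inverted (e.g. MR
  # bright gaps vs CT bright walls)
  flip_sign <- FALSE
  if (model$similarity == "ncc") {
    r0 <- suppressWarnings(stats::cor(
      sample_volume(moving_s, voxel_centers(fixed_s)),
      as.numeric(fixed_s$data)))
    flip_sign <- is.finite(r0) && r0 < 0
  }
  for (lev in seq(model$levels, 1)) {
    f <- 2^(lev - 1)
    # anti-aliased pyramid: smoothing grows with the decimation factor
    fix_s <- if (f > 1) smooth_volume(fixed, model$smooth_sigma * f)
             else fixed_s
    mov_s <- if (f > 1) smooth_volume(moving, model$smooth_sigma * f)
             else moving_s
    if (flip_sign) mov_s <- image_volume(-mov_s$data, mov_s$spacing,
                                         mov_s$origin, mov_s$encoding)
    fix_l <- if (f > 1) resample_volume(fix_s, fixed$spacing * f) else fix_s
    mov_l <- if (f > 1) resample_volume(mov_s, moving$spacing * f) else mov_s
    mask_l <- logical(0)
    if (!is.null(mask)) {
      if (f > 1) {
        mvol <- image_volume(array(as.numeric(mask), vol_dim(fixed)),
                             fixed$spacing, fixed$origin, fixed$encoding)
        mask_l <- as.numeric(resample_volume(mvol, fixed$spacing * f)$data) > 0.5
      } else mask_l <- as.logical(mask)
    }
    stride <- if (lev == 1) model$stride else 1L
    cache <- new.env(parent = emptyenv())
    evalfn <- function(p) {
      key <- c(p)
      if (!is.null(cache$par) && identical(cache$par, key)) return(cache$res)
      res <- cpp_ffd_loss(fix_l$data, dim(fix_l$data), fix_l$spacing,
                          fix_l$origin, mov_l$data, dim(mov_l$data),
                          mov_l$spacing, mov_l$origin,
                          p, cdim, corigin, cs,
                          metric, model$bending_weight, stride, 0, mask_l)
      cache$par <- key
      cache$res <- res
      res
    }
    res <- optim(coef, fn = function(p) evalfn(p)$loss,
                 gr = function(p) evalfn(p)$grad,
                 method = "L-BFGS-B",
                 control = list(maxit = maxit_level, factr = 1e7))
    coef <- res$par
    value <- res$value
    if (lev == 1 && !res$convergence %in% c(0, 1)) conv_ok <- FALSE
  }
  if (!conv_ok)
    warning("FFD registration did not converge; returning best found",
            call. = FALSE)
  d <- vol_dim(fixed)
  dense <- cpp_ffd_field(coef, cdim, corigin, cs, d, fixed$spacing,
                         fixed$origin)
  field <- displacement_field(array(dense, c(d, 3L)), fixed$spacing,
                              fixed$origin, fixed$encoding,
                              frame = "scanner", fixed_image = "fixed")
  warped_vals <- cpp_warp_pull(moving$data, dim(moving$data), moving$spacing,
                               moving$origin, d, fixed$spacing, fixed$origin,
                               field$vectors[, , , 1],
                               field$vectors[, , , 2],
                               field$vectors[, , , 3], 0)
  warped <- image_volume(array(warped_vals, d), fixed$spacing, fixed$origin,
                         moving$encoding)
  structure(list(field = field, warped = warped, value = value,
                 coefficients = coef, model = model, converged = conv_ok),
            class = "ffd_result")
}

#' @export
print.ffd_result <- function(x, ...) {
  mag <- sqrt(x$field$vectors[, , , 1]^2 + x$field$vectors[, , , 2]^2 +
              x$field$vectors[, , , 3]^2)
  cat("<ffd_result> loss ", signif(x$value, 5), ", |u| max ",
      signif(max(mag), 4), " mm, converged: ", x$converged, "\n", sep = "")
  invisible(x)
}

#' Discrete bending energy of a displacement field
#'
#' Mean squared second difference of the field components along each axis,
#' scaled by voxel spacing^-2 — the regularizer analog used by
#' [ffd_register()], evaluated on a dense field (useful to check that a
#' recovered field is no rougher than the truth it estimates).
#'
#' @param field a `displacement_field`.
#' @return A non-negative scalar (mm^2 / mm^4).
#' @export
bending_energy <- function(field) {
  d <- dim(field$vectors)[1:3]
  tot <- 0
  n <- 0
  for (c3 in 1:3) {
    a <- field$vectors[, , , c3]
    for (ax in 1:3) {
      if (d[ax] < 3) next
      i0 <- seq_len(d[ax] - 2)
      idx <- function(off) {
        ii <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
        ii[[ax]] <- i0 + off
        a[ii[[1]], ii[[2]], ii[[3]], drop = FALSE]
      }
      d2 <- (idx(0) - 2 * idx(1) + idx(2)) / field$spacing[ax]^2
      tot <- tot + sum(d2^2)
      n <- n + length(d2)
    }
  }
  tot / n
}
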