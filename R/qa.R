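#' Landmark set
#'
#' Paired physical-space points (mm) used to quantify displacement. A plain
#' `data.frame` with columns `id`, `x`, `y`, `z` plus `frame`/`source`
#' attributes; ids must be unique because landmark pairing is always by id,
#' never nearest-neighbor.
#'
#' @param points data.frame with columns `id`, `x`, `y`, `z`.
#' @param frame reference-frame label (`"scanner"` or an image id).
#' @param source one of `"truth"`, `"manual"`, `"auto"`, `"distorted"`.
#' @return A `landmark_set` (data.frame subclass).
#' @export
landmark_set <- function(points, frame = "scanner", source = "truth") {
  points <- as.data.frame(points)
  need <- c("id", "x", "y", "z")
  if (!all(need %in% names(points)))
    stop("landmarks need columns id, x, y, z", call. = FALSE)
  if (anyDuplicated(points$id))
    stop("landmark ids must be unique", call. = FALSE)
  if (any(!is.finite(as.matrix(points[, c("x", "y", "z")]))))
    stop("landmark coordinates must be finite", call. = FALSE)
  structure(points[, need], frame = frame, source = source,
            class = c("landmark_set", "data.frame"))
}

#' Read/write landmark CSV (id, x_mm, y_mm, z_mm)
#' @param path CSV path.
#' @param lms a [landmark_set()].
#' @param frame,source metadata for the read set.
#' @return A `landmark_set` (read) / `path` invisibly (write).
#' @export
read_landmarks <- function(path, frame = "scanner", source = "manual") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  names(df) <- sub("_mm$", "", names(df))
  landmark_set(df, frame = frame, source = source)
}

#' @rdname read_landmarks
#' @export
write_landmarks <- function(lms, path) {
  df <- as.data.frame(lms)
  names(df) <- c("id", "x_mm", "y_mm", "z_mm")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Per-landmark displacements between two sets
#'
#' Differences `test - ref` matched by id, with per-axis components and the
#' Euclidean distance, all in mm. Unmatched ids are excluded with a
#' warning; zero matches is an error.
#'
#' @param ref,test [landmark_set()]s.
#' @return `data.frame` with columns `id`, `dx`, `dy`, `dz`, `euclidean`.
#' @export
landmark_displacements <- function(ref, test) {
  m <- merge(as.data.frame(ref), as.data.frame(test), by = "id",
             suffixes = c("_ref", "_test"))
  n_un <- nrow(ref) + nrow(test) - 2 * nrow(m)
  if (nrow(m) == 0) stop("no matching landmark ids", call. = FALSE)
  if (n_un > 0)
    warning(n_un, " unmatched landmark(s) excluded", call. = FALSE)
  out <- data.frame(id = m$id,
                    dx = m$x_test - m$x_ref,
                    dy = m$y_test - m$y_ref,
                    dz = m$z_test - m$z_ref)
  out$euclidean <- sqrt(out$dx^2 + out$dy^2 + out$dz^2)
  out[order(out$id), , drop = FALSE]
}

#' Detect grid-phantom lattice intersections with sub-voxel precision
#'
#' Automated stand-in for manual landmark placement: cross-correlates the
#' image with a small synthetic intersection template (three orthogonal
#' wall planes, rendered at the image spacing with the same one-voxel
#' antialiasing as the digital phantom), finds correlation peaks at least
#' half a pitch apart, and refines each to sub-voxel precision by separable
#' three-point quadratic fitting. Template polarity (bright walls for
#' CT-like, dark walls for MR-like contrast) is chosen automatically from
#' the dominant correlation sign. Ids encode the nearest lattice index, so
#' detections pair with the analytic truth landmarks of
#' [build_phantom_pair()] by id even on distorted images (valid while
#' displacements stay below half a pitch).
#'
#' @param vol an `image_volume` containing a grid-phantom image.
#' @param geom the [phantom_geometry()] (provides pitch and wall thickness).
#' @param min_peak detection threshold as a fraction of the strongest
#'   correlation peak.
#' @param modality `"auto"`, `"walls_bright"` or `"walls_dark"`.
#' @param template_frac template half-size as a fraction of the pitch;
#'   the default 0.42 keeps the window of the outermost lattice layer
#'   inside the phantom, which would otherwise bias those peaks.
#' @return A [landmark_set()] (source `"auto"`). Fewer than 8 detections is
#'   an error (no lattice present).
#' @export
detect_grid_landmarks <- function(vol, geom, min_peak = 0.5,
                                  modality = c("auto", "walls_bright",
                                               "walls_dark"),
                                  template_frac = 0.42) {
  modality <- match.arg(modality)
  if (sd(vol$data) == 0)
    stop("constant image: no grid structure to detect", call. = FALSE)
  sp <- vol$spacing
  h <- pmax(2L, as.integer(floor(template_frac * geom$pitch / sp)))
  tco <- lapply(1:3, function(a) (seq(-h[a], h[a])) * sp[a])
  half_w <- geom$wall_thickness / 2
  tpl1 <- lapply(1:3, function(a)
    pmin(1, pmax(0, (half_w + sp[a] / 2 - abs(tco[[a]])) / sp[a])))
  td <- 2L * h + 1L
  ax <- array(tpl1[[1]], td)
  ay <- array(rep(tpl1[[2]], each = td[1]), td)
  az <- array(rep(tpl1[[3]], each = td[1] * td[2]), td)
  tpl <- 1 - (1 - ax) * (1 - ay) * (1 - az)
  tpl <- tpl - mean(tpl)

  # FFT cross-correlation (template is symmetric under reflection)
  d <- dim(vol$data)
  pad <- d + td
  big_img <- array(0, pad)
  big_img[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- vol$data
  big_tpl <- array(0, pad)
  big_tpl[seq_len(td[1]), seq_len(td[2]), seq_len(td[3])] <- tpl
  cc <- Re(fft(fft(big_img) * Conj(fft(big_tpl)), inverse = TRUE)) /
    prod(pad)
  # re-index so cc[v] is the correlation of the template centered at voxel v
  ix <- lapply(1:3, function(a) ((seq_len(d[a]) - 1 - h[a]) %% pad[a]) + 1L)
  cc <- cc[ix[[1]], ix[[2]], ix[[3]]]

  if (modality == "auto") {
    flip <- max(-cc) > max(cc)
  } else flip <- modality == "walls_dark"
  if (flip) cc <- -cc

  # candidate peaks: above threshold and maximal in their neighborhood
  thr <- min_peak * max(cc)
  cand <- which(cc >= thr)
  if (length(cand) == 0) stop("no lattice intersections detected",
                              call. = FALSE)
  idx <- arrayInd(cand, d)
  r <- pmax(1L, as.integer(round(geom$pitch / (2 * sp))))
  vals <- cc[cand]
  ord <- order(vals, decreasing = TRUE)
  taken <- matrix(NA_real_, 0, 3)
  peaks <- integer(0)
  for (ii in ord) {
    v <- idx[ii, ]
    if (nrow(taken) > 0) {
      dd <- abs(sweep(taken, 2, v))
      if (any(dd[, 1] <= r[1] & dd[, 2] <= r[2] & dd[, 3] <= r[3])) next
    }
    # local maximum check against 26-neighborhood
    lo <- pmax(v - 1L, 1L); hi <- pmin(v + 1L, d)
    nb <- cc[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
    if (cc[v[1], v[2], v[3]] < max(nb)) next
    taken <- rbind(taken, v)
    peaks <- c(peaks, cand[ii])
  }
  if (length(peaks) < 8)
    stop("fewer than 8 lattice intersections detected (", length(peaks),
         ")", call. = FALSE)

  pk <- arrayInd(peaks, d)
  # separable 3-point quadratic refinement
  offs <- matrix(0, nrow(pk), 3)
  for (a in 1:3) {
    ok <- pk[, a] > 1 & pk[, a] < d[a]
    for (ii in which(ok)) {
      v <- pk[ii, ]
      vm <- v; vm[a] <- v[a] - 1L
      vp <- v; vp[a] <- v[a] + 1L
      y0 <- cc[vm[1], vm[2], vm[3]]
      y1 <- cc[v[1], v[2], v[3]]
      y2 <- cc[vp[1], vp[2], vp[3]]
      den <- y0 - 2 * y1 + y2
      if (den < 0) offs[ii, a] <- 0.5 * (y0 - y2) / den
    }
  }
  pos <- sweep((pk - 1 + offs) %*% diag(sp), 2, vol$origin, "+")
  lat <- round(pos %*% diag(1 / rep(geom$pitch, 3)))
  ids <- sprintf("L%d_%d_%d", lat[, 1], lat[, 2], lat[, 3])
  keep <- !duplicated(ids)
  landmark_set(data.frame(id = ids[keep], x = pos[keep, 1],
                          y = pos[keep, 2], z = pos[keep, 3],
                          stringsAsFactors = FALSE),
               frame = "scanner", source = "auto")
}

# ---- segmentation ----------------------------------------------------------

#' Multi-level Otsu segmentation
#'
#' Exhaustive between-class-variance maximization over a 256-bin histogram.
#' `n_classes = 3` (two thresholds) matches segmenting background / walls /
#' fluid in grid-phantom images; which class forms the mask is a per-
#' modality choice (`keep_class`).
#'
#' @param vol an `image_volume` (constant images error).
#' @param n_classes 2 or 3.
#' @param keep_class `"brightest"`, `"middle"`, `"darkest"` or a class
#'   index (1 = darkest).
#' @param n_bins histogram resolution.
#' @return An object of class `segmentation_mask`: logical `mask` array plus
#'   geometry and a `provenance` record of the thresholds found.
#' @export
otsu_segment <- function(vol, n_classes = 3, keep_class = "brightest",
                         n_bins = 256) {
  x <- as.numeric(vol$data)
  rng <- range(x)
  if (rng[1] == rng[2]) stop("constant image cannot be thresholded",
                             call. = FALSE)
  br <- seq(rng[1], rng[2], length.out = n_bins + 1)
  hcount <- tabulate(pmin(n_bins, pmax(1L,
    findInterval(x, br, all.inside = TRUE))), n_bins)
  mids <- (br[-1] + br[-length(br)]) / 2
  w <- cumsum(hcount)
  m <- cumsum(hcount * mids)
  csum2 <- function(i, j) {  # between-class weight/mean of bins (i, j]
    wt <- w[j] - if (i > 0) w[i] else 0
    mu <- m[j] - if (i > 0) m[i] else 0
    c(wt, mu)
  }
  best <- -Inf
  if (n_classes == 2) {
    th <- NA
    for (t1 in 1:(n_bins - 1)) {
      a <- csum2(0, t1); b <- csum2(t1, n_bins)
      if (a[1] == 0 || b[1] == 0) next
      v <- a[2]^2 / a[1] + b[2]^2 / b[1]
      if (v > best) { best <- v; th <- t1 }
    }
    thr <- br[th + 1]
    cls <- 1L + (x > thr)
    thresholds <- thr
  } else if (n_classes == 3) {
    th <- c(NA, NA)
    for (t1 in 1:(n_bins - 2)) {
      a <- csum2(0, t1)
      if (a[1] == 0) next
      va <- a[2]^2 / a[1]
      for (t2 in (t1 + 1):(n_bins - 1)) {
        b <- csum2(t1, t2); cc <- csum2(t2, n_bins)
        if (b[1] == 0 || cc[1] == 0) next
        v <- va + b[2]^2 / b[1] + cc[2]^2 / cc[1]
        if (v > best) { best <- v; th <- c(t1, t2) }
      }
    }
    thresholds <- br[th + 1]
    cls <- 1L + (x > thresholds[1]) + (x > thresholds[2])
  } else stop("n_classes must be 2 or 3", call. = FALSE)

  pick <- if (is.numeric(keep_class)) as.integer(keep_class)
          else switch(keep_class, darkest = 1L,
                      middle = 2L, brightest = n_classes,
                      stop("unknown keep_class", call. = FALSE))
  mask <- array(cls == pick, dim(vol$data))
  structure(list(mask = mask, spacing = vol$spacing, origin = vol$origin,
                 provenance = list(method = "otsu", n_classes = n_classes,
                                   thresholds = thresholds,
                                   keep_class = keep_class)),
            class = "segmentation_mask")
}

#' @export
print.segmentation_mask <- function(x, ...) {
  cat("<segmentation_mask> ", sum(x$mask), "/", length(x$mask),
      " voxels; ", x$provenance$method,
      " thresholds: ", paste(signif(x$provenance$thresholds, 5),
                             collapse = ", "), "\n", sep = "")
  invisible(x)
}

ball_offsets <- function(radius) {
  if (radius <= 0) return(matrix(0L, 1, 3))
  r <- as.integer(radius)
  g <- as.matrix(expand.grid(x = -r:r, y = -r:r, z = -r:r))
  g[rowSums(g^2) <= radius^2 + 1e-9, , drop = FALSE]
}

shift_mask <- function(m, off, fill = FALSE) {
  d <- dim(m)
  out <- array(fill, d)
  src <- lapply(1:3, function(a) {
    i <- seq_len(d[a]) - off[a]
    i[i >= 1 & i <= d[a]]
  })
  dst <- lapply(1:3, function(a) {
    i <- seq_len(d[a])
    i[i - off[a] >= 1 & i - off[a] <= d[a]]
  })
  if (all(lengths(src) > 0))
    out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
  out
}

binary_dilate <- function(m, radius) {
  if (radius <= 0) return(m)
  offs <- ball_offsets(radius)
  out <- m
  for (i in seq_len(nrow(offs))) {
    if (all(offs[i, ] == 0)) next
    out <- out | shift_mask(m, offs[i, ], FALSE)
  }
  out
}

binary_erode <- function(m, radius) {
  if (radius <= 0) return(m)
  offs <- ball_offsets(radius)
  out <- m
  for (i in seq_len(nrow(offs))) {
    if (all(offs[i, ] == 0)) next
    out <- out & shift_mask(m, offs[i, ], TRUE)
  }
  out
}

#' Morphological cleanup of a segmentation
#'
#' Binary closing (dilation then erosion) followed by dilation, both with a
#' 3D ball structuring element (all integer offsets within the radius).
#' Radius 0 disables an operation; `(0, 0)` is the identity. Closing fills
#' small holes the thresholding leaves in thin walls; out-of-volume
#' neighbors count as background for dilation and as foreground for the
#' closing's erosion step, so structures touching the border are not eaten.
#'
#' @param mask a `segmentation_mask` or logical array.
#' @param closing_radius,dilation_radius non-negative integers (voxels).
#' @return Same type as the input, with provenance extended.
#' @export
morph_cleanup <- function(mask, closing_radius = 1, dilation_radius = 1) {
  if (closing_radius < 0 || dilation_radius < 0)
    stop("radii must be >= 0", call. = FALSE)
  is_obj <- inherits(mask, "segmentation_mask")
  m <- if (is_obj) mask$mask else mask
  if (closing_radius > 0)
    m <- binary_erode(binary_dilate(m, closing_radius), closing_radius)
  m <- binary_dilate(m, dilation_radius)
  if (is_obj) {
    mask$mask <- m
    mask$provenance$morphology <- list(closing_radius = closing_radius,
                                       dilation_radius = dilation_radius,
                                       element = "ball")
    mask
  } else m
}

#' Dice similarity coefficient
#'
#' `DSC = 2 |X intersect Y| / (|X| + |Y|)`, in \[0, 1\], symmetric, 1 iff
#' identical non-empty masks. Two empty masks are an error (0/0), not 0.
#'
#' @param a,b `segmentation_mask`s or logical arrays of equal dimensions.
#' @return The Dice coefficient.
#' @export
dice <- function(a, b) {
  ma <- if (inherits(a, "segmentation_mask")) a$mask else a
  mb <- if (inherits(b, "segmentation_mask")) b$mask else b
  if (!identical(dim(ma), dim(mb)))
    stop("masks have different dimensions", call. = FALSE)
  na <- sum(ma); nb <- sum(mb)
  if (na + nb == 0) stop("both masks are empty: Dice undefined",
                         call. = FALSE)
  2 * sum(ma & mb) / (na + nb)
}

#' Assemble a QA report from stage statistics and Dice values
#'
#' @param stats `data.frame` of per-stage displacement statistics (rows from
#'   [summarize_displacements()] with a `stage` and/or `region` column).
#' @param dice_values named numeric vector of Dice coefficients per stage.
#' @param threshold the mm accuracy threshold the fractions refer to.
#' @param file optional path: writes the machine-readable JSON there.
#' @return An object of class `qa_report` (list with `stats`, `dice`,
#'   `threshold`); its print method renders a Markdown table.
#' @export
qa_report <- function(stats, dice_values = NULL, threshold = 0.2,
                      file = NULL) {
  if (is.null(stats) || nrow(stats) == 0) stop("empty stats", call. = FALSE)
  rep <- structure(list(stats = stats, dice = dice_values,
                        threshold = threshold),
                   class = "qa_report")
  if (!is.null(file)) {
    jsonlite::write_json(list(threshold_mm = threshold, stats = stats,
                              dice = as.list(dice_values)),
                         file, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  rep
}

#' @export
print.qa_report <- function(x, ...) {
  cat("QA report (threshold ", x$threshold, " mm)\n\n", sep = "")
  df <- x$stats
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v) signif(v, 4))
  cat("| ", paste(names(df), collapse = " | "), " |\n", sep = "")
  cat("|", paste(rep("---", ncol(df)), collapse = "|"), "|\n", sep = "")
  for (i in seq_len(nrow(df)))
    cat("| ", paste(unlist(df[i, ]), collapse = " | "), " |\n", sep = "")
  if (!is.null(x$dice)) {
    cat("\nDice: ", paste(names(x$dice), signif(x$dice, 3), sep = " = ",
                          collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
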