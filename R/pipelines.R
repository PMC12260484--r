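#' Pipeline configuration
#'
#' Shared knobs of the correction pipelines. Defaults follow the QA
#' protocol the package models: 0.2 mm accuracy threshold, 10 mm B-spline
#' control spacing with bending weight 0.01, evaluation against CT at the
#' CT grid.
#'
#' @param threshold accuracy threshold, mm (> 0).
#' @param seed integer recorded in provenance (pipelines themselves are
#'   deterministic; the seed drives any synthetic inputs built by the
#'   caller).
#' @param ffd an [ffd_model()].
#' @param rigid_levels pyramid levels for rigid registration.
#' @param working_spacing mm: registrations run on copies resampled to this
#'   spacing (NULL = native resolution); estimated transforms/fields are
#'   applied at native resolution.
#' @param crop_margin mm margin kept when cropping CT to the MR extent.
#' @param map_spacing mm spacing at which the phantom displacement map is
#'   saved (NULL = fixed-image spacing).
#' @param closing_radius,dilation_radius morphology radii (voxels) for the
#'   segmentation cleanup before Dice.
#' @param keep_class_ct,keep_class_mr Otsu class forming the wall mask per
#'   modality (walls are brightest on CT, darkest on MR).
#' @param harmonize apply [harmonize_contrast()] to MR-like moving images
#'   before registering them to CT (recommended: makes the multimodal
#'   problem effectively monomodal for correlation metrics).
#' @param mask_erode_mm restrict the FFD similarity to the fixed (CT)
#'   phantom support eroded by this physical margin (mm), keeping
#'   support-boundary artifacts of harmonized images out of the metric;
#'   `NULL` disables masking.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(threshold = 0.2, seed = 1L, ffd = ffd_model(),
                            rigid_levels = 3, working_spacing = NULL,
                            crop_margin = 1, map_spacing = NULL,
                            closing_radius = 1, dilation_radius = 1,
                            keep_class_ct = "brightest",
                            keep_class_mr = "darkest", harmonize = TRUE,
                            mask_erode_mm = 0.8) {
  if (!is.numeric(threshold) || threshold <= 0)
    stop("threshold must be > 0", call. = FALSE)
  structure(list(threshold = threshold, seed = as.integer(seed), ffd = ffd,
                 rigid_levels = rigid_levels,
                 working_spacing = working_spacing,
                 crop_margin = crop_margin, map_spacing = map_spacing,
                 closing_radius = closing_radius,
                 dilation_radius = dilation_radius,
                 keep_class_ct = keep_class_ct,
                 keep_class_mr = keep_class_mr, harmonize = harmonize,
                 mask_erode_mm = mask_erode_mm),
            class = "pipeline_config")
}

crop_to_extent <- function(ct, mr, margin) {
  d <- vol_dim(mr)
  center <- mr$origin + (d - 1) / 2 * mr$spacing
  extent <- (d - 1) * mr$spacing + 2 * margin
  crop_volume(ct, center, extent)
}

maybe_harmonize <- function(vol, cfg) {
  if (isTRUE(cfg$harmonize)) harmonize_contrast(vol) else vol
}

# Interior mask of the fixed (CT-like) image for masked FFD similarity:
# morphological closing of the bright wall class, eroded by a physical margin.
registration_mask <- function(fixed, erode_mm) {
  if (is.null(erode_mm)) return(NULL)
  s <- otsu_segment(fixed, 2, "brightest")
  supp <- gridwarp_fill_support(s$mask, fixed$spacing)
  erode_support(supp, fixed$spacing, erode_mm)
}

gridwarp_fill_support <- function(mask, spacing) fill_support(mask, spacing)

maybe_downsample <- function(vol, spacing) {
  if (is.null(spacing)) return(vol)
  if (max(abs(rep_len(spacing, 3) - vol$spacing)) < 1e-9) return(vol)
  resample_volume(vol, spacing)
}

# Dice of the wall masks of an MR-like and CT-like image pair, restricted to
# a region mask (typically VOI3: inside the phantom, where background does
# not contaminate the darkest MR class).
stage_dice <- function(mr_img, ct_img, region_mask, cfg) {
  sm <- otsu_segment(mr_img, 3, cfg$keep_class_mr)
  sc <- otsu_segment(ct_img, 3, cfg$keep_class_ct)
  sm <- morph_cleanup(sm, cfg$closing_radius, cfg$dilation_radius)
  sc <- morph_cleanup(sc, cfg$closing_radius, cfg$dilation_radius)
  dice(sm$mask & region_mask, sc$mask & region_mask)
}

new_correction_result <- function(pipeline, stages, field = NULL,
                                  transform = NULL, stats = NULL,
                                  dice = NULL, cfg = NULL, extra = list()) {
  structure(c(list(pipeline = pipeline, stages = stages, field = field,
                   transform = transform, stats = stats, dice = dice,
                   provenance = c(list(
                     pipeline = pipeline,
                     stage_order = names(stages),
                     package = "gridwarp",
                     version = as.character(utils::packageVersion("gridwarp")),
                     seed = cfg$seed,
                     threshold_mm = cfg$threshold,
                     ffd = unclass(cfg$ffd),
                     working_spacing = cfg$working_spacing), extra)),
              list()),
            class = "correction_result")
}

#' @export
print.correction_result <- function(x, ...) {
  cat("<correction_result> ", x$pipeline, " | stages: ",
      paste(names(x$stages), collapse = " -> "), "\n", sep = "")
  if (!is.null(x$stats)) print(x$stats)
  if (!is.null(x$dice))
    cat("Dice: ", paste(names(x$dice), signif(x$dice, 3), sep = " = ",
                        collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' One-step distortion correction (1SDC)
#'
#' Corrects B0 and GNL distortion simultaneously by non-rigid registration
#' of the MR image to the (undistorted, reference) CT: crop CT to the MR
#' extent, rigid-register MR to CT, then B-spline FFD registration. Fast,
#' but the deformation does not distinguish the two distortion sources.
#'
#' @param mr,ct `image_volume`s (CT is the fixed reference).
#' @param cfg a [pipeline_config()].
#' @param geom optional [phantom_geometry()]: enables landmark-based stage
#'   statistics via [detect_grid_landmarks()].
#' @param landmarks optional truth [landmark_set()] in the CT frame.
#' @param region optional [voi()] (or logical mask on the cropped-CT grid)
#'   restricting the Dice evaluation; default VOI3 of [standard_vois()].
#' @return A `correction_result` with stages `rigid` and `corrected`, the
#'   estimated [displacement_field()], per-stage stats and Dice.
#' @export
run_1sdc <- function(mr, ct, cfg = pipeline_config(), geom = NULL,
                     landmarks = NULL, region = NULL) {
  if (!inherits(mr, "image_volume") || !inherits(ct, "image_volume"))
    stop("configuration error: mr and ct must be image_volume objects",
         call. = FALSE)
  ctc <- crop_to_extent(ct, mr, cfg$crop_margin)
  mr_w <- maybe_downsample(mr, cfg$working_spacing)
  ct_w <- maybe_downsample(ctc, cfg$working_spacing)
  tf <- rigid_register(maybe_harmonize(mr_w, cfg), ct_w,
                       levels = cfg$rigid_levels)
  mr_rigid <- apply_rigid(mr, tf, ctc)
  ffd <- ffd_register(
    maybe_harmonize(maybe_downsample(mr_rigid, cfg$working_spacing), cfg),
    ct_w, cfg$ffd, mask = registration_mask(ct_w, cfg$mask_erode_mm))
  field <- resample_field(ffd$field, geometry = ctc)
  field$fixed_image <- "ct"
  # compose field + rigid and sample the original MR once
  corrected <- compose_warp(mr, ctc, list(field, tf))
  stages <- list(rigid = mr_rigid, corrected = corrected)
  ev <- evaluate_stages(stages, ctc, geom, landmarks, region, cfg)
  new_correction_result("1SDC", stages, field = field, transform = tf,
                        stats = ev$stats, dice = ev$dice, cfg = cfg)
}

#' Two-step distortion correction on the phantom (2SDC)
#'
#' Step 1 converts the acquired field map into a B0 spatial map and unwarps
#' the MR image along the readout axis; step 2 removes the residual
#' (GNL-dominated) distortion by rigid + FFD registration to CT. The dense
#' FFD field is the reusable "phantom displacement map" of GNL
#' displacements; the GNL field is only ever estimated *after* B0
#' correction.
#'
#' @param mr the distorted MR `image_volume`.
#' @param field the acquired [field_map()] (Hz) on (or resampled to) the MR
#'   grid.
#' @param ct reference CT `image_volume`.
#' @param grad a [gradient_spec()].
#' @inheritParams run_1sdc
#' @return A `correction_result` with stages `rigid` (uncorrected,
#'   rigid-only), `b0` (after readout unwarping + rigid) and `corrected`
#'   (after FFD); `field` holds the phantom displacement map (at
#'   `cfg$map_spacing`), `b0_map` the B0 spatial map.
#' @export
run_2sdc_phantom <- function(mr, field, ct, grad, cfg = pipeline_config(),
                             geom = NULL, landmarks = NULL, region = NULL) {
  if (!inherits(field, "field_map"))
    stop("`field` must be a field_map with a unit", call. = FALSE)
  if (!same_geometry(field, mr)) {
    vals <- sample_volume(field, voxel_centers(mr))
    field <- field_map(array(vals, vol_dim(mr)), mr$spacing, mr$origin,
                       mr$encoding, unit = field$unit)
  }
  b0map <- b0_displacement_map(field, grad)
  mr_b0 <- apply_b0_correction(mr, b0map)
  ctc <- crop_to_extent(ct, mr, cfg$crop_margin)
  ct_w <- maybe_downsample(ctc, cfg$working_spacing)

  tf0 <- rigid_register(
    maybe_harmonize(maybe_downsample(mr, cfg$working_spacing), cfg), ct_w,
    levels = cfg$rigid_levels)
  mr_rigid <- apply_rigid(mr, tf0, ctc)
  tf <- rigid_register(
    maybe_harmonize(maybe_downsample(mr_b0, cfg$working_spacing), cfg),
    ct_w, levels = cfg$rigid_levels)
  mr_b0_rigid <- apply_rigid(mr_b0, tf, ctc)
  ffd <- ffd_register(
    maybe_harmonize(maybe_downsample(mr_b0_rigid, cfg$working_spacing), cfg),
    ct_w, cfg$ffd, mask = registration_mask(ct_w, cfg$mask_erode_mm))
  field_full <- resample_field(ffd$field, geometry = ctc)
  field_full$fixed_image <- "ct"
  saved_map <- if (is.null(cfg$map_spacing)) field_full
               else resample_field(field_full, cfg$map_spacing)
  # stage images: compose all steps, sample the original MR once each
  stage_b0 <- compose_warp(mr, ctc, list(tf, b0map))
  corrected <- compose_warp(mr, ctc, list(field_full, tf, b0map))
  stages <- list(rigid = mr_rigid, b0 = stage_b0, corrected = corrected)
  ev <- evaluate_stages(stages, ctc, geom, landmarks, region, cfg)
  out <- new_correction_result("2SDC-phantom", stages, field = saved_map,
                               transform = tf, stats = ev$stats,
                               dice = ev$dice, cfg = cfg,
                               extra = list(map_frame = saved_map$frame,
                                            map_fixed = saved_map$fixed_image))
  out$b0_map <- b0map
  out
}

#' Two-step correction of a subject image with a phantom GNL map
#'
#' The in vivo variant of 2SDC: the subject's own field map corrects B0;
#' GNL — being sequence-independent — is corrected by applying the
#' displacement map measured once on the grid phantom. Steps: upsample the
#' subject field map to the MR grid, unwarp along the readout axis,
#' resample the phantom displacement map onto the MR grid and apply it,
#' then downsample to CT resolution and rigid-register to CT for
#' evaluation.
#'
#' @param mr subject MR `image_volume`.
#' @param subject_field the subject's [field_map()] (Hz), any resolution.
#' @param phantom_field the phantom-derived [displacement_field()]; its
#'   `frame` must be `"scanner"` (a map left in a registration's native
#'   frame errors rather than being silently misapplied).
#' @param ct subject CT `image_volume`.
#' @param grad a [gradient_spec()].
#' @inheritParams run_1sdc
#' @return A `correction_result` with stages `b0` and `corrected` (both
#'   rigid-registered to CT at CT resolution).
#' @export
run_2sdc_subject <- function(mr, subject_field, phantom_field, ct, grad,
                             cfg = pipeline_config(), geom = NULL,
                             landmarks = NULL, region = NULL) {
  if (!inherits(phantom_field, "displacement_field"))
    stop("`phantom_field` must be a displacement_field", call. = FALSE)
  if (!identical(phantom_field$frame, "scanner"))
    stop("phantom displacement map frame is '", phantom_field$frame,
         "', not 'scanner': resolve the frame before applying it",
         call. = FALSE)
  if (!inherits(subject_field, "field_map"))
    stop("`subject_field` must be a field_map with a unit", call. = FALSE)
  if (!same_geometry(subject_field, mr)) {
    vals <- sample_volume(subject_field, voxel_centers(mr))
    subject_field <- field_map(array(vals, vol_dim(mr)), mr$spacing,
                               mr$origin, mr$encoding,
                               unit = subject_field$unit)
  }
  b0map <- b0_displacement_map(subject_field, grad)
  mr_b0 <- apply_b0_correction(mr, b0map)
  pf <- resample_field(phantom_field, geometry = mr_b0)
  mr_gnl <- apply_field(mr_b0, pf)

  ctc <- crop_to_extent(ct, mr, cfg$crop_margin)
  mr_b0_ct <- resample_onto(mr_b0, ctc)
  mr_gnl_ct <- resample_onto(mr_gnl, ctc)
  tf1 <- rigid_register(maybe_harmonize(mr_b0_ct, cfg), ctc,
                        levels = cfg$rigid_levels)
  tf2 <- rigid_register(maybe_harmonize(mr_gnl_ct, cfg), ctc,
                        levels = cfg$rigid_levels)
  stages <- list(b0 = compose_warp(mr, ctc, list(tf1, b0map)),
                 corrected = compose_warp(mr, ctc, list(tf2, pf, b0map)))
  ev <- evaluate_stages(stages, ctc, geom, landmarks, region, cfg)
  new_correction_result("2SDC-subject", stages, field = phantom_field,
                        transform = tf2, stats = ev$stats, dice = ev$dice,
                        cfg = cfg)
}

resample_onto <- function(vol, geometry, background = 0) {
  vals <- cpp_warp_pull(vol$data, dim(vol$data), vol$spacing, vol$origin,
                        vol_dim(geometry), geometry$spacing,
                        geometry$origin, 0, 0, 0, background)
  image_volume(array(vals, vol_dim(geometry)), geometry$spacing,
               geometry$origin, vol$encoding)
}

evaluate_stages <- function(stages, ct, geom, landmarks, region, cfg) {
  stats <- NULL
  dice_v <- NULL
  if (!is.null(geom) && !is.null(landmarks)) {
    rows <- lapply(names(stages), function(nm) {
      det <- detect_grid_landmarks(stages[[nm]], geom)
      disp <- suppressWarnings(landmark_displacements(landmarks, det))
      cbind(stage = nm, summarize_displacements(disp$euclidean,
                                                cfg$threshold))
    })
    stats <- do.call(rbind, rows)
    rownames(stats) <- NULL
  }
  if (!is.null(region)) {
    rmask <- if (inherits(region, "voi")) voi_voxel_mask(region, ct)
             else region
    dice_v <- vapply(stages, function(img) stage_dice(img, ct, rmask, cfg),
                     numeric(1))
  }
  list(stats = stats, dice = dice_v)
}

#' Shim-scenario displacement study over nested VOIs
#'
#' For each shimming scenario (a residual off-resonance field), computes
#' the B0 displacement map and its statistics in VOI1, VOI2-VOI1 and
#' VOI3-VOI2 — displacement growing with distance from the VOI center and
#' isocenter is the expected signature.
#'
#' @param scenarios named list of [field_map()]s or [shim_config()]s.
#' @param geometry `image_volume` grid on which configs are rendered.
#' @param grad a [gradient_spec()].
#' @param vois list of three nested [voi()]s (default [standard_vois()]).
#' @param threshold mm accuracy threshold.
#' @return An object of class `shim_study`: `stats` (data.frame scenario x
#'   region) and `values` (per scenario x region |displacement| vectors,
#'   for histograms).
#' @export
run_shim_study <- function(scenarios, geometry, grad,
                           vois = standard_vois(), threshold = 0.2) {
  if (length(vois) < 1) stop("at least one VOI required", call. = FALSE)
  masks <- nested_voi_masks(vois, geometry)
  rows <- list()
  values <- list()
  for (nm in names(scenarios)) {
    sc <- scenarios[[nm]]
    fm <- if (inherits(sc, "shim_config")) make_shim_field(sc, geometry)
          else sc
    b0 <- b0_displacement_map(fm, grad)
    st <- voi_displacement_stats(b0, masks, threshold)
    rows[[nm]] <- cbind(scenario = nm, st)
    values[[nm]] <- lapply(masks, function(m) abs(b0$displacement[m]))
  }
  stats <- do.call(rbind, rows)
  rownames(stats) <- NULL
  structure(list(stats = stats, values = values, threshold = threshold),
            class = "shim_study")
}

#' @export
print.shim_study <- function(x, ...) {
  cat("<shim_study> threshold ", x$threshold, " mm\n", sep = "")
  df <- x$stats
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v) signif(v, 3))
  print(df)
  invisible(x)
}
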