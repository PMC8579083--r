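# End-to-end orchestration: normalize -> mask/crop -> resample -> detect ->
# refine -> quantify -> (register -> match -> assess).

#' Pipeline configuration
#'
#' @param profile `"full"` (192^3 detection cube, 512 px refinement
#'   patches) or `"tiny"` (64^3 cube, 128 px patches, for desk-scale runs).
#' @param ... overrides for individual fields.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(profile = c("tiny", "full"), ...) {
  profile <- match.arg(profile)
  cfg <- list(profile = profile,
              resample_size = if (profile == "full") 192L else 64L,
              patch_size = if (profile == "full") 512L else 128L,
              crop_margin = 2L,
              detect_threshold = 0.5,
              min_voxels = 2L,
              patch_margin = 0.25,
              box_margin = 1L,
              gm_reference = "auto",
              reg_levels = c(4L, 2L, 1L),
              reg_max_iter = c(150L, 150L, 60L),
              reg_polish = FALSE,
              match_tolerance_mm = 5,
              min_diameter_mm = 5,
              max_targets = 5L)
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %%
               2147483000) + 1L
}

# shared preprocessing: brain mask, normalization, crop, detection cube
preprocess_case <- function(vol, config, gm_reference = NULL) {
  mask <- extract_brain_mask(vol)
  gm <- if (is.null(gm_reference)) config$gm_reference else gm_reference
  norm <- normalize_intensity(vol, gm, background_mask = mask$data == 0L)
  crop <- crop_to_brain(norm, mask, config$crop_margin)
  cube <- resample_isotropic_cube(crop$volume, config$resample_size)
  list(mask = mask, norm = norm, crop = crop, cube = cube)
}

# map truth/native labels into the detection cube (binary, nearest)
labels_to_cube <- function(labels, box, record) {
  cropped <- label_map(box_slice(labels$data, box), labels$spacing,
                       labels$origin + box$min * labels$spacing)
  scale <- record$out_spacing / record$in_spacing
  shift <- (0.5 - record$offset_vox) * scale - 0.5
  A <- cbind(diag(scale), shift)
  res <- cpp_resample_affine(as.numeric(cropped$data), dim(cropped$data), A,
                             rep(record$size, 3L), TRUE, 0)
  array(as.integer(round(res)), rep(record$size, 3L))
}

#' Segment one volume with the coarse-to-fine pipeline
#'
#' Runs brain masking, gray-matter normalization, cropping, isotropic-cube
#' resampling, coarse 3D detection, per-lesion 2D refinement and
#' quantification.  With `oracle_labels`, ground-truth masks are injected
#' in place of both models' predictions (plumbing check mode).
#'
#' @param vol a [volume3d()] (or path to a NIfTI file).
#' @param detector,refiner trained segmenters (ignored in oracle mode).
#' @param config a [pipeline_config()].
#' @param oracle_labels optional truth [label_map()]; when supplied the
#'   models are bypassed.
#' @param gm_reference optional known gray-matter intensity.
#' @return A list with the final `labels` ([label_map()], native grid),
#'   `records` (lesion table), and intermediates (`mask`, `norm`, `crop`,
#'   `cube`, `detection`).
#' @export
segment_volume <- function(vol, detector = NULL, refiner = NULL,
                           config = pipeline_config(),
                           oracle_labels = NULL, gm_reference = NULL) {
  if (is.character(vol)) vol <- read_volume(vol)
  oracle <- !is.null(oracle_labels)
  if (!oracle && (is.null(detector) || is.null(refiner)))
    stop("no trained detector/refiner supplied and oracle mode not enabled")
  pp <- preprocess_case(vol, config, gm_reference)
  det_model <- if (oracle) {
    prob <- labels_to_cube(oracle_labels, pp$crop$box, pp$cube$record)
    oracle_segmenter(array(as.numeric(prob > 0), dim(prob)))
  } else detector
  det_cube <- detect_lesions(pp$cube$volume, det_model,
                             config$detect_threshold, config$min_voxels)
  det_crop <- cube_to_native(det_cube, pp$cube$record)
  dims <- dim(vol$data)
  det_native <- label_map(uncrop_array(det_crop$data, pp$crop$box, dims),
                          vol$spacing, vol$origin)
  boxes <- extract_bounding_boxes(det_native, config$box_margin)
  norm_native <- volume3d(pp$norm$data, vol$spacing, vol$origin)
  masks <- list(array(FALSE, dims))
  truth_bin <- if (oracle)
    volume3d(array(as.numeric(oracle_labels$data > 0), dims), vol$spacing,
             vol$origin)
  for (box in boxes) {
    patches <- crop_and_upsample(norm_native, box, config$patch_size,
                                 config$patch_margin)
    ref_model <- if (oracle) {
      lp <- crop_and_upsample(truth_bin, box, config$patch_size,
                              config$patch_margin, nearest = TRUE)
      oracle_segmenter(lp$patches)
    } else refiner
    masks[[length(masks) + 1L]] <- refine_lesion(patches, ref_model,
                                                 config$detect_threshold)
  }
  asm <- assemble_lesion_map(masks, vol$spacing, vol$origin,
                             config$min_voxels)
  list(labels = asm$labels, records = asm$records, mask = pp$mask,
       norm = pp$norm, crop = pp$crop, cube = pp$cube,
       detection = det_native)
}

#' Run the full longitudinal pipeline on a study pair
#'
#' Segments baseline and follow-up, registers the follow-up to the
#' baseline, matches lesions and assesses treatment response under the
#' modified RANO-BM criteria (one-dimensional and volumetric).
#'
#' @param baseline,followup [volume3d()] objects, NIfTI paths, or
#'   `phantom_case` objects (required for oracle mode); `followup` may be
#'   `NULL` for a single-timepoint run.
#' @param detector,refiner trained segmenters (or `NULL` with
#'   `oracle = TRUE`).
#' @param config a [pipeline_config()].
#' @param oracle inject ground-truth labels in place of model predictions
#'   (inputs must carry label maps).
#' @param out_dir optional directory for lesion tables, the match CSV, the
#'   transform JSON and the assessment JSON.
#' @return A report list: per-timepoint `records`, and for pairs the
#'   `transform`, `matches` and `assessment`.
#' @export
run_end_to_end <- function(baseline, followup = NULL, detector = NULL,
                           refiner = NULL, config = pipeline_config(),
                           oracle = FALSE, out_dir = NULL) {
  get_case <- function(x) {
    if (is.character(x)) list(volume = read_volume(x), labels = NULL)
    else if (inherits(x, "phantom_case")) x
    else if (inherits(x, "volume3d")) list(volume = x, labels = NULL)
    else stop("unsupported input type")
  }
  if (!oracle && (is.null(detector) || is.null(refiner)))
    stop("missing detector/refiner checkpoint (or use oracle mode)")
  b <- get_case(baseline)
  if (oracle && is.null(b$labels))
    stop("oracle mode requires inputs with ground-truth label maps")
  gm_b <- if (oracle) b$truth$gm_intensity else NULL
  seg_b <- segment_volume(b$volume, detector, refiner, config,
                          oracle_labels = if (oracle) b$labels,
                          gm_reference = gm_b)
  report <- list(baseline = list(records = seg_b$records,
                                 labels = seg_b$labels),
                 config = unclass(config))
  if (!is.null(followup)) {
    f <- get_case(followup)
    gm_f <- if (oracle) f$truth$gm_intensity else NULL
    seg_f <- segment_volume(f$volume, detector, refiner, config,
                            oracle_labels = if (oracle) f$labels,
                            gm_reference = gm_f)
    transform <- register_similarity(seg_b$crop$volume, seg_f$crop$volume,
                                     levels = config$reg_levels,
                                     max_iter = config$reg_max_iter,
                                     polish = config$reg_polish)
    matches <- match_lesions(seg_b$records, seg_f$records, transform,
                             config$match_tolerance_mm)
    assessment <- assess_study_pair(seg_b$records, seg_f$records, matches,
                                    config$max_targets,
                                    config$min_diameter_mm)
    report$followup <- list(records = seg_f$records, labels = seg_f$labels)
    report$transform <- transform
    report$matches <- matches
    report$assessment <- assessment
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_lesion_table(seg_b$records,
                       file.path(out_dir, "baseline_lesions.csv"))
    if (!is.null(followup)) {
      write_lesion_table(report$followup$records,
                         file.path(out_dir, "followup_lesions.csv"))
      write_transform(report$transform,
                      file.path(out_dir, "transform.json"))
      mp <- report$matches$pairs
      rows <- list()
      if (nrow(mp))
        rows$matched <- data.frame(baseline_id = mp$baseline_id,
                                   followup_id = mp$followup_id,
                                   residual_mm = mp$residual_mm,
                                   status = "matched")
      if (length(report$matches$new))
        rows$new <- data.frame(baseline_id = NA,
                               followup_id = report$matches$new,
                               residual_mm = NA, status = "new")
      if (length(report$matches$disappeared))
        rows$gone <- data.frame(baseline_id = report$matches$disappeared,
                                followup_id = NA, residual_mm = NA,
                                status = "disappeared")
      match_df <- if (length(rows)) do.call(rbind, rows)
        else data.frame(baseline_id = integer(), followup_id = integer(),
                        residual_mm = numeric(), status = character())
      write.csv(match_df, file.path(out_dir, "matches.csv"),
                row.names = FALSE)
      a <- report$assessment
      jsonlite::write_json(
        list(one_dimensional = unclass(a$one_dimensional),
             volumetric = unclass(a$volumetric)),
        file.path(out_dir, "assessment.json"), auto_unbox = TRUE,
        digits = NA)
    }
  }
  report
}

# ---- synthetic study cohorts ----------------------------------------------

# truth-level match set and response assessment for a phantom pair
truth_assessment <- function(pair, config = pipeline_config()) {
  rb <- truth_lesion_records(pair$baseline$truth)
  rf <- truth_lesion_records(pair$followup$truth)
  kept <- intersect(rb$id, rf$id)
  new_ids <- setdiff(rf$id, rb$id)
  matches <- structure(list(
    pairs = data.frame(baseline_id = kept, followup_id = kept,
                       residual_mm = 0),
    new = new_ids, disappeared = setdiff(rb$id, kept)),
    class = "lesion_match_set")
  assess_study_pair(rb, rf, matches, config$max_targets,
                    config$min_diameter_mm)
}

random_similarity <- function(center_mm, max_angle = 6, max_trans = 4,
                              scale_range = c(0.98, 1.02)) {
  similarity_transform(runif(3, -max_angle, max_angle),
                       runif(3, -max_trans, max_trans),
                       runif(1, scale_range[1], scale_range[2]),
                       center_mm)
}

# place a new follow-up lesion inside the (mapped) brain, clear of existing
# mapped lesions
place_new_lesion <- function(truth, transform, diameter_mm) {
  mapped_center <- as.numeric(apply_transform(
    transform, rbind(truth$brain$center_mm)))
  sem <- transform$scale * truth$brain$semiaxes_mm
  existing <- lapply(truth$lesions, function(l) list(
    center_mm = as.numeric(apply_transform(transform, rbind(l$center_mm))),
    radii_mm = l$radii_mm))
  r <- diameter_mm / 2
  cand <- place_lesion(mapped_center, sem * 0.8, rep(r, 3), existing, 500L)
  if (is.null(cand)) stop("could not place new follow-up lesion")
  list(center_mm = cand, diameter_mm = diameter_mm, contrast = 2.2)
}

#' Generate a longitudinal phantom cohort
#'
#' Baseline/follow-up pairs under known similarity transforms, cycling
#' through response scenarios: complete response (all lesions removed),
#' partial response (all radii scaled 0.6), stable disease (unchanged),
#' progression by growth (radii scaled 1.35) and progression by a new 3 mm
#' lesion.  Every baseline is guaranteed at least one measurable lesion.
#'
#' @param n_pairs number of study pairs.
#' @param seed cohort seed.
#' @param config a [phantom_config()].
#' @return A list of pairs, each with `baseline`, `followup`,
#'   `scenario` and `truth_assessment`.
#' @export
generate_cohort <- function(n_pairs = 20L, seed = 1L,
                            config = phantom_config("tiny")) {
  scenarios <- c("CR", "PR", "SD", "PD-growth", "PD-new")
  out <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    scen <- scenarios[(i - 1L) %% length(scenarios) + 1L]
    base <- NULL
    for (try in 1:25) {
      cand <- tryCatch(
        generate_phantom(config, derive_seed(seed, i * 31L + try)),
        error = function(e) NULL)
      if (is.null(cand)) next
      dm <- truth_lesion_records(cand$truth)$diameter_mm
      if (any(dm >= 6.5)) { base <- cand; break }
    }
    if (is.null(base)) stop("could not generate a measurable baseline")
    ids <- vapply(base$truth$lesions, function(l) l$id, integer(1))
    fu <- NULL
    set.seed(derive_seed(seed, i * 101L))
    for (try in 1:25) {
      tr <- random_similarity(base$truth$brain$center_mm)
      changes <- switch(scen,
        "CR" = followup_changes(remove = ids),
        "PR" = followup_changes(growth = setNames(rep(0.6, length(ids)),
                                                  ids)),
        "SD" = followup_changes(),
        "PD-growth" = followup_changes(
          growth = setNames(rep(1.35, length(ids)), ids)),
        "PD-new" = followup_changes(
          add = list(place_new_lesion(base$truth, tr, 3))))
      fu <- tryCatch(
        generate_followup(base, tr, changes,
                          seed = derive_seed(seed, i * 211L + try)),
        error = function(e) NULL)
      if (!is.null(fu)) break
    }
    if (is.null(fu)) stop("could not generate follow-up for pair ", i)
    pair <- list(baseline = base, followup = fu, scenario = scen)
    pair$truth_assessment <- if (scen == "CR") {
      # all lesions removed: category is CR by construction
      rb <- truth_lesion_records(base$truth)
      tg <- select_target_lesions(rb)
      list(one_dimensional = assess_response_1d(
             tg$sum_longest_diameters_mm, 0, FALSE, FALSE, tg$ids),
           volumetric = assess_response_volumetric(
             tg$total_volume_mm3, 0, FALSE))
    } else truth_assessment(pair)
    out[[i]] <- pair
  }
  out
}

#' Write a deterministic test fixture set
#'
#' Generates a reproducible phantom cohort (tiny profile) and bundles the
#' packaged RANO-BM agreement tables alongside, for metric tests.
#'
#' @param seed cohort seed.
#' @param out_dir output directory.
#' @param n_pairs number of study pairs.
#' @return The manifest path, invisibly.
#' @export
make_fixtures <- function(seed, out_dir, n_pairs = 20L) {
  cohort <- generate_cohort(n_pairs, seed)
  studies <- lapply(seq_along(cohort), function(i)
    list(id = sprintf("case%02d", i), baseline = cohort[[i]]$baseline,
         followup = cohort[[i]]$followup))
  manifest <- write_study(studies, out_dir, overwrite = TRUE)
  for (basis in c("one_dimensional", "volumetric"))
    file.copy(system.file("extdata",
                          paste0("rano_agreement_", basis, ".csv"),
                          package = "metrano", mustWork = TRUE),
              file.path(out_dir, paste0("rano_agreement_", basis, ".csv")),
              overwrite = TRUE)
  invisible(manifest)
}

# ---- training-set assembly -------------------------------------------------

#' Build detector and refiner training inputs from phantom cases
#'
#' Preprocesses each case exactly as the inference pipeline does and pairs
#' the detection cube / refinement patches with their ground-truth masks.
#'
#' @param cases list of `phantom_case` objects.
#' @param config a [pipeline_config()].
#' @param max_slices_per_lesion cap on refinement patches per lesion
#'   (evenly spread over the lesion's slice extent); `Inf` keeps all.
#' @return A list with `cubes`, `cube_labels` (3D training pairs),
#'   `patch_sets`, `label_sets` (2D training pairs) and the per-case
#'   preprocessing records.
#' @export
build_training_set <- function(cases, config = pipeline_config(),
                               max_slices_per_lesion = Inf) {
  cubes <- list(); cube_labels <- list()
  patch_sets <- list(); label_sets <- list()
  pps <- list()
  for (ci in seq_along(cases)) {
    cs <- cases[[ci]]
    pp <- preprocess_case(cs$volume, config, cs$truth$gm_intensity)
    cubes[[ci]] <- pp$cube$volume$data
    cube_labels[[ci]] <- array(
      as.numeric(labels_to_cube(cs$labels, pp$crop$box,
                                pp$cube$record) > 0),
      dim(pp$cube$volume$data))
    norm_native <- volume3d(pp$norm$data, cs$volume$spacing,
                            cs$volume$origin)
    truth_bin <- volume3d(array(as.numeric(cs$labels$data > 0),
                                dim(cs$labels$data)),
                          cs$volume$spacing, cs$volume$origin)
    for (box in extract_bounding_boxes(cs$labels, config$box_margin)) {
      ps <- crop_and_upsample(norm_native, box, config$patch_size,
                              config$patch_margin)
      ls <- crop_and_upsample(truth_bin, box, config$patch_size,
                              config$patch_margin, nearest = TRUE)
      nz <- dim(ps$patches)[3]
      if (is.finite(max_slices_per_lesion) && nz > max_slices_per_lesion) {
        keep <- unique(round(seq(1, nz,
                                 length.out = max_slices_per_lesion)))
        ps$patches <- ps$patches[, , keep, drop = FALSE]
        ls$patches <- ls$patches[, , keep, drop = FALSE]
      }
      patch_sets[[length(patch_sets) + 1L]] <- ps
      label_sets[[length(label_sets) + 1L]] <- ls
    }
    pps[[ci]] <- pp
  }
  list(cubes = cubes, cube_labels = cube_labels, patch_sets = patch_sets,
       label_sets = label_sets, preprocessed = pps)
}

#' Train detector and refiner on a phantom cohort (tiny-profile recipe)
#'
#' The desk-scale training recipe: depth-1 U-Nets with 2 base channels,
#' Adam at batch size 1 under the Dice loss, learning rate 3e-3 dropped
#' tenfold for the final quarter of training; 20 epochs for the 3D
#' detector, 12 for the 2D refiner with at most 5 patches per lesion.
#'
#' @param cases list of `phantom_case` objects (training cohort).
#' @param config a [pipeline_config()].
#' @param seed training seed (initialization and shuffling).
#' @param detector_cfg,refiner_cfg [train_config()] overrides.
#' @param depth,base_channels architecture knobs shared by both models.
#' @param max_slices_per_lesion refinement patches per lesion.
#' @return A list with `detector` and `refiner` (trained segmenters).
#' @export
train_phantom_models <- function(cases, config = pipeline_config(),
                                 seed = 1L,
                                 detector_cfg = NULL, refiner_cfg = NULL,
                                 depth = 1L, base_channels = 2L,
                                 max_slices_per_lesion = 5L) {
  if (is.null(detector_cfg))
    detector_cfg <- train_config(epochs = 20L, learning_rate = 3e-3,
                                 milestones = c(15L, 20L),
                                 validation_fraction = 0.1, seed = seed)
  if (is.null(refiner_cfg))
    refiner_cfg <- train_config(epochs = 12L, learning_rate = 3e-3,
                                milestones = c(9L, 12L),
                                validation_fraction = 0.1, seed = seed + 1L)
  ts <- build_training_set(cases, config, max_slices_per_lesion)
  detector <- fit_detector(ts$cubes, ts$cube_labels, detector_cfg,
                           depth = depth, base_channels = base_channels)
  refiner <- fit_refiner(ts$patch_sets, ts$label_sets, refiner_cfg,
                         depth = depth, base_channels = base_channels)
  list(detector = detector, refiner = refiner)
}

#' Evaluate trained models on held-out phantom cases
#'
#' Runs the full coarse-to-fine pipeline per case and scores lesion-wise
#' detection and segmentation against the ground truth.
#'
#' @param cases list of held-out `phantom_case` objects.
#' @param detector,refiner trained segmenters.
#' @param config a [pipeline_config()].
#' @param measurable_mm size threshold for the aggregate metrics.
#' @return A list: `sensitivity_measurable`, `mean_dsc_measurable`,
#'   `fp_per_scan`, the per-case `evals` and the size-binned table.
#' @export
evaluate_detection <- function(cases, detector, refiner,
                               config = pipeline_config(),
                               measurable_mm = 5) {
  evals <- lapply(cases, function(cs) {
    seg <- segment_volume(cs$volume, detector, refiner, config,
                          gm_reference = cs$truth$gm_intensity)
    match_detections_to_truth(seg$labels, cs$labels)
  })
  tab <- sensitivity_by_size(evals, measurable_mm = measurable_mm)
  lesions <- do.call(rbind, lapply(evals, function(e) e$lesions))
  meas <- lesions[lesions$diameter_mm >= measurable_mm, , drop = FALSE]
  list(sensitivity_measurable = attr(tab, "sensitivity_measurable"),
       mean_dsc_measurable = mean(meas$dsc, na.rm = TRUE),
       fp_per_scan = mean(vapply(evals, function(e) e$fp_count,
                                 numeric(1))),
       by_size = tab, evals = evals)
}
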