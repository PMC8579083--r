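# Synthetic longitudinal brain phantoms with exact lesion ground truth.
#
# The phantom emulates what the downstream contracts need from contrast-
# enhanced 3D T1 data: a brain-shaped foreground on an exactly-zero
# background, a known gray-matter reference intensity with mild smooth
# gradients, quasi-spherical hyperintense lesions with known ellipsoid
# parameters, additive Gaussian noise, and follow-up scans related to the
# baseline by a known similarity transform with per-lesion growth, shrinkage,
# appearance and disappearance.

#' Phantom generator configuration
#'
#' @param profile `"tiny"` (64^3 grid, for fast tests) or `"full"`
#'   (160x192x160 at 1 mm, mirroring a 1 mm-isotropic clinical protocol).
#' @param dim,spacing grid shape and voxel size in mm.
#' @param brain_frac brain ellipsoid semi-axes as a fraction of half the
#'   grid extent, per axis; the default is deliberately anisotropic
#'   (head-like, wider left-right than deep) so that rotations are
#'   identifiable.
#' @param gm_intensity gray-matter reference intensity (arbitrary units).
#' @param gradient_amp relative amplitude of the smooth linear intensity
#'   gradients inside the brain.
#' @param noise_sigma standard deviation of additive Gaussian noise (same
#'   units as `gm_intensity`; applied inside the brain only).
#' @param n_lesions integer length-2 range for the lesion count.
#' @param diameter_range_mm lesion longest-diameter range; diameters are
#'   drawn log-uniformly so that small nodules dominate, as in clinical
#'   series.
#' @param contrast_range lesion intensity as a multiple of `gm_intensity`.
#' @param anisotropy maximal relative deviation of the secondary radii from
#'   the in-plane maximum (quasi-spherical lesions).
#' @param max_tries placement retries before giving up on a lesion.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(profile = c("tiny", "full"),
                           dim = NULL, spacing = c(1, 1, 1),
                           brain_frac = c(0.80, 0.65, 0.72),
                           gm_intensity = 100,
                           gradient_amp = 0.08,
                           noise_sigma = 5,
                           n_lesions = c(3L, 8L),
                           diameter_range_mm = c(3, 15),
                           contrast_range = c(1.5, 3.0),
                           anisotropy = 0.1,
                           max_tries = 200L) {
  profile <- match.arg(profile)
  if (is.null(dim))
    dim <- if (profile == "full") c(160L, 192L, 160L) else c(64L, 64L, 64L)
  stopifnot(length(dim) == 3L, all(dim >= 8L), all(spacing > 0),
            gm_intensity > 0, noise_sigma >= 0,
            diameter_range_mm[1] > 0,
            diameter_range_mm[2] >= diameter_range_mm[1])
  structure(list(profile = profile, dim = as.integer(dim),
                 spacing = as.numeric(spacing),
                 brain_frac = rep(brain_frac, length.out = 3),
                 gm_intensity = gm_intensity, gradient_amp = gradient_amp,
                 noise_sigma = noise_sigma,
                 n_lesions = as.integer(rep(n_lesions, length.out = 2)),
                 diameter_range_mm = diameter_range_mm,
                 contrast_range = contrast_range, anisotropy = anisotropy,
                 max_tries = as.integer(max_tries)),
            class = "phantom_config")
}

# world-coordinate grids for a (dim, spacing, origin) lattice, as an N x 3
# matrix in column-major voxel order
grid_world_coords <- function(dim, spacing, origin = c(0, 0, 0)) {
  xs <- origin[1] + (seq_len(dim[1]) - 1) * spacing[1]
  ys <- origin[2] + (seq_len(dim[2]) - 1) * spacing[2]
  zs <- origin[3] + (seq_len(dim[3]) - 1) * spacing[3]
  cbind(rep(xs, times = dim[2] * dim[3]),
        rep(rep(ys, each = dim[1]), times = dim[3]),
        rep(zs, each = dim[1] * dim[2]))
}

ellipsoid_quad <- function(P, center, semiaxes) {
  ((P[, 1] - center[1]) / semiaxes[1])^2 +
    ((P[, 2] - center[2]) / semiaxes[2])^2 +
    ((P[, 3] - center[3]) / semiaxes[3])^2
}

# Render a phantom volume + labels on a grid.  `mapped_lesions` and the brain
# are evaluated at Q (coordinates mapped back into the baseline frame);
# `direct_lesions` are evaluated at W (the grid's own frame).
render_phantom <- function(truth, Q, W, mapped_lesions, direct_lesions,
                           noise_seed) {
  dim <- truth$grid$dim; spacing <- truth$grid$spacing
  brain <- ellipsoid_quad(Q, truth$brain$center_mm,
                          truth$brain$semiaxes_mm) <= 1
  rel <- sweep(sweep(Q, 2, truth$brain$center_mm, `-`), 2,
               truth$brain$semiaxes_mm, `/`)
  intens <- truth$gm_intensity * (1 + as.numeric(rel %*% truth$gradient))
  vol <- numeric(nrow(Q))
  vol[brain] <- intens[brain]
  labels <- integer(nrow(Q))
  fill_lesion <- function(P, les, radii) {
    inside <- ellipsoid_quad(P, les$center_mm, radii) <= 1
    labels[inside] <<- les$id
    vol[inside] <<- les$contrast * truth$gm_intensity
  }
  for (les in mapped_lesions) fill_lesion(Q, les, les$render_radii_mm)
  for (les in direct_lesions) fill_lesion(W, les, les$render_radii_mm)
  set.seed(noise_seed)
  if (truth$noise_sigma > 0)
    vol[brain] <- vol[brain] + rnorm(sum(brain), 0, truth$noise_sigma)
  list(volume = volume3d(array(vol, dim), spacing, truth$grid$origin),
       labels = label_map(array(labels, dim), spacing, truth$grid$origin))
}

sample_lesion_geometry <- function(config) {
  d <- exp(runif(1, log(config$diameter_range_mm[1]),
                 log(config$diameter_range_mm[2])))
  r <- d / 2
  a <- config$anisotropy
  radii <- c(r, r * runif(1, 1 - a, 1), r * runif(1, 1 - a, 1))
  if (runif(1) < 0.5) radii[1:2] <- radii[2:1]  # random in-plane major axis
  list(radii_mm = radii, contrast = runif(1, config$contrast_range[1],
                                          config$contrast_range[2]))
}

# `headroom` leaves room for later growth: separations and the brain margin
# are computed as if every radius were `headroom` times larger, so follow-up
# growth up to that factor can neither merge lesions nor cross the brain edge
place_lesion <- function(center_mm, semiaxes_mm, radii, existing, max_tries,
                         headroom = 1.4) {
  maxr <- max(radii) * headroom
  shrink <- pmax(semiaxes_mm - maxr - 1, 1)
  for (i in seq_len(max_tries)) {
    u <- runif(3, -1, 1)
    if (sum(u^2) > 1) next
    cand <- center_mm + u * shrink
    ok <- TRUE
    for (e in existing) {
      if (sqrt(sum((cand - e$center_mm)^2)) <
          maxr + headroom * max(e$radii_mm) + 2) { ok <- FALSE; break }
    }
    if (ok) return(cand)
  }
  NULL
}

#' Generate a synthetic baseline phantom
#'
#' Produces a brain-shaped volume on an exactly-zero background with
#' hyperintense ellipsoidal lesions, the exact lesion label map, and a truth
#' record sufficient to regenerate the case bit-identically.
#'
#' @param config a [phantom_config()].
#' @param seed integer seed; the same seed and config give bit-identical
#'   output.
#' @return A list of class `phantom_case` with elements `volume`
#'   ([volume3d()]), `labels` ([label_map()]) and `truth`.
#' @export
generate_phantom <- function(config = phantom_config(), seed = 1L) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(seed)
  dim <- config$dim; spacing <- config$spacing
  extent <- dim * spacing
  center <- extent / 2
  semiax <- config$brain_frac * extent / 2
  gradient <- runif(3, -config$gradient_amp, config$gradient_amp)
  n <- if (config$n_lesions[1] == config$n_lesions[2]) config$n_lesions[1]
       else sample(config$n_lesions[1]:config$n_lesions[2], 1)
  lesions <- list()
  for (i in seq_len(n)) {
    geo <- sample_lesion_geometry(config)
    cand <- place_lesion(center, semiax, geo$radii_mm, lesions,
                         config$max_tries)
    if (is.null(cand))
      stop(sprintf(
        "could not place lesion %d (radii %s mm) inside the brain after %d tries",
        i, paste(signif(geo$radii_mm, 3), collapse = "x"), config$max_tries))
    lesions[[i]] <- list(id = i, center_mm = cand, radii_mm = geo$radii_mm,
                         contrast = geo$contrast,
                         render_radii_mm = geo$radii_mm)
  }
  truth <- list(
    seed = seed,
    grid = list(dim = dim, spacing = spacing, origin = c(0, 0, 0)),
    gm_intensity = config$gm_intensity,
    brain = list(center_mm = center, semiaxes_mm = semiax),
    gradient = gradient,
    noise_sigma = config$noise_sigma,
    lesions = lapply(lesions, function(l) l[c("id", "center_mm", "radii_mm",
                                              "contrast")]),
    transform = NULL, changes = NULL)
  W <- grid_world_coords(dim, spacing)
  out <- render_phantom(truth, W, W, list(), lesions, noise_seed = seed + 1L)
  structure(c(out, list(truth = truth)), class = "phantom_case")
}

#' Describe per-lesion changes for a follow-up phantom
#'
#' @param growth named numeric vector of per-lesion radius scale factors
#'   (names are baseline lesion ids; unlisted lesions keep factor 1).
#' @param remove integer ids of lesions absent at follow-up.
#' @param add list of new-lesion specs, each a list with `center_mm`
#'   (follow-up frame), `diameter_mm` and optionally `contrast`.
#' @return A list of class `followup_changes`.
#' @export
followup_changes <- function(growth = numeric(), remove = integer(),
                             add = list()) {
  structure(list(growth = growth, remove = as.integer(remove), add = add),
            class = "followup_changes")
}

#' Generate a follow-up phantom from a baseline truth
#'
#' The follow-up shows the baseline anatomy seen through the inverse of
#' `transform` (so that registering baseline to follow-up recovers
#' `transform` exactly), with per-lesion growth/shrinkage/removal applied in
#' the baseline frame and optional new lesions in the follow-up frame.
#' Follow-up truth records lesion centers mapped through the transform and
#' radii scaled by the transform's isotropic scale times the change factor.
#'
#' @param baseline a `phantom_case` (or its `truth`).
#' @param transform a [similarity_transform()] mapping baseline world
#'   coordinates to follow-up world coordinates.
#' @param changes a [followup_changes()].
#' @param seed seed for the follow-up noise realization.
#' @return A `phantom_case` whose truth records `transform` and `changes`.
#' @export
generate_followup <- function(baseline, transform,
                              changes = followup_changes(), seed = 2L) {
  truth <- if (inherits(baseline, "phantom_case")) baseline$truth
           else baseline
  stopifnot(inherits(transform, "similarity_transform"),
            inherits(changes, "followup_changes"))
  dim <- truth$grid$dim; spacing <- truth$grid$spacing
  # refuse transforms that push the brain off the grid: the mapped
  # ellipsoid's tight bounding box along axis i is c'_i +/- ||row_i(A) * a||
  af <- transform_affine(transform)
  cen <- as.numeric(af$A %*% truth$brain$center_mm + af$d)
  half <- sqrt(rowSums(sweep(af$A, 2, truth$brain$semiaxes_mm, `*`)^2))
  extent <- dim * spacing
  if (any(cen - half < -spacing) || any(cen + half > extent))
    stop("transform moves the brain outside the grid")
  kept <- Filter(function(l) !(l$id %in% changes$remove), truth$lesions)
  kept <- lapply(kept, function(l) {
    f <- changes$growth[as.character(l$id)]
    f <- if (length(f) == 1 && !is.na(f)) as.numeric(f) else 1
    l$render_radii_mm <- l$radii_mm * f   # baseline-frame rendering radii
    l$factor <- f
    l
  })
  next_id <- if (length(truth$lesions))
    max(vapply(truth$lesions, function(l) as.integer(l$id), integer(1)))
  else 0L
  new_lesions <- list()
  set.seed(seed)
  for (i in seq_along(changes$add)) {
    sp <- changes$add[[i]]
    r <- sp$diameter_mm / 2
    new_lesions[[i]] <- list(
      id = next_id + i, center_mm = as.numeric(sp$center_mm),
      radii_mm = rep(r, 3),
      contrast = if (is.null(sp$contrast)) 2 else sp$contrast,
      render_radii_mm = rep(r, 3))
  }
  tinv <- invert_transform(transform)
  W <- grid_world_coords(dim, spacing)
  Q <- apply_transform(tinv, W)
  out <- render_phantom(truth, Q, W, kept, new_lesions,
                        noise_seed = seed + 1L)
  s <- transform$scale
  fu_lesions <- c(
    lapply(kept, function(l) list(
      id = l$id,
      center_mm = as.numeric(apply_transform(transform, rbind(l$center_mm))),
      radii_mm = l$radii_mm * l$factor * s,
      contrast = l$contrast)),
    lapply(new_lesions, function(l) l[c("id", "center_mm", "radii_mm",
                                        "contrast")]))
  fu_truth <- truth
  fu_truth$seed <- seed
  fu_truth$lesions <- fu_lesions
  fu_truth$transform <- transform
  fu_truth$changes <- list(
    growth = as.list(changes$growth), remove = changes$remove,
    new_ids = vapply(new_lesions, `[[`, integer(1), "id"))
  structure(c(out, list(truth = fu_truth)), class = "phantom_case")
}

#' Ground-truth lesion records
#'
#' Converts a phantom truth into the same per-lesion table the measurement
#' stage produces: analytic ellipsoid volume (4/3 pi rx ry rz) and longest
#' axial diameter 2*max(rx, ry).
#'
#' @param truth a phantom truth (from a `phantom_case`).
#' @return A data.frame with one row per lesion.
#' @export
truth_lesion_records <- function(truth) {
  if (inherits(truth, "phantom_case")) truth <- truth$truth
  if (length(truth$lesions) == 0L)
    return(data.frame(id = integer(), volume_mm3 = numeric(),
                      diameter_mm = numeric(), centroid_x_mm = numeric(),
                      centroid_y_mm = numeric(), centroid_z_mm = numeric()))
  do.call(rbind, lapply(truth$lesions, function(l) {
    data.frame(id = l$id,
               volume_mm3 = 4 / 3 * pi * prod(l$radii_mm),
               diameter_mm = 2 * max(l$radii_mm[1:2]),
               centroid_x_mm = l$center_mm[1],
               centroid_y_mm = l$center_mm[2],
               centroid_z_mm = l$center_mm[3])
  }))
}

#' Analytic brain mask of a phantom
#' @param truth a phantom truth or `phantom_case`.
#' @return A binary [label_map()] of the brain ellipsoid.
#' @export
phantom_brain_mask <- function(truth) {
  if (inherits(truth, "phantom_case")) truth <- truth$truth
  W <- grid_world_coords(truth$grid$dim, truth$grid$spacing,
                         truth$grid$origin)
  inside <- ellipsoid_quad(W, truth$brain$center_mm,
                           truth$brain$semiaxes_mm) <= 1
  label_map(array(as.integer(inside), truth$grid$dim), truth$grid$spacing,
            truth$grid$origin)
}

# ---- study serialization ---------------------------------------------------

truth_to_json <- function(truth, path) {
  tr <- truth
  if (!is.null(tr$transform)) tr$transform <- unclass(tr$transform)
  jsonlite::write_json(tr, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

json_to_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$grid$dim <- as.integer(x$grid$dim)
  if (is.data.frame(x$lesions))
    x$lesions <- lapply(seq_len(nrow(x$lesions)), function(i) {
      l <- x$lesions[i, ]
      list(id = as.integer(l$id), center_mm = unlist(l$center_mm),
           radii_mm = unlist(l$radii_mm), contrast = l$contrast)
    })
  if (!is.null(x$transform) && length(x$transform))
    x$transform <- similarity_transform(x$transform$angles_deg,
                                        x$transform$translation_mm,
                                        x$transform$scale,
                                        x$transform$center_mm)
  else x$transform <- NULL
  x
}

#' Write a longitudinal phantom study to disk
#'
#' Writes NIfTI volumes and label maps, truth JSON sidecars and a manifest
#' listing the role of every file.
#'
#' @param studies list of study entries; each entry is a list with `id`,
#'   `baseline` (a `phantom_case`) and optionally `followup`.
#' @param dir output directory (created if needed).
#' @param overwrite overwrite an existing manifest.
#' @return The manifest path, invisibly.
#' @export
write_study <- function(studies, dir, overwrite = FALSE) {
  if (length(studies) == 0L) stop("empty study list")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(dir, "manifest.json")
  if (file.exists(manifest_path) && !overwrite)
    stop("manifest already exists (use overwrite = TRUE): ", manifest_path)
  entries <- list()
  for (st in studies) {
    id <- st$id
    for (role in c("baseline", "followup")) {
      cs <- st[[role]]
      if (is.null(cs)) next
      stem <- file.path(dir, paste0(id, "_", role))
      write_volume(cs$volume, paste0(stem, ".nii.gz"))
      write_volume(cs$labels, paste0(stem, "_labels.nii.gz"))
      truth_to_json(cs$truth, paste0(stem, "_truth.json"))
      entries[[length(entries) + 1L]] <- list(
        id = id, role = role,
        volume = basename(paste0(stem, ".nii.gz")),
        labels = basename(paste0(stem, "_labels.nii.gz")),
        truth = basename(paste0(stem, "_truth.json")))
    }
  }
  jsonlite::write_json(entries, manifest_path, auto_unbox = TRUE)
  invisible(manifest_path)
}

#' Read a phantom study manifest back
#' @param manifest_path path written by [write_study()].
#' @return A list of study entries with volumes, labels and truths loaded.
#' @export
read_study <- function(manifest_path) {
  entries <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  dir <- dirname(manifest_path)
  out <- list()
  for (e in entries) {
    cs <- list(volume = read_volume(file.path(dir, e$volume)),
               labels = read_volume(file.path(dir, e$labels),
                                    as_labels = TRUE),
               truth = json_to_truth(file.path(dir, e$truth)))
    class(cs) <- "phantom_case"
    if (is.null(out[[e$id]])) out[[e$id]] <- list(id = e$id)
    out[[e$id]][[e$role]] <- cs
  }
  unname(out)
}
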