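# Coarse 3D lesion detection on the resampled cube.

#' Train the 3D lesion detector
#'
#' Fits a 3D U-Net under the Dice loss on resampled normalized cubes with
#' binary (any-lesion) labels.
#'
#' @param volumes list of normalized intensity cubes (3D arrays, all the
#'   same size).
#' @param labels list of binary arrays of the same shapes.
#' @param cfg a [train_config()].
#' @param depth,base_channels architecture knobs (see [unet_segmenter()]).
#' @return A trained `unet_segmenter` with a per-epoch loss history.
#' @export
fit_detector <- function(volumes, labels, cfg = train_config(),
                         depth = 1L, base_channels = 4L) {
  if (length(volumes) == 0L) stop("empty training set")
  volumes <- lapply(volumes, function(v)
    if (inherits(v, "volume3d")) v$data else v)
  labels <- lapply(labels, function(l) {
    a <- if (inherits(l, "volume3d")) l$data else l
    array(as.numeric(a > 0), dim(a))
  })
  model <- unet_segmenter(3L, depth, base_channels, 1L, seed = cfg$seed)
  fit_segmenter(model, volumes, labels, cfg)
}

#' Detect lesions on a normalized cube
#'
#' Thresholds the model's probability map at `threshold`, labels 26-connected
#' components and drops components below `min_voxels`.
#'
#' @param vol normalized cube ([volume3d()] or array).
#' @param model trained segmenter or [oracle_segmenter()].
#' @param threshold probability cutoff (default 0.5).
#' @param min_voxels minimum component size in voxels (default 2).
#' @return A [label_map()] in cube space.
#' @export
detect_lesions <- function(vol, model, threshold = 0.5, min_voxels = 2L) {
  arr <- if (inherits(vol, "volume3d")) vol$data else vol
  spacing <- if (inherits(vol, "volume3d")) vol$spacing else c(1, 1, 1)
  origin <- if (inherits(vol, "volume3d")) vol$origin else c(0, 0, 0)
  prob <- predict_probabilities(model, arr)
  labels <- label_array(prob >= threshold, min_voxels)
  label_map(labels, spacing, origin)
}

# threshold mask -> 26-connected components -> drop small -> relabel 1..K
label_array <- function(mask, min_voxels = 0L) {
  dims <- dim(mask)
  lab <- cpp_label_components(as.integer(mask), dims)
  if (min_voxels > 1L && any(lab > 0L)) {
    counts <- tabulate(lab)
    drop <- which(counts < min_voxels)
    if (length(drop)) {
      lab[lab %in% drop] <- 0L
      keep <- sort(unique(lab[lab > 0L]))
      lab <- match(lab, keep, nomatch = 0L)
    }
  }
  array(as.integer(lab), dims)
}

#' Extract per-lesion bounding boxes from a label map
#'
#' One tight half-open box per label id, expanded by `margin` voxels and
#' clamped to the grid; ordered by ascending label id.
#'
#' @param labels a [label_map()].
#' @param margin voxels added to each face.
#' @return A list of [bounding_box()] objects (empty for an empty map).
#' @export
extract_bounding_boxes <- function(labels, margin = 0L) {
  arr <- if (inherits(labels, "volume3d")) labels$data else labels
  ids <- sort(unique(arr[arr > 0L]))
  lapply(ids, function(id) {
    expand_box(mask_bounding_box(arr == id), margin, dim(arr))
  })
}
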