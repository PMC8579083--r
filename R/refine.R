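# Per-lesion fine segmentation: crop each detected bounding box, resample
# its axial slices to a high-resolution square patch, segment in 2D, and
# stitch the result back onto the native grid.

#' Crop a lesion box and upsample its axial slices
#'
#' The box is expanded by `margin_frac` per axis, then every axial slice it
#' intersects is resampled to a `size` x `size` patch preserving the
#' in-plane aspect ratio via zero padding.  A geometric record per patch set
#' allows exact inverse mapping.
#'
#' @param vol a [volume3d()] (normalized intensities, native grid).
#' @param box a [bounding_box()] in native voxel indices.
#' @param size patch edge in pixels (default 512).
#' @param margin_frac box expansion per axis before resampling.
#' @param nearest use nearest-neighbor interpolation (for label patches).
#' @return A list of class `lesion_patch_set`: `patches` (size x size x
#'   nslices array) and `geom` (the inverse-mapping record).
#' @export
crop_and_upsample <- function(vol, box, size = 512L, margin_frac = 0.25,
                              nearest = FALSE) {
  stopifnot(inherits(vol, "volume3d"), inherits(box, "bounding_box"))
  dims <- dim(vol$data)
  ext <- box$max - box$min
  ext <- pmax(ext, 8L)  # degenerate boxes padded to a minimum extent
  margin <- ceiling(margin_frac * ext)
  center <- (box$min + box$max) / 2
  half <- ext / 2 + margin
  lo <- pmax(as.integer(floor(center - half)), 0L)
  hi <- pmin(as.integer(ceiling(center + half)), as.integer(dims))
  ebox <- bounding_box(lo, hi)
  nb <- ebox$max - ebox$min
  # in-plane aspect-preserving scale into the size x size patch
  extent_mm <- nb[1:2] * vol$spacing[1:2]
  out_sp <- max(extent_mm) / size
  content <- pmin(as.integer(round(extent_mm / out_sp)), size)
  offset <- (size - content) %/% 2L
  scale <- out_sp / vol$spacing[1:2]
  shift <- (0.5 - offset) * scale - 0.5  # box-local coordinates: pad is 0
  nsl <- nb[3]
  sub <- box_slice(vol$data, ebox)
  patches <- array(0, c(size, size, nsl))
  A <- rbind(cbind(diag(scale), c(0, 0), shift), c(0, 0, 0, 0))
  for (k in seq_len(nsl)) {
    A[3, 4] <- k - 1
    patches[, , k] <- array(
      cpp_resample_affine(as.numeric(sub), nb, A,
                          c(size, size, 1L), nearest, 0),
      c(size, size))
  }
  structure(list(patches = patches,
                 geom = list(box = ebox, size = as.integer(size),
                             out_spacing = out_sp, offset = offset,
                             content = content, scale = scale,
                             in_dims = dims, in_spacing = vol$spacing,
                             in_origin = vol$origin)),
            class = "lesion_patch_set")
}

# map one binary patch back to its native-grid slice (nearest-neighbor)
patch_to_native_slice <- function(patch, geom) {
  b <- geom$box
  nb <- b$max[1:2] - b$min[1:2]
  out <- matrix(0L, nb[1], nb[2])
  # native in-plane voxel (x, y) within the box -> patch pixel
  scale <- geom$in_spacing[1:2] / geom$out_spacing
  for (y in seq_len(nb[2])) {
    py <- round((y - 0.5) * scale[2] + geom$offset[2] - 0.5) + 1
    if (py < 1 || py > geom$size) next
    px <- round((seq_len(nb[1]) - 0.5) * scale[1] + geom$offset[1] - 0.5) + 1
    ok <- px >= 1 & px <= geom$size
    out[ok, y] <- as.integer(patch[px[ok], py] > 0)
  }
  out
}

#' Train the 2D lesion refiner
#'
#' Fits a 2D U-Net under the Dice loss on per-lesion axial patches.
#'
#' @param patch_sets list of `lesion_patch_set` objects (intensities).
#' @param label_sets matching list of `lesion_patch_set` objects built from
#'   the truth label masks (use `nearest = TRUE`).
#' @param cfg a [train_config()]; with `augment = TRUE` each patch is
#'   expanded by the 16 flip/rotation/scale combinations.
#' @param depth,base_channels architecture knobs.
#' @return A trained 2D `unet_segmenter`.
#' @export
fit_refiner <- function(patch_sets, label_sets, cfg = train_config(),
                        depth = 1L, base_channels = 4L) {
  xs <- list(); ts <- list()
  for (i in seq_along(patch_sets)) {
    ps <- patch_sets[[i]]$patches
    ls <- label_sets[[i]]$patches
    for (k in seq_len(dim(ps)[3])) {
      x2 <- ps[, , k]; t2 <- array(as.numeric(ls[, , k] > 0), dim(x2))
      if (isTRUE(cfg$augment)) {
        ax <- augment_16(x2); at <- augment_16(t2)
        for (j in seq_along(ax)) {
          xs[[length(xs) + 1L]] <- ax[[j]]
          ts[[length(ts) + 1L]] <- array(as.numeric(at[[j]] > 0.5),
                                         dim(at[[j]]))
        }
      } else {
        xs[[length(xs) + 1L]] <- x2
        ts[[length(ts) + 1L]] <- t2
      }
    }
  }
  if (length(xs) < 2L) stop("need at least 2 training patches")
  model <- unet_segmenter(2L, depth, base_channels, 1L, seed = cfg$seed)
  cfg$augment <- FALSE  # static 16x expansion already applied above
  fit_segmenter(model, xs, ts, cfg)
}

#' Refine one detected lesion
#'
#' Runs the 2D model on every patch slice, thresholds at 0.5, maps each
#' slice back to the native grid and unions them into a 3D mask.  An empty
#' result is allowed: the refiner may veto a detection.
#'
#' @param patches a `lesion_patch_set`.
#' @param model trained 2D segmenter or [oracle_segmenter()].
#' @param threshold probability cutoff.
#' @return A logical 3D array on the native grid (the lesion mask).
#' @export
refine_lesion <- function(patches, model, threshold = 0.5) {
  stopifnot(inherits(patches, "lesion_patch_set"))
  geom <- patches$geom
  mask <- array(FALSE, geom$in_dims)
  b <- geom$box
  prob_all <- predict_probabilities(model, patches$patches)
  for (k in seq_len(dim(patches$patches)[3])) {
    prob <- prob_all[, , k]
    sl <- patch_to_native_slice(prob >= threshold, geom)
    if (any(sl > 0))
      mask[(b$min[1] + 1):b$max[1], (b$min[2] + 1):b$max[2],
           b$min[3] + k] <-
        mask[(b$min[1] + 1):b$max[1], (b$min[2] + 1):b$max[2],
             b$min[3] + k] | (sl > 0)
  }
  mask
}

#' Assemble refined lesion masks into a label map
#'
#' Voxelwise OR of the per-lesion masks, relabeled by 26-connectivity, with
#' one lesion record stub per final component.
#'
#' @param masks list of logical arrays on a common grid.
#' @param spacing,origin grid geometry.
#' @param min_voxels drop final components smaller than this.
#' @return A list with `labels` (a [label_map()]) and `records` (see
#'   [lesion_records()]).
#' @export
assemble_lesion_map <- function(masks, spacing = c(1, 1, 1),
                                origin = c(0, 0, 0), min_voxels = 0L) {
  if (length(masks) == 0L)
    stop("no masks supplied; pass at least an all-FALSE array")
  dims <- dim(masks[[1]])
  acc <- array(FALSE, dims)
  for (m in masks) {
    if (!identical(dim(m), dims)) stop("mask grid mismatch")
    acc <- acc | m
  }
  labels <- label_map(label_array(acc, min_voxels), spacing, origin)
  list(labels = labels, records = lesion_records(labels))
}
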