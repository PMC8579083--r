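# Intensity normalization, brain masking/cropping and aspect-preserving
# resampling to the detector's cube.

#' Normalize intensities against a gray-matter reference
#'
#' Maps non-background intensities to `[0, 1]` by `v / (2 * gm_reference)`
#' with clipping, so the gray-matter reference lands at 0.5; background
#' voxels are forced to exactly 0.  With `gm_reference = "auto"` the median
#' intensity of the non-background voxels is used as the anchor.
#'
#' @param vol a [volume3d()].
#' @param gm_reference positive scalar anchor intensity, or `"auto"`.
#' @param background_mask logical/0-1 array of background voxels (same shape
#'   as `vol`); if `NULL`, background is taken as voxels below 2% of the 99th
#'   intensity percentile.
#' @return A `normalized_volume` (a [volume3d()] with values in `[0, 1]`,
#'   plus `gm_reference` and the logical `background` mask).
#' @export
normalize_intensity <- function(vol, gm_reference = "auto",
                                background_mask = NULL) {
  stopifnot(inherits(vol, "volume3d"))
  x <- vol$data
  if (is.null(background_mask)) {
    thr <- 0.02 * quantile(x, 0.99, names = FALSE)
    background <- x < thr
  } else {
    if (!identical(dim(background_mask), dim(x)))
      stop("background mask shape does not match volume")
    background <- background_mask > 0
  }
  if (identical(gm_reference, "auto")) {
    if (all(background)) stop("no foreground voxels to anchor normalization")
    gm_reference <- median(x[!background])
  }
  gm_reference <- as.numeric(gm_reference)
  if (!is.finite(gm_reference) || gm_reference <= 0)
    stop("gm_reference must be > 0")
  y <- pmin(pmax(x / (2 * gm_reference), 0), 1)
  y[background] <- 0
  out <- volume3d(array(y, dim(x)), vol$spacing, vol$origin)
  out$gm_reference <- gm_reference
  out$background <- background
  class(out) <- c("normalized_volume", "volume3d")
  out
}

otsu_threshold <- function(x, n_bins = 256L) {
  h <- tabulate(pmin(
    as.integer((x - min(x)) / (diff(range(x)) + 1e-12) * n_bins) + 1L,
    n_bins), n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(n_bins))
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  k <- which.max(replace(sigma_b, !is.finite(sigma_b), -Inf))
  min(x) + k / n_bins * diff(range(x))
}

#' Extract a brain mask
#'
#' With a trained segmenter the mask is its thresholded prediction; the
#' default fallback is an Otsu threshold.  Either way the mask is reduced to
#' its single largest 26-connected component and holes are filled slice-wise.
#'
#' @param vol a [volume3d()].
#' @param segmenter optional trained segmenter (see [fit_detector()]); `NULL`
#'   selects the threshold fallback.
#' @return A binary [label_map()].
#' @export
extract_brain_mask <- function(vol, segmenter = NULL) {
  stopifnot(inherits(vol, "volume3d"))
  if (is.null(segmenter)) {
    if (all(vol$data == 0)) stop("no brain found: volume is identically zero")
    fg <- vol$data > otsu_threshold(vol$data)
  } else {
    fg <- predict_probabilities(segmenter, vol$data) >= 0.5
  }
  if (!any(fg)) stop("no brain found: empty foreground mask")
  dims <- dim(vol$data)
  lab <- cpp_label_components(as.integer(fg), dims)
  counts <- tabulate(lab)
  keep <- which.max(counts)
  mask <- as.integer(lab == keep)
  mask <- cpp_fill_holes_slicewise(mask, dims)
  label_map(array(mask, dims), vol$spacing, vol$origin)
}

#' Crop a volume to its brain bounding box
#'
#' @param vol a [volume3d()].
#' @param mask a nonempty binary [label_map()] on the same grid.
#' @param margin_voxels padding added to every box face (clamped to the
#'   grid).
#' @return A list with `volume` (the cropped [volume3d()], origin updated)
#'   and `box` (the [bounding_box()] in native voxel indices).
#' @export
crop_to_brain <- function(vol, mask, margin_voxels = 2L) {
  stopifnot(inherits(vol, "volume3d"))
  box <- mask_bounding_box(mask$data)
  if (is.null(box)) stop("empty brain mask")
  box <- expand_box(box, margin_voxels, dim(vol$data))
  cropped <- volume3d(box_slice(vol$data, box), vol$spacing,
                      vol$origin + box$min * vol$spacing)
  list(volume = cropped, box = box)
}

# place a cropped array back onto the native grid (integer bookkeeping)
uncrop_array <- function(arr, box, dims, fill = 0L) {
  out <- array(fill, dims)
  out[(box$min[1] + 1):box$max[1],
      (box$min[2] + 1):box$max[2],
      (box$min[3] + 1):box$max[3]] <- arr
  out
}

#' Resample a volume into an isotropic zero-padded cube
#'
#' One global scale factor `size / max(physical extent)` is applied to all
#' axes, preserving the aspect ratio; the content is centered in the cube and
#' the rest is zero padding.  Intensities are interpolated trilinearly,
#' labels nearest-neighbor.  The returned record allows exact inverse
#' mapping.
#'
#' @param vol a [volume3d()] or [label_map()].
#' @param size cube edge length in voxels (detector default 192; tiny
#'   profile 64).
#' @param labels resample with nearest-neighbor (forced for [label_map()]s).
#' @return A list with `volume` (the cube) and `record` (geometry for
#'   [cube_to_native()]).
#' @export
resample_isotropic_cube <- function(vol, size = 192L, labels = NULL) {
  stopifnot(inherits(vol, "volume3d"), size >= 8L)
  if (is.null(labels)) labels <- inherits(vol, "label_map")
  dims <- dim(vol$data)
  extent <- dims * vol$spacing
  out_sp <- max(extent) / size
  content <- pmin(as.integer(round(extent / out_sp)), size)
  offset <- (size - content) %/% 2L
  # cube voxel u -> input voxel coordinate
  scale <- out_sp / vol$spacing
  shift <- (0.5 - offset) * scale - 0.5
  A <- cbind(diag(scale), shift)
  res <- cpp_resample_affine(as.numeric(vol$data), dims, A,
                             rep(size, 3L), labels, 0)
  record <- list(size = as.integer(size), out_spacing = out_sp,
                 offset_vox = offset, content_dims = content,
                 in_dims = dims, in_spacing = vol$spacing,
                 in_origin = vol$origin)
  cube <- if (labels)
    label_map(array(as.integer(round(res)), rep(size, 3L)), rep(out_sp, 3))
  else volume3d(array(res, rep(size, 3L)), rep(out_sp, 3))
  list(volume = cube, record = record)
}

#' Map a cube-space label map back to the native grid
#'
#' Exact inverse of the [resample_isotropic_cube()] geometry
#' (nearest-neighbor).
#'
#' @param cube_labels [label_map()] in cube space.
#' @param record the resampling record.
#' @return A [label_map()] on the native grid.
#' @export
cube_to_native <- function(cube_labels, record) {
  stopifnot(inherits(cube_labels, "volume3d"))
  # input voxel x -> cube voxel coordinate
  scale <- record$in_spacing / record$out_spacing
  shift <- (0.5 * record$in_spacing / record$out_spacing) +
    record$offset_vox - 0.5
  A <- cbind(diag(scale), shift)
  res <- cpp_resample_affine(as.numeric(cube_labels$data),
                             dim(cube_labels$data), A,
                             record$in_dims, TRUE, 0)
  label_map(array(as.integer(round(res)), record$in_dims),
            record$in_spacing, record$in_origin)
}
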