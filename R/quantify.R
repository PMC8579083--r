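# Per-lesion volumetry and longest axial diameter.

#' Measure lesion volume
#'
#' Voxel count times the voxel volume `sx * sy * sz` (in-plane spacings
#' times slice thickness), exact arithmetic.
#'
#' @param n_voxels positive voxel count (or a voxel index matrix, whose rows
#'   are counted).
#' @param spacing voxel spacing (mm).
#' @return Volume in mm^3.
#' @export
measure_volume <- function(n_voxels, spacing) {
  if (is.matrix(n_voxels)) n_voxels <- nrow(n_voxels)
  if (length(n_voxels) != 1L || n_voxels < 1) stop("empty lesion voxel set")
  n_voxels * prod(spacing[1:3])
}

#' Measure the longest axial diameter of a lesion
#'
#' For every axial (z) slice containing the lesion, the maximal pairwise
#' Euclidean distance between in-plane voxel centers is computed and the
#' mean in-plane spacing is added as an outer-edge correction (a single
#' voxel thus measures one pixel across).  The maximum over slices is
#' returned.
#'
#' @param voxels n x 3 matrix of 0-based voxel indices.
#' @param spacing voxel spacing (mm).
#' @return Longest axial diameter in mm.
#' @export
measure_longest_axial_diameter <- function(voxels, spacing) {
  voxels <- matrix(voxels, ncol = 3)
  if (nrow(voxels) == 0L) stop("empty lesion voxel set")
  edge <- mean(spacing[1:2])
  best <- 0
  for (z in unique(voxels[, 3])) {
    pts <- voxels[voxels[, 3] == z, 1:2, drop = FALSE]
    pts <- cbind(pts[, 1] * spacing[1], pts[, 2] * spacing[2])
    if (nrow(pts) == 1L) { best <- max(best, 0); next }
    if (nrow(pts) > 3L) {
      hull <- grDevices::chull(pts)
      pts <- pts[hull, , drop = FALSE]
    }
    d2 <- max(as.matrix(stats::dist(pts)))
    best <- max(best, d2)
  }
  best + edge
}

#' Build per-lesion records from a label map
#'
#' @param labels a [label_map()].
#' @return A data.frame with one row per lesion: id, voxel count, volume
#'   (mm^3), longest axial diameter (mm), world centroid (mm) and slice
#'   extent.
#' @export
lesion_records <- function(labels) {
  stopifnot(inherits(labels, "volume3d"))
  arr <- labels$data
  sp <- labels$spacing
  ids <- sort(unique(arr[arr > 0L]))
  if (length(ids) == 0L)
    return(data.frame(id = integer(), voxels = integer(),
                      volume_mm3 = numeric(), diameter_mm = numeric(),
                      centroid_x_mm = numeric(), centroid_y_mm = numeric(),
                      centroid_z_mm = numeric(), n_slices = integer()))
  do.call(rbind, lapply(ids, function(id) {
    vox <- which(arr == id, arr.ind = TRUE) - 1L  # 0-based
    cen <- voxel_to_world(colMeans(vox), labels)
    data.frame(id = as.integer(id), voxels = nrow(vox),
               volume_mm3 = measure_volume(nrow(vox), sp),
               diameter_mm = measure_longest_axial_diameter(vox, sp),
               centroid_x_mm = cen[1], centroid_y_mm = cen[2],
               centroid_z_mm = cen[3],
               n_slices = length(unique(vox[, 3])))
  }))
}

#' Write a lesion table as CSV
#' @param records data.frame from [lesion_records()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_lesion_table <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}
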