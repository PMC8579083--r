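#' @useDynLib metrano, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median optim qbeta quantile rnorm runif sd setNames
#' @importFrom utils head read.csv write.csv
NULL

# ---- core data model -------------------------------------------------------
#
# Geometry conventions used throughout the package:
#   * voxel indices are 0-based, the axis order is (x, y, z) with z the axial
#     (slice) direction;
#   * the world coordinate of the CENTER of voxel (i, j, k) is
#     origin + (i, j, k) * spacing;
#   * bounding boxes are half-open [min, max) in 0-based voxel indices.

#' Construct a 3D volume
#'
#' A `volume3d` bundles a 3D intensity array with its voxel spacing (mm) and
#' the world coordinate of the center of voxel (0,0,0).  All pipeline stages
#' operate on this container.
#'
#' @param data 3D numeric array, axis order (x, y, z), z axial.
#' @param spacing numeric length-3, voxel size in mm per axis; all > 0.
#' @param origin numeric length-3, world coordinates (mm) of voxel (0,0,0).
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("expected 3D volume: data must be a 3-dimensional array")
  if (any(dim(data) < 1L)) stop("each dimension must be >= 1")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three finite positive values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be three finite values (mm)")
  if (any(!is.finite(data)))
    stop("volume contains non-finite voxels")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "volume3d")
}

#' Construct a label map sharing a volume's geometry
#'
#' Label maps are non-negative integer grids; 0 is background and lesion
#' labels are positive integers.
#'
#' @param labels 3D integer array (or coercible).
#' @param spacing,origin geometry, as in [volume3d()].
#' @return An object of class `label_map` (also a `volume3d`).
#' @export
label_map <- function(labels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  storage.mode(labels) <- "integer"
  if (any(labels < 0L, na.rm = TRUE)) stop("labels must be non-negative")
  v <- volume3d(labels, spacing, origin)
  class(v) <- c("label_map", "volume3d")
  v
}

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm, origin (%s) mm\n",
              class(x)[1], paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$data)

# world coordinate (mm) of 0-based voxel indices; idx is an n x 3 matrix
voxel_to_world <- function(idx, vol) {
  idx <- matrix(idx, ncol = 3)
  sweep(sweep(idx, 2, vol$spacing, `*`), 2, vol$origin, `+`)
}

same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < tol)
}

# ---- bounding boxes --------------------------------------------------------

#' Create a bounding box
#'
#' Boxes are half-open `[min, max)` in 0-based voxel indices.
#'
#' @param min_corner,max_corner integer length-3; `min_corner < max_corner`
#'   on every axis.
#' @return An object of class `bounding_box`.
#' @export
bounding_box <- function(min_corner, max_corner) {
  min_corner <- as.integer(min_corner)
  max_corner <- as.integer(max_corner)
  if (length(min_corner) != 3L || length(max_corner) != 3L)
    stop("box corners must have length 3")
  if (any(min_corner >= max_corner))
    stop("bounding box must satisfy min < max on every axis")
  structure(list(min = min_corner, max = max_corner), class = "bounding_box")
}

# tight box of a logical/positive mask array (0-based, half-open); NULL if empty
mask_bounding_box <- function(mask) {
  pos <- which(mask > 0, arr.ind = TRUE)
  if (nrow(pos) == 0L) return(NULL)
  bounding_box(apply(pos, 2, min) - 1L, apply(pos, 2, max))
}

# expand by margin voxels and clamp to grid dims
expand_box <- function(box, margin, dims) {
  margin <- as.integer(rep(margin, length.out = 3))
  bounding_box(pmax(box$min - margin, 0L),
               pmin(box$max + margin, as.integer(dims)))
}

box_slice <- function(arr, box) {
  arr[(box$min[1] + 1):box$max[1],
      (box$min[2] + 1):box$max[2],
      (box$min[3] + 1):box$max[3], drop = FALSE]
}

# ---- NIfTI I/O -------------------------------------------------------------

#' Read a 3D volume from a NIfTI-1 file
#'
#' Spacing and origin are taken from the file header (sform/qform).  The data
#' array is kept in the file's stored axis order, interpreted as (x, y, z)
#' with z axial.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param as_labels if `TRUE`, return a [label_map()] (integer data).
#' @return A [volume3d()] or [label_map()].
#' @export
read_volume <- function(path, as_labels = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) dim(img) <- d[1:3]
  else if (length(d) != 3L)
    stop("expected 3D volume, got ", length(d), "D image: ", path)
  xf <- RNifti::xform(img)
  origin <- as.numeric(xf[1:3, 4])
  spacing <- RNifti::pixdim(img)[1:3]
  arr <- array(as.numeric(img), dim = dim(img))
  if (any(!is.finite(arr))) stop("volume contains non-finite voxels: ", path)
  if (as_labels) label_map(round(arr), spacing, origin)
  else volume3d(arr, spacing, origin)
}

#' Write a volume or label map to a NIfTI-1 file
#'
#' Integer label maps round-trip bit-exactly; float volumes round-trip within
#' single-precision accuracy.
#'
#' @param vol a [volume3d()] or [label_map()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume3d"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  if (file.access(dir, 2) != 0) stop("directory not writable: ", dir)
  is_int <- inherits(vol, "label_map") || is.integer(vol$data)
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  m <- structure(rbind(cbind(diag(vol$spacing), vol$origin), c(0, 0, 0, 1)),
                 code = 2L)
  RNifti::qform(img) <- m
  RNifti::sform(img) <- m
  RNifti::writeNifti(img, path,
                     datatype = if (is_int) "int32" else "double")
  invisible(path)
}
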