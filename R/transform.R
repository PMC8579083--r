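# Similarity transforms: rigid rotation + translation + one isotropic scale.
#
# A transform maps FIXED-image world coordinates to MOVING-image world
# coordinates (the resampling convention):  p' = c + s * R * (p - c) + t
# with rotation R composed from extrinsic Euler angles in fixed X-Y-Z order,
# R = Rz(az) %*% Ry(ay) %*% Rx(ax), angles in degrees.

#' Construct a similarity transform
#'
#' The 7-parameter inter-scan transform: three rotations (degrees, fixed XYZ
#' order), three translations (mm) and one isotropic scale, about a center of
#' rotation in world coordinates.  Maps fixed-image world coordinates into the
#' moving image's frame: `p' = center + scale * R %*% (p - center) + t`.
#'
#' @param angles_deg numeric length-3 Euler angles (degrees).
#' @param translation_mm numeric length-3 (mm).
#' @param scale positive isotropic scale factor.
#' @param center_mm center of rotation, world mm.
#' @return An object of class `similarity_transform`.
#' @export
similarity_transform <- function(angles_deg = c(0, 0, 0),
                                 translation_mm = c(0, 0, 0),
                                 scale = 1,
                                 center_mm = c(0, 0, 0)) {
  stopifnot(length(angles_deg) == 3L, length(translation_mm) == 3L,
            length(center_mm) == 3L, length(scale) == 1L)
  if (!is.finite(scale) || scale <= 0) stop("scale must be > 0")
  structure(list(angles_deg = as.numeric(angles_deg),
                 translation_mm = as.numeric(translation_mm),
                 scale = as.numeric(scale),
                 center_mm = as.numeric(center_mm)),
            class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf(
    "<similarity_transform> angles (%s) deg, t (%s) mm, scale %.5f\n",
    paste(signif(x$angles_deg, 4), collapse = ", "),
    paste(signif(x$translation_mm, 4), collapse = ", "), x$scale))
  invisible(x)
}

rotation_matrix_xyz <- function(angles_deg) {
  a <- angles_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

euler_angles_xyz <- function(R) {
  ay <- asin(max(-1, min(1, -R[3, 1])))
  ax <- atan2(R[3, 2], R[3, 3])
  az <- atan2(R[2, 1], R[1, 1])
  c(ax, ay, az) * 180 / pi
}

# affine (A, d) form with p' = A %*% p + d
transform_affine <- function(tr) {
  A <- tr$scale * rotation_matrix_xyz(tr$angles_deg)
  d <- tr$center_mm + tr$translation_mm - A %*% tr$center_mm
  list(A = A, d = as.numeric(d))
}

affine_to_transform <- function(A, d, center_mm = c(0, 0, 0)) {
  s <- det(A)^(1 / 3)
  R <- A / s
  t <- d + A %*% center_mm - center_mm
  similarity_transform(euler_angles_xyz(R), as.numeric(t), s, center_mm)
}

#' Apply a similarity transform to world points
#'
#' @param transform a [similarity_transform()].
#' @param points n x 3 matrix of world coordinates (mm).
#' @return n x 3 matrix of mapped coordinates.
#' @export
apply_transform <- function(transform, points) {
  af <- transform_affine(transform)
  points <- matrix(points, ncol = 3)
  t(af$A %*% t(points) + af$d)
}

#' Invert a similarity transform
#' @param transform a [similarity_transform()].
#' @return The inverse transform (same rotation center).
#' @export
invert_transform <- function(transform) {
  af <- transform_affine(transform)
  Ai <- t(af$A / transform$scale) / transform$scale  # (sR)^-1 = R^T / s
  affine_to_transform(Ai, as.numeric(-Ai %*% af$d), transform$center_mm)
}

#' Compose two similarity transforms
#'
#' `compose_transforms(t2, t1)` applies `t1` first: the result maps
#' `p -> t2(t1(p))`.
#' @param t2,t1 [similarity_transform()] objects.
#' @return The composed transform (rotation center of `t1`).
#' @export
compose_transforms <- function(t2, t1) {
  a2 <- transform_affine(t2); a1 <- transform_affine(t1)
  affine_to_transform(a2$A %*% a1$A, as.numeric(a2$A %*% a1$d + a2$d),
                      t1$center_mm)
}

#' Write / read a transform as JSON
#' @param transform a [similarity_transform()].
#' @param path output file.
#' @return `path` (writer) or the transform (reader).
#' @export
write_transform <- function(transform, path) {
  jsonlite::write_json(unclass(transform), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  similarity_transform(x$angles_deg, x$translation_mm, x$scale, x$center_mm)
}
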