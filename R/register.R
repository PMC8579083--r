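# Similarity registration between serial scans and lesion-level matching.

# separable binomial (1,2,1)/4 smoothing, edge-replicated
smooth_volume <- function(vol, passes = 2L) {
  a <- vol$data
  for (p in seq_len(passes)) for (ax in 1:3) {
    n <- dim(a)[ax]
    if (n < 2L) next
    lo <- c(1, seq_len(n - 1)); hi <- c(seq_len(n - 1) + 1, n)
    if (ax == 1) a <- (a[lo, , , drop = FALSE] + 2 * a +
                         a[hi, , , drop = FALSE]) / 4
    else if (ax == 2) a <- (a[, lo, , drop = FALSE] + 2 * a +
                              a[, hi, , drop = FALSE]) / 4
    else a <- (a[, , lo, drop = FALSE] + 2 * a +
                 a[, , hi, drop = FALSE]) / 4
  }
  volume3d(a, vol$spacing, vol$origin)
}

downsample_volume <- function(vol, factor) {
  if (factor == 1L) return(vol)
  dims <- dim(vol$data)
  out_dims <- pmax(dims %/% factor, 1L)
  A <- cbind(diag(rep(factor, 3)), rep((factor - 1) / 2, 3))
  res <- cpp_resample_affine(as.numeric(vol$data), dims, A, out_dims,
                             FALSE, 0)
  volume3d(array(res, out_dims), vol$spacing * factor, vol$origin)
}

# 3x4 voxel-to-voxel map: fixed voxel -> world -> transform -> moving voxel
transform_to_voxel_affine <- function(transform, fixed, moving) {
  af <- transform_affine(transform)
  Sf <- diag(fixed$spacing); Sm_inv <- diag(1 / moving$spacing)
  A <- Sm_inv %*% af$A %*% Sf
  d <- Sm_inv %*% (af$A %*% fixed$origin + af$d - moving$origin)
  cbind(A, d)
}

#' Resample a moving volume onto a fixed grid through a transform
#'
#' @param moving a [volume3d()].
#' @param fixed a [volume3d()] defining the output grid.
#' @param transform a [similarity_transform()] mapping fixed world
#'   coordinates to moving world coordinates.
#' @param nearest nearest-neighbor interpolation (labels).
#' @return A [volume3d()] (or [label_map()]) on the fixed grid.
#' @export
resample_through_transform <- function(moving, fixed, transform,
                                       nearest = FALSE) {
  A <- transform_to_voxel_affine(transform, fixed, moving)
  res <- cpp_resample_affine(as.numeric(moving$data), dim(moving$data), A,
                             dim(fixed$data), nearest, 0)
  if (nearest)
    label_map(array(as.integer(round(res)), dim(fixed$data)),
              fixed$spacing, fixed$origin)
  else volume3d(array(res, dim(fixed$data)), fixed$spacing, fixed$origin)
}

msd_metric <- function(par, fixed, moving, center) {
  tr <- similarity_transform(par[1:3], par[4:6], par[7], center)
  A <- transform_to_voxel_affine(tr, fixed, moving)
  res <- cpp_resample_affine(as.numeric(moving$data), dim(moving$data), A,
                             dim(fixed$data), FALSE, 0)
  mean((as.numeric(fixed$data) - res)^2)
}

#' Register two volumes with a similarity transform
#'
#' Multi-resolution iterative optimization of a mean-squared-difference
#' metric over the 7 similarity parameters (3 rotations, 3 translations, 1
#' isotropic scale), Nelder-Mead at each pyramid level.  The rotation
#' center is the intensity centroid of the fixed image.
#'
#' @param fixed,moving [volume3d()] objects, brain-cropped and normalized.
#' @param levels downsampling factors of the pyramid, coarse to fine.
#' @param max_iter Nelder-Mead iterations per level (recycled).
#' @param rigid freeze the scale at 1 (rigid-only mode).
#' @param smooth_passes binomial smoothing passes applied to both inputs
#'   before the pyramid (scale-space regularization; keeps the noise from
#'   biasing the optimum at the finest level).
#' @param polish quasi-Newton (BFGS) refinement after the simplex at the
#'   finest level; needed for sub-degree parameter recovery, skippable
#'   when only millimeter-level alignment is required.
#' @param allow_spacing_mismatch proceed even if voxel spacings differ.
#' @return A [similarity_transform()] with attributes `metric` (final MSD),
#'   `trace` (per-level metric) and `converged`.
#' @export
register_similarity <- function(fixed, moving, levels = c(4L, 2L, 1L),
                                max_iter = c(200L, 200L, 400L),
                                rigid = FALSE, smooth_passes = 6L,
                                polish = TRUE,
                                allow_spacing_mismatch = FALSE) {
  stopifnot(inherits(fixed, "volume3d"), inherits(moving, "volume3d"))
  if (!allow_spacing_mismatch &&
      any(abs(fixed$spacing - moving$spacing) > 1e-6))
    stop("voxel spacings differ; resample first or set ",
         "allow_spacing_mismatch = TRUE")
  max_iter <- rep(max_iter, length.out = length(levels))
  w <- as.numeric(fixed$data)
  idx <- which(w > 0, arr.ind = FALSE)
  vox <- arrayInd(idx, dim(fixed$data)) - 1L
  center <- as.numeric(colSums(vox * w[idx]) / sum(w[idx]))
  center <- fixed$origin + center * fixed$spacing
  par <- c(0, 0, 0, 0, 0, 0, 1)
  parscale <- c(1, 1, 1, 1, 1, 1, 0.01)
  trace <- data.frame()
  if (smooth_passes > 0L) {
    fixed <- smooth_volume(fixed, smooth_passes)
    moving <- smooth_volume(moving, smooth_passes)
  }
  for (li in seq_along(levels)) {
    f <- downsample_volume(fixed, levels[li])
    m <- downsample_volume(moving, levels[li])
    obj <- if (rigid)
      function(p) msd_metric(c(p, 1), f, m, center)
    else
      function(p) msd_metric(p, f, m, center)
    p0 <- if (rigid) par[1:6] else par
    ps <- if (rigid) parscale[1:6] else parscale
    init_metric <- obj(p0)
    opt <- optim(p0, obj, method = "Nelder-Mead",
                 control = list(maxit = max_iter[li], parscale = ps,
                                reltol = 1e-10))
    if (polish && li == length(levels)) {
      # quasi-Newton polish at the finest level: the simplex can stall
      # short of the optimum in 6-7 dimensions
      polish <- optim(opt$par, obj, method = "BFGS",
                      control = list(maxit = 60L, parscale = ps,
                                     ndeps = rep(1e-3, length(ps)),
                                     reltol = 1e-12))
      if (polish$value <= opt$value) opt <- polish
    }
    if (opt$value > init_metric + 1e-12) {
      stop(sprintf(paste0(
        "registration diverged at pyramid level %d: metric %.6g -> %.6g\n",
        "trace:\n%s"), levels[li], init_metric, opt$value,
        paste(utils::capture.output(print(trace)), collapse = "\n")))
    }
    par <- if (rigid) c(opt$par, 1) else opt$par
    trace <- rbind(trace, data.frame(level = levels[li],
                                     initial = init_metric,
                                     final = opt$value))
  }
  out <- similarity_transform(par[1:3], par[4:6], par[7], center)
  attr(out, "metric") <- trace$final[nrow(trace)]
  attr(out, "trace") <- trace
  attr(out, "converged") <- TRUE
  out
}

# ---- assignment ------------------------------------------------------------

# O(n^3) assignment by shortest augmenting paths with potentials (the
# Hungarian algorithm); returns, for each row, the assigned column index.
# Rectangular inputs are padded to square with a large cost.
hungarian_assign <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0L || m == 0L) return(rep(NA_integer_, n))
  k <- max(n, m)
  pad <- max(cost[is.finite(cost)], 0) * (k + 1) + 1
  C <- matrix(pad, k, k)
  C[seq_len(n), seq_len(m)] <- ifelse(is.finite(cost), cost, pad)
  # arrays indexed 1..k+1 where index 1 is the virtual column 0
  u <- numeric(k + 1); v <- numeric(k + 1)
  p <- integer(k + 1)  # p[j]: row currently matched to column j-1 (0 = none)
  way <- integer(k + 1)
  for (i in seq_len(k)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(Inf, k + 1)
    used <- rep(FALSE, k + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0L
      for (j in 2:(k + 1)) {
        if (used[j]) next
        cur <- C[i0, j - 1] - u[i0 + 1] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in seq_len(k + 1)) {
        if (used[j]) { u[p[j] + 1] <- u[p[j] + 1] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  assign <- rep(NA_integer_, n)
  for (j in 2:(k + 1)) {
    if (p[j] >= 1L && p[j] <= n && (j - 1L) <= m) assign[p[j]] <- j - 1L
  }
  assign
}

#' Match lesions between baseline and follow-up
#'
#' Baseline centroids are mapped through the inter-scan transform; candidate
#' pairs closer than `max(tolerance_mm, r_b + r_f)` (equivalent-sphere
#' radii) are assigned one-to-one by minimal total distance (Hungarian
#' algorithm).  Unmatched follow-up lesions are "new", unmatched baseline
#' lesions "disappeared".
#'
#' @param baseline_records,followup_records lesion tables (see
#'   [lesion_records()] / [truth_lesion_records()]) with world centroids and
#'   volumes.
#' @param transform a [similarity_transform()] mapping baseline world
#'   coordinates into the follow-up frame.
#' @param tolerance_mm distance gate floor (mm).
#' @return An object of class `lesion_match_set`: `pairs` (data.frame with
#'   baseline_id, followup_id, residual_mm), `new` and `disappeared` id
#'   vectors.
#' @export
match_lesions <- function(baseline_records, followup_records, transform,
                          tolerance_mm = 5) {
  b <- baseline_records; f <- followup_records
  empty <- data.frame(baseline_id = integer(), followup_id = integer(),
                      residual_mm = numeric())
  out <- structure(list(pairs = empty, new = f$id, disappeared = b$id),
                   class = "lesion_match_set")
  if (nrow(b) == 0L || nrow(f) == 0L) return(out)
  bc <- apply_transform(transform,
                        as.matrix(b[, c("centroid_x_mm", "centroid_y_mm",
                                        "centroid_z_mm")]))
  fc <- as.matrix(f[, c("centroid_x_mm", "centroid_y_mm", "centroid_z_mm")])
  D <- sqrt(pmax(outer(rowSums(bc^2), rowSums(fc^2), `+`) -
                   2 * bc %*% t(fc), 0))
  eqr <- function(v) (3 * v / (4 * pi))^(1 / 3)
  gate <- outer(eqr(b$volume_mm3), eqr(f$volume_mm3), `+`)
  gate <- pmax(gate, tolerance_mm)
  cost <- ifelse(D < gate, D, Inf)
  assign <- hungarian_assign(cost)
  pairs <- empty
  for (i in seq_along(assign)) {
    j <- assign[i]
    if (!is.na(j) && is.finite(cost[i, j]))
      pairs <- rbind(pairs, data.frame(baseline_id = b$id[i],
                                       followup_id = f$id[j],
                                       residual_mm = D[i, j]))
  }
  structure(list(pairs = pairs,
                 new = setdiff(f$id, pairs$followup_id),
                 disappeared = setdiff(b$id, pairs$baseline_id)),
            class = "lesion_match_set")
}

#' Fraction of true lesion correspondences recovered over a cohort
#'
#' Mirrors the serial-MRI matching success rate: a true pair is recovered
#' when the match set pairs exactly the corresponding baseline and follow-up
#' ids.
#'
#' @param match_sets list of `lesion_match_set` objects.
#' @param truth_pairs list of data.frames with columns `baseline_id`,
#'   `followup_id` (the true correspondences per study pair).
#' @return Fraction in `[0, 1]`, with attributes `n_true` and `n_recovered`.
#' @export
registration_success_rate <- function(match_sets, truth_pairs) {
  if (length(match_sets) == 0L) stop("empty cohort")
  stopifnot(length(match_sets) == length(truth_pairs))
  n_true <- 0L; n_rec <- 0L
  for (i in seq_along(match_sets)) {
    tp <- truth_pairs[[i]]
    mp <- match_sets[[i]]$pairs
    n_true <- n_true + nrow(tp)
    if (nrow(tp) == 0L) next
    key_t <- paste(tp$baseline_id, tp$followup_id)
    key_m <- paste(mp$baseline_id, mp$followup_id)
    n_rec <- n_rec + sum(key_t %in% key_m)
  }
  if (n_true == 0L) stop("cohort has no true correspondences")
  out <- n_rec / n_true
  attr(out, "n_true") <- n_true
  attr(out, "n_recovered") <- n_rec
  out
}
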