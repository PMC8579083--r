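# Independent brute-force reference implementations used to cross-check the
# production code, plus small shared fixtures.

# flood-fill 26-connected labelling, pure R (reference for the union-find
# implementation)
flood_fill_label <- function(mask) {
  dims <- dim(mask)
  lab <- array(0L, dims)
  nxt <- 0L
  idx_ok <- function(v) all(v >= 1L) && all(v <= dims)
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offsets <- offsets[rowSums(abs(offsets)) > 0, ]
  for (i in which(mask > 0)) {
    if (lab[i] > 0L) next
    nxt <- nxt + 1L
    queue <- list(arrayInd(i, dims)[1, ])
    lab[i] <- nxt
    while (length(queue)) {
      v <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      for (r in seq_len(nrow(offsets))) {
        w <- v + offsets[r, ]
        if (!idx_ok(w)) next
        if (mask[w[1], w[2], w[3]] > 0 && lab[w[1], w[2], w[3]] == 0L) {
          lab[w[1], w[2], w[3]] <- nxt
          queue[[length(queue) + 1L]] <- w
        }
      }
    }
  }
  lab
}

# all-pairs longest axial diameter (no convex hull shortcut)
brute_diameter <- function(voxels, spacing) {
  voxels <- matrix(voxels, ncol = 3)
  best <- 0
  for (z in unique(voxels[, 3])) {
    pts <- voxels[voxels[, 3] == z, 1:2, drop = FALSE]
    pts <- cbind(pts[, 1] * spacing[1], pts[, 2] * spacing[2])
    n <- nrow(pts)
    if (n >= 2) for (a in 1:(n - 1)) for (b in (a + 1):n)
      best <- max(best, sqrt(sum((pts[a, ] - pts[b, ])^2)))
  }
  best + mean(spacing[1:2])
}

# double-loop weighted kappa
brute_kappa <- function(tab, w) {
  k <- nrow(tab); N <- sum(tab)
  po <- 0; pe <- 0
  r <- rowSums(tab); cl <- colSums(tab)
  for (i in 1:k) for (j in 1:k) {
    po <- po + w[i, j] * tab[i, j] / N
    pe <- pe + w[i, j] * r[i] * cl[j] / N^2
  }
  (po - pe) / (1 - pe)
}

# table-driven reference for the response rules; boundaries are inclusive
# (up to float rounding of the ratio itself)
oracle_response_1d <- function(sb, sf, new_lesion) {
  if (new_lesion) return("PD")
  if (sf == 0) return("CR")
  d <- (sf - sb) / sb
  if (d <= -0.30 + 1e-9) return("PR")
  if (d >= 0.20 - 1e-9) return("PD")
  "SD"
}
oracle_response_vol <- function(vb, vf, new_lesion) {
  if (new_lesion) return("PD")
  if (vf == 0) return("CR")
  r <- vf / vb
  if (r <= 0.343 + 1e-9) return("PR")
  if (r >= 1.728 - 1e-9) return("PD")
  "SD"
}

# brute-force optimal assignment by permutation enumeration (n <= 7)
brute_assign <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  best <- NULL; best_cost <- Inf
  for (p in perms(seq_len(m))) {
    sel <- p[seq_len(n)]
    cc <- sum(cost[cbind(seq_len(n), sel)])
    if (cc < best_cost) { best_cost <- cc; best <- sel }
  }
  list(assign = best, cost = best_cost)
}

# small shared phantom (memoised per test run)
tiny_case <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_phantom(phantom_config("tiny"), seed = 7L)
    cache
  }
})
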