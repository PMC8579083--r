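# Detection, segmentation and agreement metrics.

#' Lesion-wise comparison of a predicted and a truth label map
#'
#' A truth lesion counts as detected iff at least one predicted voxel
#' overlaps it (any-voxel hit criterion); a predicted component overlapping
#' no truth lesion is one false positive.  Per-lesion Dice coefficients are
#' computed between each truth lesion and the union of predicted components
#' overlapping it.
#'
#' @param pred,truth [label_map()]s on the same grid.
#' @param hit_criterion `"overlap"` (any voxel) or `"centroid"` (predicted
#'   component centroid inside the truth lesion).
#' @return An object of class `detection_eval`: per-lesion table (id,
#'   diameter_mm, detected, dsc), `fp_count`, `sensitivity`.
#' @export
match_detections_to_truth <- function(pred, truth,
                                      hit_criterion = c("overlap",
                                                        "centroid")) {
  hit_criterion <- match.arg(hit_criterion)
  if (!same_geometry(pred, truth)) stop("prediction/truth grid mismatch")
  pa <- pred$data; ta <- truth$data
  truth_ids <- sort(unique(ta[ta > 0L]))
  pred_ids <- sort(unique(pa[pa > 0L]))
  trecs <- lesion_records(truth)
  hit_of_pred <- setNames(rep(FALSE, length(pred_ids)),
                          as.character(pred_ids))
  lesions <- data.frame()
  for (id in truth_ids) {
    tmask <- ta == id
    over <- unique(pa[tmask & pa > 0L])
    if (hit_criterion == "centroid" && length(over)) {
      keep <- logical(0)
      for (pid in over) {
        cen <- round(colMeans(which(pa == pid, arr.ind = TRUE)))
        keep <- c(keep, ta[cen[1], cen[2], cen[3]] == id)
      }
      over <- over[keep]
    }
    detected <- length(over) > 0L
    dsc <- if (detected)
      dice_coefficient(array(pa %in% over, dim(pa)), tmask) else NA_real_
    hit_of_pred[as.character(over)] <- TRUE
    lesions <- rbind(lesions, data.frame(
      id = as.integer(id),
      diameter_mm = trecs$diameter_mm[trecs$id == id],
      detected = detected, dsc = dsc))
  }
  fp <- sum(!hit_of_pred)
  structure(list(lesions = lesions, fp_count = fp,
                 n_truth = length(truth_ids),
                 n_detected = sum(lesions$detected),
                 sensitivity = if (length(truth_ids))
                   mean(lesions$detected) else NA_real_),
            class = "detection_eval")
}

#' Sensitivity stratified by lesion size
#'
#' @param evals list of `detection_eval` objects (one per scan).
#' @param bin_edges_mm increasing diameter bin edges; the last bin is
#'   right-open.
#' @param measurable_mm threshold for the aggregate row (default 5 mm).
#' @return A data.frame of per-bin n, detected and sensitivity (NA for
#'   empty bins), with the `>= measurable_mm` aggregate as attributes
#'   `n_measurable`, `detected_measurable`, `sensitivity_measurable`.
#' @export
sensitivity_by_size <- function(evals, bin_edges_mm = c(0, 3, 5, 10, 20,
                                                        Inf),
                                measurable_mm = 5) {
  if (is.unsorted(bin_edges_mm, strictly = TRUE))
    stop("bin edges must be strictly increasing")
  lesions <- do.call(rbind, lapply(evals, function(e) e$lesions))
  bins <- cut(lesions$diameter_mm, bin_edges_mm, right = FALSE)
  tab <- data.frame(bin = levels(bins),
                    n = as.integer(table(bins)),
                    detected = as.integer(tapply(lesions$detected, bins,
                                                 sum, default = 0L)))
  tab$sensitivity <- ifelse(tab$n > 0, tab$detected / tab$n, NA_real_)
  meas <- lesions[lesions$diameter_mm >= measurable_mm, , drop = FALSE]
  attr(tab, "n_measurable") <- nrow(meas)
  attr(tab, "detected_measurable") <- sum(meas$detected)
  attr(tab, "sensitivity_measurable") <-
    if (nrow(meas)) mean(meas$detected) else NA_real_
  tab
}

#' Dice similarity coefficient
#'
#' `2|P n T| / (|P| + |T|)` between two masks on the same grid.
#'
#' @param pred,truth logical/0-1 arrays of identical shape; `truth` must be
#'   nonempty.
#' @return DSC in `[0, 1]`.
#' @export
dice_coefficient <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) stop("mask grid mismatch")
  p <- pred > 0; t <- truth > 0
  if (!any(t)) stop("empty truth mask")
  2 * sum(p & t) / (sum(p) + sum(t))
}

#' Weighted Cohen's kappa for ordered categories
#'
#' `kappa_w = (P_o - P_e) / (1 - P_e)` with weights
#' `w_ij = 1 - |i - j|/(k - 1)` (linear, default) or
#' `1 - (|i - j|/(k - 1))^2` (quadratic);
#' `P_o = sum(w * n) / N`, `P_e = sum(w_ij * r_i * c_j) / N^2`.
#'
#' @param table k x k contingency table (rows: rater 1, columns: rater 2),
#'   categories in identical order on both axes.
#' @param weights `"linear"` or `"quadratic"`.
#' @return Kappa, with attributes `P_o`, `P_e` and `agreement` (the
#'   conventional verbal category: poor < 0, slight 0-0.20, fair 0.21-0.40,
#'   moderate 0.41-0.60, substantial 0.61-0.80, almost perfect > 0.80).
#' @export
weighted_kappa <- function(table, weights = c("linear", "quadratic")) {
  weights <- match.arg(weights)
  table <- as.matrix(table)
  k <- nrow(table)
  if (k != ncol(table) || k < 2L) stop("table must be square, k >= 2")
  if (any(table < 0)) stop("negative counts")
  N <- sum(table)
  if (N <= 0) stop("empty table")
  d <- abs(outer(seq_len(k), seq_len(k), `-`)) / (k - 1)
  w <- if (weights == "linear") 1 - d else 1 - d^2
  po <- sum(w * table) / N
  pe <- sum(w * outer(rowSums(table), colSums(table))) / N^2
  if (abs(1 - pe) < 1e-12) stop("degenerate marginals: P_e = 1")
  kap <- (po - pe) / (1 - pe)
  attr(kap, "P_o") <- po
  attr(kap, "P_e") <- pe
  attr(kap, "agreement") <- kappa_agreement_category(kap)
  kap
}

#' Verbal agreement category for a kappa value
#' @param kappa numeric kappa.
#' @return One of "poor", "slight", "fair", "moderate", "substantial",
#'   "almost perfect".
#' @export
kappa_agreement_category <- function(kappa) {
  if (kappa < 0) "poor"
  else if (kappa <= 0.20) "slight"
  else if (kappa <= 0.40) "fair"
  else if (kappa <= 0.60) "moderate"
  else if (kappa <= 0.80) "substantial"
  else "almost perfect"
}

#' Binomial proportion confidence interval, in percent
#'
#' Exact (Clopper-Pearson) two-sided interval by default; Wilson score
#' interval by flag.
#'
#' @param successes,trials counts with `0 <= successes <= trials`,
#'   `trials > 0`.
#' @param method `"clopper-pearson"` or `"wilson"`.
#' @param conf_level confidence level.
#' @return Length-2 vector `c(lower, upper)` in percent.
#' @export
proportion_ci <- function(successes, trials,
                          method = c("clopper-pearson", "wilson"),
                          conf_level = 0.95) {
  method <- match.arg(method)
  if (trials <= 0 || successes < 0 || successes > trials)
    stop("invalid counts")
  if (method == "clopper-pearson") {
    ci <- stats::binom.test(successes, trials,
                            conf.level = conf_level)$conf.int
  } else {
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    p <- successes / trials
    den <- 1 + z^2 / trials
    mid <- (p + z^2 / (2 * trials)) / den
    half <- z * sqrt(p * (1 - p) / trials + z^2 / (4 * trials^2)) / den
    ci <- c(mid - half, mid + half)
  }
  100 * as.numeric(ci)
}

#' Bundled RANO-BM agreement tables
#'
#' The packaged 4x4 CR/PR/SD/PD contingency tables (automated assessment in
#' rows, expert ground truth in columns) for the one-dimensional and
#' volumetric bases, from the reference temporal test cohort.
#'
#' @param basis `"one_dimensional"` or `"volumetric"`.
#' @return A 4x4 integer matrix with CR/PR/SD/PD dimnames.
#' @export
rano_agreement_table <- function(basis = c("one_dimensional",
                                           "volumetric")) {
  basis <- match.arg(basis)
  path <- system.file("extdata",
                      paste0("rano_agreement_", basis, ".csv"),
                      package = "metrano", mustWork = TRUE)
  df <- read.csv(path, row.names = 1)
  m <- as.matrix(df)
  dimnames(m) <- list(cad = RANO_CATEGORIES, truth = RANO_CATEGORIES)
  m
}
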