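# Automated treatment-response categorization under modified RANO-BM
# criteria, one-dimensional and volumetric.
#
# The one-dimensional rules compare the sum of longest diameters of up to
# five target lesions: disappearance is complete response (CR), a decrease
# of at least 30% partial response (PR), an increase of at least 20% (or any
# new lesion, regardless of its size) progressive disease (PD), anything
# else stable disease (SD).  The measurability threshold is 5 mm (the
# modified criterion for 1 mm-slice 3D imaging).  Volumetric cutoffs are the
# cubes of the 1D ones (0.7^3 = 0.343, 1.2^3 = 1.728), so that an isotropic
# diameter change maps to the same category on both bases; they are
# configurable.

RANO_CATEGORIES <- c("CR", "PR", "SD", "PD")

#' Select target lesions
#'
#' Measurable lesions (diameter >= `min_diameter_mm`) sorted by diameter
#' descending (ties by volume descending, then id ascending); the first
#' `max_n` become targets.
#'
#' @param records lesion table with `id`, `diameter_mm`, `volume_mm3`.
#' @param max_n maximal number of targets (default 5).
#' @param min_diameter_mm measurability threshold (default 5 mm).
#' @return An object of class `target_set` with `ids`,
#'   `sum_longest_diameters_mm` and `total_volume_mm3` (empty set allowed).
#' @export
select_target_lesions <- function(records, max_n = 5L,
                                  min_diameter_mm = 5) {
  meas <- records[records$diameter_mm >= min_diameter_mm, , drop = FALSE]
  ord <- order(-meas$diameter_mm, -meas$volume_mm3, meas$id)
  meas <- meas[head(ord, max_n), , drop = FALSE]
  structure(list(ids = meas$id,
                 diameters_mm = meas$diameter_mm,
                 sum_longest_diameters_mm = sum(meas$diameter_mm),
                 total_volume_mm3 = sum(meas$volume_mm3)),
            class = "target_set")
}

new_assessment <- function(category, basis, baseline, followup, new_lesion,
                           target_ids = integer()) {
  structure(list(category = category, basis = basis,
                 baseline_sum = baseline, followup_sum = followup,
                 pct_change = if (baseline > 0)
                   100 * (followup - baseline) / baseline else NA_real_,
                 new_lesion = new_lesion, target_ids = target_ids),
            class = "response_assessment")
}

#' @export
print.response_assessment <- function(x, ...) {
  cat(sprintf("<response_assessment> %s (%s): %.4g -> %.4g (%+.1f%%)%s\n",
              x$category, x$basis, x$baseline_sum, x$followup_sum,
              x$pct_change, if (x$new_lesion) ", new lesion" else ""))
  invisible(x)
}

#' One-dimensional RANO-BM response
#'
#' Any new lesion gives PD regardless of size.  Otherwise, with relative
#' change `d = (S_f - S_b)/S_b`: `S_f = 0` (and no remaining measurable
#' disease) gives CR, `d <= -0.30` PR, `d >= +0.20` PD, otherwise SD;
#' boundaries inclusive.
#'
#' @param baseline_sum_mm baseline sum of target diameters (> 0).
#' @param followup_sum_mm follow-up sum over the tracked targets
#'   (disappeared targets contribute 0).
#' @param new_lesion any new lesion present?
#' @param residual_measurable any measurable lesion remaining at follow-up
#'   besides the tracked targets (blocks CR).
#' @param target_ids optional ids stored for provenance.
#' @return A `response_assessment`.
#' @export
assess_response_1d <- function(baseline_sum_mm, followup_sum_mm,
                               new_lesion = FALSE,
                               residual_measurable = FALSE,
                               target_ids = integer()) {
  if (baseline_sum_mm <= 0)
    stop("empty baseline target set: 1D response undefined")
  eps <- 1e-9  # inclusive boundaries are robust to float rounding
  cat <- if (new_lesion) "PD" else {
    d <- (followup_sum_mm - baseline_sum_mm) / baseline_sum_mm
    if (followup_sum_mm == 0 && !residual_measurable) "CR"
    else if (d <= -0.30 + eps) "PR"
    else if (d >= 0.20 - eps) "PD"
    else "SD"
  }
  new_assessment(cat, "one-dimensional", baseline_sum_mm, followup_sum_mm,
                 new_lesion, target_ids)
}

#' Volumetric RANO-BM response
#'
#' Any new lesion gives PD.  Otherwise, with ratio `R = V_f / V_b`:
#' `V_f = 0` gives CR, `R <= pr_ratio` PR, `R >= pd_ratio` PD, otherwise
#' SD; boundaries inclusive.  Default cutoffs are the cubes of the 1D
#' thresholds, stated exactly as 0.343 (= 0.70^3) and 1.728 (= 1.20^3) so
#' the printed boundary values classify inclusively.
#'
#' @param baseline_volume_mm3 baseline target volume (> 0).
#' @param followup_volume_mm3 follow-up target volume.
#' @param new_lesion any new lesion present?
#' @param pr_ratio,pd_ratio volumetric cutoffs.
#' @param target_ids optional ids stored for provenance.
#' @return A `response_assessment`.
#' @export
assess_response_volumetric <- function(baseline_volume_mm3,
                                       followup_volume_mm3,
                                       new_lesion = FALSE,
                                       pr_ratio = 0.343, pd_ratio = 1.728,
                                       target_ids = integer()) {
  if (baseline_volume_mm3 <= 0)
    stop("zero baseline volume: volumetric response undefined")
  eps <- 1e-9
  cat <- if (new_lesion) "PD" else {
    r <- followup_volume_mm3 / baseline_volume_mm3
    if (followup_volume_mm3 == 0) "CR"
    else if (r <= pr_ratio + eps) "PR"
    else if (r >= pd_ratio - eps) "PD"
    else "SD"
  }
  new_assessment(cat, "volumetric", baseline_volume_mm3,
                 followup_volume_mm3, new_lesion, target_ids)
}

#' Assess a baseline/follow-up study pair
#'
#' Targets are selected on the baseline and tracked forward through the
#' lesion match set (no re-selection at follow-up); disappeared targets
#' contribute 0 to the follow-up sums.  Any unmatched follow-up lesion sets
#' the new-lesion flag.
#'
#' @param baseline_records,followup_records lesion tables.
#' @param matches a `lesion_match_set` from [match_lesions()].
#' @param max_targets,min_diameter_mm target selection parameters.
#' @param pr_ratio,pd_ratio volumetric cutoffs.
#' @return A list with `one_dimensional` and `volumetric`
#'   `response_assessment`s plus the baseline `target_set`.
#' @export
assess_study_pair <- function(baseline_records, followup_records, matches,
                              max_targets = 5L, min_diameter_mm = 5,
                              pr_ratio = 0.343, pd_ratio = 1.728) {
  targets <- select_target_lesions(baseline_records, max_targets,
                                   min_diameter_mm)
  if (length(targets$ids) == 0L)
    stop("no measurable baseline lesions: response undefined")
  new_lesion <- length(matches$new) > 0L
  fu_of <- setNames(matches$pairs$followup_id,
                    as.character(matches$pairs$baseline_id))
  s_f <- 0; v_f <- 0
  matched_fu_ids <- integer()
  for (id in targets$ids) {
    j <- fu_of[as.character(id)]
    if (!is.na(j)) {
      row <- followup_records[followup_records$id == j, ]
      s_f <- s_f + row$diameter_mm
      v_f <- v_f + row$volume_mm3
      matched_fu_ids <- c(matched_fu_ids, j)
    }
  }
  other_fu <- followup_records[!(followup_records$id %in% matched_fu_ids), ,
                               drop = FALSE]
  residual <- any(other_fu$diameter_mm >= min_diameter_mm)
  list(one_dimensional = assess_response_1d(
         targets$sum_longest_diameters_mm, s_f, new_lesion, residual,
         targets$ids),
       volumetric = assess_response_volumetric(
         targets$total_volume_mm3, v_f, new_lesion, pr_ratio, pd_ratio,
         targets$ids),
       targets = targets)
}
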