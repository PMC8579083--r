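rec_of <- function(diam, vol = diam^3, id = seq_along(diam)) {
  data.frame(id = id, diameter_mm = diam, volume_mm3 = vol)
}

test_that("target selection applies threshold, ordering and the cap of 5", {
  ts <- select_target_lesions(rec_of(c(12, 11, 9, 8, 6, 5, 4)))
  expect_equal(ts$diameters_mm, c(12, 11, 9, 8, 6))
  expect_equal(ts$sum_longest_diameters_mm, 46)
  ts2 <- select_target_lesions(rec_of(c(6, 5)))
  expect_equal(ts2$sum_longest_diameters_mm, 11)
  ts3 <- select_target_lesions(rec_of(c(4, 3, 2)))
  expect_length(ts3$ids, 0L)
  expect_equal(ts3$sum_longest_diameters_mm, 0)
  # ties broken by volume then id
  tied <- data.frame(id = c(2, 1), diameter_mm = c(8, 8),
                     volume_mm3 = c(100, 300))
  expect_equal(select_target_lesions(tied)$ids, c(1, 2))
})

test_that("one-dimensional rules honor inclusive boundaries and new lesions", {
  expect_equal(assess_response_1d(40, 28, FALSE)$category, "PR")  # -30%
  expect_equal(assess_response_1d(40, 48, FALSE)$category, "PD")  # +20%
  expect_equal(assess_response_1d(40, 39, TRUE)$category, "PD")   # new lesion
  expect_equal(assess_response_1d(40, 0, FALSE)$category, "CR")
  expect_equal(assess_response_1d(40, 0, FALSE,
                                  residual_measurable = TRUE)$category,
               "PR")
  expect_equal(assess_response_1d(40, 35, FALSE)$category, "SD")
  expect_error(assess_response_1d(0, 10, FALSE), "baseline")
})

test_that("volumetric rules use the cubed thresholds inclusively", {
  expect_equal(assess_response_volumetric(1000, 343, FALSE)$category, "PR")
  expect_equal(assess_response_volumetric(1000, 1728, FALSE)$category, "PD")
  expect_equal(assess_response_volumetric(1000, 0, FALSE)$category, "CR")
  expect_equal(assess_response_volumetric(1000, 1000, TRUE)$category, "PD")
  expect_equal(assess_response_volumetric(1000, 1000, FALSE)$category, "SD")
  expect_error(assess_response_volumetric(0, 10, FALSE), "zero baseline")
})

test_that("classifiers agree with the table-driven oracle on a dense grid", {
  sb <- 40
  for (sf in seq(0, 80, by = 0.5)) {
    for (new in c(FALSE, TRUE)) {
      expect_equal(assess_response_1d(sb, sf, new)$category,
                   oracle_response_1d(sb, sf, new),
                   info = sprintf("sf=%g new=%d", sf, new))
      expect_equal(assess_response_volumetric(1000, sf * 25, new)$category,
                   oracle_response_vol(1000, sf * 25, new),
                   info = sprintf("vf=%g new=%d", sf * 25, new))
    }
  }
  # explicit boundary values
  for (sf in c(0, 28 - 1e-9, 28, 28 + 1e-9, 48 - 1e-9, 48, 48 + 1e-9))
    expect_equal(assess_response_1d(40, sf, FALSE)$category,
                 oracle_response_1d(40, sf, FALSE))
  for (vf in c(0, 343 - 1e-6, 343, 343 + 1e-6, 1728 - 1e-6, 1728,
               1728 + 1e-6))
    expect_equal(assess_response_volumetric(1000, vf, FALSE)$category,
                 oracle_response_vol(1000, vf, FALSE))
})

test_that("1D and volumetric categories agree for isotropic change", {
  # single spherical lesion rescaled by k: thresholds are consistent cubes
  for (k in c(0, 0.2, 0.5, 0.699, 0.7, 0.701, 0.9, 1, 1.1, 1.199, 1.2,
              1.21, 1.5, 2)) {
    d0 <- 10; v0 <- pi / 6 * d0^3
    a1 <- assess_response_1d(d0, k * d0, FALSE)
    av <- assess_response_volumetric(v0, k^3 * v0, FALSE)
    expect_equal(a1$category, av$category, info = sprintf("k=%g", k))
  }
})

test_that("category is monotone as the follow-up sum decreases", {
  rank <- c(PD = 4, SD = 3, PR = 2, CR = 1)
  prev <- 5
  for (sf in seq(80, 0, by = -0.5)) {
    cur <- rank[[assess_response_1d(40, sf, FALSE)$category]]
    expect_lte(cur, prev)
    prev <- cur
  }
})

test_that("study-pair assessment tracks targets through matches", {
  p <- tiny_case()
  base_rec <- truth_lesion_records(p$truth)
  idt <- similarity_transform(center_mm = p$truth$brain$center_mm)
  ids <- base_rec$id

  # all radii halved: PR on both bases
  fu <- generate_followup(p, idt, followup_changes(
    growth = setNames(rep(0.5, length(ids)), ids)), seed = 5)
  fu_rec <- truth_lesion_records(fu$truth)
  matches <- match_lesions(base_rec, fu_rec, idt)
  a <- assess_study_pair(base_rec, fu_rec, matches)
  expect_equal(a$one_dimensional$category, "PR")
  expect_equal(a$volumetric$category, "PR")

  # an added 3 mm lesion alone forces PD on both bases
  nl <- list(center_mm = p$truth$brain$center_mm + c(12, 0, 0),
             diameter_mm = 3)
  fu2 <- generate_followup(p, idt, followup_changes(add = list(nl)),
                           seed = 5)
  fu2_rec <- truth_lesion_records(fu2$truth)
  m2 <- match_lesions(base_rec, fu2_rec, idt)
  a2 <- assess_study_pair(base_rec, fu2_rec, m2)
  expect_equal(a2$one_dimensional$category, "PD")
  expect_equal(a2$volumetric$category, "PD")
  expect_true(a2$one_dimensional$new_lesion)

  # identity follow-up: SD on both bases
  m3 <- match_lesions(base_rec, base_rec, idt)
  a3 <- assess_study_pair(base_rec, base_rec, m3)
  expect_equal(a3$one_dimensional$category, "SD")
  expect_equal(a3$volumetric$category, "SD")
})
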