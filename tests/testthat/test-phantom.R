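test_that("phantom generation is seed-deterministic and background-clean", {
  cfg <- phantom_config("tiny")
  a <- generate_phantom(cfg, seed = 7)
  b <- generate_phantom(cfg, seed = 7)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$labels$data, b$labels$data)
  brain <- phantom_brain_mask(a)
  expect_true(all(a$volume$data[brain$data == 0L] == 0))
  expect_gt(length(a$truth$lesions), 0L)
})

test_that("a lesion-free configuration yields an all-zero label map", {
  cfg <- phantom_config("tiny", n_lesions = c(0L, 0L))
  p <- generate_phantom(cfg, seed = 3)
  expect_true(all(p$labels$data == 0L))
  expect_equal(nrow(truth_lesion_records(p$truth)), 0L)
})

test_that("voxelized lesion volume approximates the analytic ellipsoid", {
  # 10 mm diameter sphere on a 1 mm grid: count within 5% of 4/3*pi*5^3
  cfg <- phantom_config("tiny", n_lesions = c(1L, 1L),
                        diameter_range_mm = c(10, 10), anisotropy = 0)
  p <- generate_phantom(cfg, seed = 3)
  analytic <- 4 / 3 * pi * 5^3
  expect_lt(abs(sum(p$labels$data == 1L) - analytic) / analytic, 0.05)
  # finer grid converges closer
  cfg2 <- phantom_config("tiny", dim = c(48L, 48L, 48L),
                         spacing = c(0.5, 0.5, 0.5),
                         n_lesions = c(1L, 1L),
                         diameter_range_mm = c(10, 10), anisotropy = 0)
  p2 <- generate_phantom(cfg2, seed = 3)
  vol2 <- sum(p2$labels$data == 1L) * 0.5^3
  expect_lt(abs(vol2 - analytic) / analytic,
            abs(sum(p$labels$data == 1L) - analytic) / analytic)
})

test_that("follow-up generation keeps exact truth bookkeeping", {
  cfg <- phantom_config("tiny")
  base <- generate_phantom(cfg, seed = 7)
  ids <- vapply(base$truth$lesions, `[[`, integer(1), "id")

  # identity transform, no changes, same noise seed: voxelwise identical
  idt <- similarity_transform(center_mm = base$truth$brain$center_mm)
  fu0 <- generate_followup(base, idt, followup_changes(),
                           seed = base$truth$seed)
  expect_identical(fu0$volume$data, base$volume$data)
  expect_identical(fu0$labels$data, base$labels$data)

  # growth factor 1.2: truth diameters grow exactly 20%
  fu1 <- generate_followup(base, idt,
                           followup_changes(growth = setNames(
                             rep(1.2, length(ids)), ids)), seed = 9)
  rb <- truth_lesion_records(base$truth)
  rf <- truth_lesion_records(fu1$truth)
  expect_equal(rf$diameter_mm[match(rb$id, rf$id)], 1.2 * rb$diameter_mm)

  # one added 3 mm lesion: exactly one id absent at baseline
  nl <- list(center_mm = base$truth$brain$center_mm + c(12, 0, 0),
             diameter_mm = 3)
  fu2 <- generate_followup(base, idt, followup_changes(add = list(nl)),
                           seed = 9)
  new_ids <- setdiff(truth_lesion_records(fu2$truth)$id, rb$id)
  expect_length(new_ids, 1L)

  # transforms that push the brain off the grid are refused
  big <- similarity_transform(translation_mm = c(40, 0, 0),
                              center_mm = base$truth$brain$center_mm)
  expect_error(generate_followup(base, big, followup_changes(), 9),
               "outside the grid")
})

test_that("truth diameters are recovered by measurement within one voxel", {
  cfg <- phantom_config("tiny")
  p <- generate_phantom(cfg, seed = 11)
  rec <- lesion_records(p$labels)
  tr <- truth_lesion_records(p$truth)
  for (i in seq_len(nrow(tr))) {
    if (tr$diameter_mm[i] < 3) next
    got <- rec$diameter_mm[rec$id == tr$id[i]]
    expect_lt(abs(got - tr$diameter_mm[i]), 1.0)
  }
})

test_that("study round trip restores volumes, labels and truth", {
  dir <- withr::local_tempdir()
  cfg <- phantom_config("tiny")
  base <- generate_phantom(cfg, seed = 7)
  tr <- similarity_transform(c(2, -1, 1), c(2, 1, -1), 1.01,
                             base$truth$brain$center_mm)
  fu <- generate_followup(base, tr, followup_changes(), seed = 8)
  man <- write_study(list(list(id = "case01", baseline = base,
                               followup = fu)), dir)
  files <- jsonlite::read_json(man, simplifyVector = TRUE)
  expect_equal(nrow(files), 2L)  # one baseline + one follow-up entry
  back <- read_study(man)
  expect_identical(back[[1]]$baseline$labels$data, base$labels$data)
  expect_lt(max(abs(back[[1]]$baseline$volume$data - base$volume$data)),
            1e-6)
  bt <- back[[1]]$followup$truth
  expect_equal(bt$transform$angles_deg, tr$angles_deg, tolerance = 1e-12)
  expect_equal(bt$gm_intensity, base$truth$gm_intensity)
  # refuse to clobber an existing manifest
  expect_error(write_study(list(list(id = "x", baseline = base)), dir),
               "exists")
  expect_error(write_study(list(), dir), "empty")
})
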