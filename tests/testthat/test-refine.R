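test_that("crop_and_upsample scales and centers patches as specified", {
  set.seed(6)
  v <- volume3d(array(runif(64^3), c(64, 64, 64)))
  # 32x32 in-plane box at patch 512: content fills the whole square
  b <- bounding_box(c(16, 16, 30), c(48, 48, 34))
  ps <- crop_and_upsample(v, b, size = 512L, margin_frac = 0)
  expect_equal(ps$geom$content, c(512L, 512L))
  expect_equal(ps$geom$offset, c(0L, 0L))
  expect_equal(dim(ps$patches)[1:2], c(512L, 512L))
  # 32x16 box: content spans 512x256, centered, zero padded
  b2 <- bounding_box(c(16, 24, 30), c(48, 40, 34))
  ps2 <- crop_and_upsample(v, b2, size = 512L, margin_frac = 0)
  expect_equal(ps2$geom$content, c(512L, 256L))
  expect_equal(ps2$geom$offset, c(0L, 128L))
  # padding is zero beyond the interpolation support (one input voxel,
  # i.e. 16 patch pixels at this zoom)
  expect_true(all(ps2$patches[, 1:112, ] == 0))
  # degenerate single-voxel-thick boxes are padded to a minimum extent
  b3 <- bounding_box(c(30, 30, 30), c(31, 31, 31))
  ps3 <- crop_and_upsample(v, b3, size = 64L, margin_frac = 0)
  expect_gte(dim(ps3$patches)[3], 8L)
})

test_that("truth patches survive the patch round trip for >= 5 mm lesions", {
  p <- tiny_case()
  rec <- truth_lesion_records(p$truth)
  truth_bin <- volume3d(array(as.numeric(p$labels$data > 0),
                              dim(p$labels$data)),
                        p$labels$spacing, p$labels$origin)
  for (id in rec$id[rec$diameter_mm >= 5]) {
    box <- metrano:::mask_bounding_box(p$labels$data == id)
    lp <- crop_and_upsample(truth_bin, box, size = 128L, nearest = TRUE)
    back <- refine_lesion(lp, oracle_segmenter(lp$patches))
    expect_gte(dice_coefficient(back, p$labels$data == id), 0.95)
    # stitching never labels voxels outside the margin-expanded box
    eb <- lp$geom$box
    outside <- back
    outside[(eb$min[1] + 1):eb$max[1], (eb$min[2] + 1):eb$max[2],
            (eb$min[3] + 1):eb$max[3]] <- FALSE
    expect_false(any(outside))
  }
})

test_that("an all-zero probability vetoes the lesion", {
  v <- volume3d(array(runif(32^3), c(32, 32, 32)))
  b <- bounding_box(c(10, 10, 10), c(20, 20, 20))
  ps <- crop_and_upsample(v, b, size = 64L)
  mask <- refine_lesion(ps, oracle_segmenter(array(0, dim(ps$patches))))
  expect_false(any(mask))
})

test_that("refiner training reduces loss and is reproducible", {
  set.seed(10)
  mk_patchset <- function() {
    x <- array(runif(32 * 32 * 2, 0, 0.4), c(32, 32, 2))
    t <- array(0, c(32, 32, 2))
    t[12:20, 12:20, ] <- 1
    x[t > 0] <- x[t > 0] + 0.5
    list(p = structure(list(patches = x, geom = NULL),
                       class = "lesion_patch_set"),
         l = structure(list(patches = t, geom = NULL),
                       class = "lesion_patch_set"))
  }
  sets <- lapply(1:3, function(i) mk_patchset())
  cfg <- train_config(epochs = 4L, learning_rate = 3e-3,
                      milestones = c(10L, 10L), validation_fraction = 0,
                      seed = 2L)
  m1 <- fit_refiner(lapply(sets, `[[`, "p"), lapply(sets, `[[`, "l"), cfg,
                    depth = 1L, base_channels = 2L)
  expect_lt(tail(m1$history$train_loss, 1), m1$history$train_loss[1])
  m2 <- fit_refiner(lapply(sets, `[[`, "p"), lapply(sets, `[[`, "l"), cfg,
                    depth = 1L, base_channels = 2L)
  expect_identical(m1$history, m2$history)
})

test_that("patch augmentation yields 16 distinct flip/rotation/scale views", {
  set.seed(12)
  x <- matrix(runif(32 * 32), 32, 32)
  aug <- metrano:::augment_16(x)
  expect_length(aug, 16L)
  sig <- vapply(aug, function(a) paste(signif(c(a), 6), collapse = ","),
                character(1))
  expect_equal(length(unique(sig)), 16L)
})

test_that("assembly merges overlaps, splits disjoint masks, counts records", {
  d <- c(24, 24, 24)
  m1 <- array(FALSE, d); m1[3:6, 3:6, 3:6] <- TRUE
  m2 <- array(FALSE, d); m2[15:18, 15:18, 15:18] <- TRUE
  m3 <- array(FALSE, d); m3[5:8, 5:8, 5:8] <- TRUE   # overlaps m1
  two <- assemble_lesion_map(list(m1, m2))
  expect_equal(max(two$labels$data), 2L)
  expect_equal(nrow(two$records), 2L)
  merged <- assemble_lesion_map(list(m1, m3))
  expect_equal(max(merged$labels$data), 1L)
  none <- assemble_lesion_map(list(array(FALSE, d)))
  expect_equal(sum(none$labels$data), 0L)
  expect_equal(nrow(none$records), 0L)
  expect_error(assemble_lesion_map(list(m1, array(FALSE, c(2, 2, 2)))),
               "mismatch")
})
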