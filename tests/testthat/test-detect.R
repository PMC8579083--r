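test_that("dice loss matches its closed form and is bounded", {
  t <- array(0, c(4, 4, 4)); t[1:2, , ] <- 1
  expect_lt(dice_loss(t, t), 1e-5)                  # perfect overlap
  expect_gt(dice_loss(1 - t, t), 1 - 1e-5)          # disjoint
  # p = 0.5 everywhere, truth half ones -> 0.5 exactly
  p <- array(0.5, c(4, 4, 4))
  expect_equal(dice_loss(p, t), 0.5, tolerance = 1e-6)
  expect_error(dice_loss(array(0, c(2, 2, 2)), t), "shape")
  # symmetry and bounds on random binary grids
  set.seed(5)
  for (i in 1:20) {
    a <- array(runif(6^3) < 0.3, c(6, 6, 6)) * 1
    b <- array(runif(6^3) < 0.3, c(6, 6, 6)) * 1
    la <- dice_loss(a, b); lb <- dice_loss(b, a)
    expect_equal(la, lb, tolerance = 1e-12)
    expect_gte(la, 0); expect_lte(la, 1)
  }
})

test_that("training reduces the loss and is seed-reproducible", {
  set.seed(9)
  mk <- function() {
    x <- array(runif(20^3, 0, 0.4), c(20, 20, 20))
    t <- array(0, c(20, 20, 20))
    cx <- sample(6:14, 3)
    for (dx in -2:2) for (dy in -2:2) for (dz in -2:2)
      if (dx^2 + dy^2 + dz^2 <= 4)
        t[cx[1] + dx, cx[2] + dy, cx[3] + dz] <- 1
    x[t > 0] <- x[t > 0] + 0.5
    list(x = x, t = t)
  }
  cases <- lapply(1:4, function(i) mk())
  cfg <- train_config(epochs = 4L, learning_rate = 3e-3,
                      milestones = c(10L, 20L), validation_fraction = 0,
                      seed = 1L)
  m1 <- fit_detector(lapply(cases, `[[`, "x"), lapply(cases, `[[`, "t"),
                     cfg, depth = 1L, base_channels = 2L)
  expect_lt(tail(m1$history$train_loss, 1), m1$history$train_loss[1])
  m2 <- fit_detector(lapply(cases, `[[`, "x"), lapply(cases, `[[`, "t"),
                     cfg, depth = 1L, base_channels = 2L)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
  # checkpoint round trip preserves predictions
  f <- withr::local_tempfile(fileext = ".json")
  save_segmenter(m1, f)
  m3 <- load_segmenter(f)
  expect_equal(predict_probabilities(m3, cases[[1]]$x),
               predict_probabilities(m1, cases[[1]]$x), tolerance = 1e-12)
  expect_error(fit_detector(list(), list(), cfg), "empty")
})

test_that("detection output follows threshold, connectivity and size rules", {
  # oracle model reproduces truth components
  t <- array(0, c(16, 16, 16))
  t[3:5, 3:5, 3:5] <- 1; t[10:13, 10:13, 10:13] <- 1
  lm <- detect_lesions(array(0.3, dim(t)) * 0 + t, oracle_segmenter(t),
                       min_voxels = 2L)
  expect_equal(max(lm$data), 2L)
  expect_true(all((lm$data > 0) == (t > 0)))
  # all-zero probability gives an empty map
  lm0 <- detect_lesions(t, oracle_segmenter(array(0, dim(t))))
  expect_equal(sum(lm0$data), 0L)
  # corner-touching blobs form ONE component under 26-connectivity
  u <- array(0, c(6, 6, 6))
  u[1:2, 1:2, 1:2] <- 1; u[3, 3, 3] <- 1
  lmu <- detect_lesions(u, oracle_segmenter(u), min_voxels = 1L)
  expect_equal(max(lmu$data), 1L)
  # components below min_voxels are removed
  w <- array(0, c(8, 8, 8)); w[2, 2, 2] <- 1; w[5:6, 5:6, 5:6] <- 1
  lmw <- detect_lesions(w, oracle_segmenter(w), min_voxels = 2L)
  expect_equal(max(lmw$data), 1L)
  expect_equal(sum(lmw$data > 0), 8L)
})

test_that("component labelling agrees with flood fill on random grids", {
  set.seed(11)
  for (i in 1:25) {
    d <- sample(4:12, 3, replace = TRUE)
    mask <- array(runif(prod(d)) < 0.25, d) * 1L
    lab <- metrano:::cpp_label_components(as.integer(mask), d)
    ref <- flood_fill_label(array(mask, d))
    expect_equal(max(lab), max(ref))
    # same partition: label images are equal up to renaming
    if (max(ref) > 0) {
      key <- paste(lab, c(ref))
      expect_equal(length(unique(key[c(mask) > 0])), max(ref))
    }
  }
})

test_that("detection is invariant to adding pure background padding", {
  p <- tiny_case()
  pc <- pipeline_config("tiny")
  pp <- metrano:::preprocess_case(p$volume, pc, p$truth$gm_intensity)
  cube <- metrano:::labels_to_cube(p$labels, pp$crop$box, pp$cube$record)
  prob <- array(as.numeric(cube > 0), dim(cube))
  base <- detect_lesions(prob, oracle_segmenter(prob))
  pad <- array(0, dim(prob) + 8L)
  pad[5:(4 + dim(prob)[1]), 5:(4 + dim(prob)[2]), 5:(4 + dim(prob)[3])] <-
    prob
  padded <- detect_lesions(pad, oracle_segmenter(pad))
  expect_equal(max(padded$data), max(base$data))
  expect_equal(sum(padded$data > 0), sum(base$data > 0))
})

test_that("bounding boxes are tight, ordered, expanded and clamped", {
  arr <- array(0L, c(20, 20, 20))
  arr[11:13, 11:13, 11:13] <- 1L
  arr[2:3, 2:3, 2:3] <- 2L
  boxes <- extract_bounding_boxes(label_map(arr), margin = 0L)
  expect_length(boxes, 2L)
  expect_equal(boxes[[1]]$min, c(10L, 10L, 10L))
  expect_equal(boxes[[1]]$max, c(13L, 13L, 13L))
  expect_equal(extract_bounding_boxes(label_map(array(0L, c(4, 4, 4)))),
               list())
  near <- array(0L, c(10, 10, 10)); near[1:2, 1:2, 1:2] <- 1L
  bn <- extract_bounding_boxes(label_map(near), margin = 4L)[[1]]
  expect_equal(bn$min, c(0L, 0L, 0L))
  expect_equal(bn$max, c(6L, 6L, 6L))
})
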