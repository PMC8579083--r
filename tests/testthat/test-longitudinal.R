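test_that("transform algebra: round trip, composition, closed-form inverse", {
  tr <- similarity_transform(c(5, -3, 2), c(4, -3, 2), 1.02,
                             center_mm = c(30, 32, 28))
  inv <- invert_transform(tr)
  rt <- compose_transforms(tr, inv)
  expect_lt(max(abs(rt$angles_deg)), 1e-9)
  expect_lt(max(abs(rt$translation_mm)), 1e-9)
  expect_lt(abs(rt$scale - 1), 1e-9)
  # inverse maps points back exactly
  set.seed(15)
  pts <- matrix(runif(30, 0, 64), ncol = 3)
  back <- apply_transform(inv, apply_transform(tr, pts))
  expect_lt(max(abs(back - pts)), 1e-9)
  # JSON round trip
  f <- withr::local_tempfile(fileext = ".json")
  write_transform(tr, f)
  tr2 <- read_transform(f)
  expect_equal(tr2$angles_deg, tr$angles_deg, tolerance = 1e-12)
  expect_error(similarity_transform(scale = -1), "scale")
})

test_that("self-registration returns the identity transform", {
  p <- tiny_case()
  pc <- pipeline_config("tiny")
  pp <- metrano:::preprocess_case(p$volume, pc, p$truth$gm_intensity)
  reg <- register_similarity(pp$crop$volume, pp$crop$volume,
                             levels = c(4L, 2L), max_iter = c(80L, 60L))
  expect_lt(max(abs(reg$angles_deg)), 0.1)
  expect_lt(max(abs(reg$translation_mm)), 0.1)
  expect_lt(abs(reg$scale - 1), 0.001)
})

test_that("mismatched spacing is rejected without the resample flag", {
  a <- volume3d(array(runif(8^3), c(8, 8, 8)), spacing = c(1, 1, 1))
  b <- volume3d(array(runif(8^3), c(8, 8, 8)), spacing = c(2, 2, 2))
  expect_error(register_similarity(a, b), "spacing")
})

test_that("the assignment solver matches brute-force enumeration", {
  set.seed(16)
  for (i in 1:30) {
    n <- sample(2:5, 1); m <- sample(n:6, 1)
    cost <- matrix(runif(n * m, 0, 10), n, m)
    got <- metrano:::hungarian_assign(cost)
    ref <- brute_assign(cost)
    expect_equal(sum(cost[cbind(seq_len(n), got)]), ref$cost,
                 tolerance = 1e-9)
  }
})

test_that("lesion matching applies the gate and the one-to-one rule", {
  rec <- function(id, x, y, z, v = 500) {
    data.frame(id = id, volume_mm3 = v, diameter_mm = 8,
               centroid_x_mm = x, centroid_y_mm = y, centroid_z_mm = z)
  }
  idt <- similarity_transform()
  # single lesion displaced by the transform: matched with small residual
  tr <- similarity_transform(c(3, 0, 0), c(4, -2, 1), 1.01,
                             center_mm = c(32, 32, 32))
  b <- rec(1, 20, 25, 30)
  mapped <- apply_transform(tr, as.matrix(b[, 4:6]))
  f <- rec(1, mapped[1], mapped[2], mapped[3])
  ms <- match_lesions(b, f, tr)
  expect_equal(nrow(ms$pairs), 1L)
  expect_lt(ms$pairs$residual_mm, 0.5)
  # a follow-up lesion 40 mm away is new
  f2 <- rbind(f, rec(2, mapped[1] + 40, mapped[2], mapped[3]))
  ms2 <- match_lesions(b, f2, tr)
  expect_equal(ms2$new, 2)
  # empty follow-up: all baseline ids disappeared
  ms3 <- match_lesions(b, f[0, ], tr)
  expect_equal(ms3$disappeared, 1)
  expect_equal(nrow(ms3$pairs), 0L)
  # assignment prefers the globally minimal pairing
  b2 <- rbind(rec(1, 10, 10, 10), rec(2, 13, 10, 10))
  f3 <- rbind(rec(11, 12.5, 10, 10), rec(12, 9.5, 10, 10))
  ms4 <- match_lesions(b2, f3, idt)
  expect_equal(ms4$pairs$followup_id[ms4$pairs$baseline_id == 1], 12)
  expect_equal(ms4$pairs$followup_id[ms4$pairs$baseline_id == 2], 11)
})

test_that("matching is symmetric under baseline/follow-up exchange", {
  set.seed(17)
  tr <- similarity_transform(c(2, -4, 3), c(3, 1, -2), 1.015,
                             center_mm = c(32, 32, 32))
  n <- 5
  b <- data.frame(id = 1:n, volume_mm3 = runif(n, 50, 800),
                  diameter_mm = 8,
                  centroid_x_mm = runif(n, 15, 50),
                  centroid_y_mm = runif(n, 15, 50),
                  centroid_z_mm = runif(n, 15, 50))
  mp <- apply_transform(tr, as.matrix(b[, 4:6]))
  f <- b
  f[, 4:6] <- mp + matrix(runif(3 * n, -1, 1), ncol = 3)
  fwd <- match_lesions(b, f, tr)
  bwd <- match_lesions(f, b, invert_transform(tr))
  expect_equal(fwd$pairs$baseline_id[order(fwd$pairs$baseline_id)],
               sort(bwd$pairs$followup_id))
  expect_equal(sort(fwd$new), sort(bwd$disappeared))
})

test_that("cohort success rate detects shuffled correspondences", {
  pairs_df <- data.frame(baseline_id = 1:3, followup_id = 1:3)
  good <- structure(list(pairs = cbind(pairs_df, residual_mm = 0),
                         new = integer(), disappeared = integer()),
                    class = "lesion_match_set")
  expect_equal(as.numeric(registration_success_rate(list(good),
                                                    list(pairs_df))), 1)
  shuffled <- good
  shuffled$pairs$followup_id <- c(2L, 1L, 3L)
  expect_lt(registration_success_rate(list(shuffled), list(pairs_df)), 1)
  expect_error(registration_success_rate(list(), list()), "empty")
})
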