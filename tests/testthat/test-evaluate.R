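mk_labels <- function(arr) label_map(arr)

test_that("lesion-wise detection counting follows the hit criterion", {
  t <- array(0L, c(20, 20, 6))
  t[2:4, 2:4, 2:4] <- 1L; t[10:12, 10:12, 2:4] <- 2L
  t[16:18, 16:18, 2:4] <- 3L
  p <- array(0L, c(20, 20, 6))
  p[3, 3, 3] <- 1L                       # hits lesion 1
  p[10:12, 10:12, 2:4] <- 2L             # hits lesion 2
  p[6:7, 6:7, 5:6] <- 3L                 # stray component
  ev <- match_detections_to_truth(mk_labels(p), mk_labels(t))
  expect_equal(ev$sensitivity, 2 / 3)
  expect_equal(ev$fp_count, 1L)
  # empty prediction
  ev0 <- match_detections_to_truth(mk_labels(array(0L, dim(t))),
                                   mk_labels(t))
  expect_equal(ev0$sensitivity, 0)
  expect_equal(ev0$fp_count, 0L)
  # perfect prediction
  ev1 <- match_detections_to_truth(mk_labels(t), mk_labels(t))
  expect_equal(ev1$sensitivity, 1)
  expect_equal(ev1$fp_count, 0L)
  expect_true(all(ev1$lesions$dsc == 1))
  expect_error(match_detections_to_truth(
    mk_labels(array(0L, c(2, 2, 2))), mk_labels(t)), "mismatch")
})

test_that("size-binned sensitivity handles empty bins and the aggregate", {
  ev <- structure(list(lesions = data.frame(
    id = 1:3, diameter_mm = c(4, 6, 12), detected = c(FALSE, TRUE, TRUE),
    dsc = c(NA, 0.8, 0.9)), fp_count = 0L), class = "detection_eval")
  tab <- sensitivity_by_size(list(ev), c(0, 5, 10, Inf))
  expect_equal(tab$sensitivity, c(0, 1, 1))
  expect_equal(attr(tab, "sensitivity_measurable"), 1)
  expect_equal(attr(tab, "n_measurable"), 2L)
  ev2 <- ev; ev2$lesions <- ev$lesions[2, ]
  tab2 <- sensitivity_by_size(list(ev2), c(0, 5, 10, Inf))
  expect_true(is.na(tab2$sensitivity[1]))
  expect_true(is.na(tab2$sensitivity[3]))
  expect_error(sensitivity_by_size(list(ev), c(5, 0, 10)), "increasing")
})

test_that("Dice coefficient matches hand-computed overlaps", {
  a <- array(0, c(10, 10, 2)); b <- array(0, c(10, 10, 2))
  a[1:10, 1:10, 1] <- 1                      # |P| = 100
  b[1:10, 1:5, 1] <- 1; b[1:10, 6:10, 2] <- 1  # |T| = 100, overlap 50
  expect_equal(dice_coefficient(a, b), 0.5)
  expect_equal(dice_coefficient(b, b), 1)
  expect_equal(dice_coefficient(a * 0, b), 0)
  expect_error(dice_coefficient(b, b * 0), "empty truth")
})

test_that("weighted kappa reproduces the reference agreement tables", {
  t1 <- rano_agreement_table("one_dimensional")
  expect_equal(sum(t1), 20)
  expect_equal(unname(rowSums(t1)), c(4, 8, 1, 7))
  expect_equal(unname(colSums(t1)), c(2, 5, 5, 8))
  k1 <- weighted_kappa(t1, "linear")
  expect_equal(round(as.numeric(k1), 2), 0.52)
  expect_equal(attr(k1, "P_o"), 0.800, tolerance = 1e-12)
  expect_equal(attr(k1, "P_e"), 0.580, tolerance = 1e-12)
  expect_equal(attr(k1, "agreement"), "moderate")
  t2 <- rano_agreement_table("volumetric")
  k2 <- weighted_kappa(t2, "linear")
  expect_equal(round(as.numeric(k2), 2), 0.68)
  expect_equal(attr(k2, "agreement"), "substantial")
  # perfect agreement
  expect_equal(as.numeric(weighted_kappa(diag(c(3, 4, 5, 6)))), 1)
  expect_error(weighted_kappa(matrix(0, 4, 4)), "empty")
})

test_that("kappa matches brute force and is count-scale invariant", {
  set.seed(18)
  k <- 4
  d <- abs(outer(1:k, 1:k, `-`)) / (k - 1)
  for (i in 1:40) {
    tab <- matrix(rpois(16, 3), 4, 4)
    if (sum(tab) == 0 || all(tab[!diag(4) == 1] == 0)) next
    w_lin <- 1 - d
    got <- weighted_kappa(tab, "linear")
    expect_equal(as.numeric(got), brute_kappa(tab, w_lin),
                 tolerance = 1e-12)
    wq <- 1 - d^2
    expect_equal(as.numeric(weighted_kappa(tab, "quadratic")),
                 brute_kappa(tab, wq), tolerance = 1e-12)
    # multiplying all counts leaves kappa unchanged
    expect_equal(as.numeric(weighted_kappa(tab * 7L, "linear")),
                 as.numeric(got), tolerance = 1e-12)
    # identity weights reduce to unweighted Cohen's kappa
    expect_equal(brute_kappa(tab, diag(4)),
                 local({
                   N <- sum(tab)
                   po <- sum(diag(tab)) / N
                   pe <- sum(rowSums(tab) * colSums(tab)) / N^2
                   (po - pe) / (1 - pe)
                 }), tolerance = 1e-12)
  }
})

test_that("verbal agreement categories follow the conventional bands", {
  expect_equal(kappa_agreement_category(-0.1), "poor")
  expect_equal(kappa_agreement_category(0.1), "slight")
  expect_equal(kappa_agreement_category(0.3), "fair")
  expect_equal(kappa_agreement_category(0.52), "moderate")
  expect_equal(kappa_agreement_category(0.68), "substantial")
  expect_equal(kappa_agreement_category(0.9), "almost perfect")
})

test_that("binomial intervals: exact bounds, boundaries, nesting", {
  ci <- proportion_ci(18, 19)
  expect_equal(round(ci[1], 1), 74.0)
  expect_equal(round(ci[2], 1), 99.9)
  expect_equal(proportion_ci(0, 10)[1], 0)
  expect_equal(proportion_ci(10, 10)[2], 100)
  # interval contains the point estimate and widens with fewer trials
  for (i in 1:20) {
    n <- 5 * i; x <- round(0.6 * n)
    ci_n <- proportion_ci(x, n)
    expect_lte(ci_n[1], 100 * x / n)
    expect_gte(ci_n[2], 100 * x / n)
  }
  wide <- proportion_ci(6, 10); narrow <- proportion_ci(60, 100)
  expect_lt(diff(narrow), diff(wide))
  # Wilson flag gives the score interval
  w <- proportion_ci(18, 19, method = "wilson")
  pt <- prop.test(18, 19, correct = FALSE)$conf.int * 100
  expect_equal(w, as.numeric(pt), tolerance = 1e-9)
  expect_error(proportion_ci(5, 0), "invalid")
  expect_error(proportion_ci(11, 10), "invalid")
})
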