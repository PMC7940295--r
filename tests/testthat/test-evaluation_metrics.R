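mask_of <- function(arr, spacing = c(1, 1, 1)) binary_mask(arr, spacing, "cyst")

test_that("overlap metrics match explicit voxel-set counting", {
  # |test| = 4, |reference| = 6, overlap 3
  t_ <- array(0, c(4, 4, 2)); t_[c(1, 2, 3, 5)] <- 1
  r_ <- array(0, c(4, 4, 2)); r_[c(1, 2, 3, 9, 10, 11)] <- 1
  m <- overlap_metrics(mask_of(t_), mask_of(r_))
  expect_equal(m$dice, 2 * 3 / 10)
  expect_equal(m$jaccard, 3 / 7)
  expect_equal(m$sensitivity, 3 / 6)
  expect_equal(m$precision, 3 / 4)

  same <- mask_of(r_)
  p <- overlap_metrics(same, same)
  expect_equal(unlist(p[c("dice", "jaccard", "sensitivity", "precision")]),
               c(dice = 1, jaccard = 1, sensitivity = 1, precision = 1))

  d1 <- array(0, c(3, 3, 1)); d1[1] <- 1
  d2 <- array(0, c(3, 3, 1)); d2[5] <- 1
  z <- overlap_metrics(mask_of(d1), mask_of(d2))
  expect_equal(unlist(z[c("dice", "jaccard", "sensitivity", "precision")]),
               c(dice = 0, jaccard = 0, sensitivity = 0, precision = 0))

  empty <- mask_of(array(0, c(3, 3, 1)))
  u <- overlap_metrics(empty, empty)
  expect_true(is.na(u$dice) && is.na(u$sensitivity) && is.na(u$precision))
  expect_error(overlap_metrics(mask_of(d1), mask_of(array(0, c(4, 3, 1)))),
               "congruent")
})

test_that("Hausdorff distance is exact in voxel units", {
  a <- array(0, c(8, 8, 4)); a[1, 1, 1] <- 1
  b <- array(0, c(8, 8, 4)); b[4, 5, 1] <- 1   # offset (3, 4, 0)
  expect_equal(hausdorff_vox(mask_of(a), mask_of(b)), 5)
  expect_equal(hausdorff_vox(mask_of(a), mask_of(a)), 0)
  expect_error(hausdorff_vox(mask_of(a), mask_of(array(0, c(8, 8, 4)))),
               "empty")

  # concentric spheres: directed inner->outer is 0, so the symmetric
  # distance equals the outer->inner direction and is positive
  dims <- c(13, 13, 13)
  ctr <- 7
  dist2 <- array(0, dims)
  for (k in 1:13)
    dist2[, , k] <- outer((1:13 - ctr)^2, (1:13 - ctr)^2, "+") + (k - ctr)^2
  inner <- mask_of((dist2 <= 3^2) * 1)
  outer_ <- mask_of((dist2 <= 5^2) * 1)
  h <- hausdorff_vox(inner, outer_)
  expect_gt(h, 0)
  expect_equal(h, oracle_hausdorff(inner, outer_), tolerance = 1e-9)
})

test_that("volume statistics use voxel count times voxel volume", {
  k <- array(0, c(20, 20, 5)); k[seq_len(1000)] <- 1
  c_ <- array(0, c(20, 20, 5)); c_[seq_len(250)] <- 1
  vs <- volume_stats(binary_mask(k, c(1.5, 1.5, 3.0), "kidney"),
                     binary_mask(c_, c(1.5, 1.5, 3.0), "cyst"))
  expect_equal(vs$tkv_ml, 1000 * 6.75 / 1000)
  expect_equal(vs$tcv_ml, 250 * 6.75 / 1000)
  expect_equal(vs$cystic_index, 0.25)

  full <- volume_stats(binary_mask(k, c(1.5, 1.5, 3.0), "kidney"),
                       binary_mask(k, c(1.5, 1.5, 3.0), "cyst"))
  expect_equal(full$cystic_index, 1.0)
  none <- volume_stats(binary_mask(k, c(1.5, 1.5, 3.0), "kidney"),
                       binary_mask(k * 0, c(1.5, 1.5, 3.0), "cyst"))
  expect_equal(none$tcv_ml, 0)
  expect_equal(none$cystic_index, 0)
})

test_that("percent difference is signed and reference-denominated", {
  expect_equal(percent_difference(100, 100), 0)
  expect_equal(percent_difference(110, 100), 10)
  expect_equal(percent_difference(80, 100), -20)
  expect_error(percent_difference(10, 0), "reference")
})

test_that("Bland-Altman matches the closed form", {
  ba <- bland_altman(cbind(c(1, 3), c(0, 0)))
  expect_equal(ba$bias, 2)
  expect_equal(ba$loa_low, 2 - 1.96 * sqrt(2))
  expect_equal(ba$loa_high, 2 + 1.96 * sqrt(2))
  expect_equal(ba$points$mean, c(0.5, 1.5))

  eq <- bland_altman(cbind(1:4, 1:4))
  expect_equal(eq$bias, 0)
  expect_equal(eq$loa_low, 0)
  swapped <- bland_altman(cbind(c(0, 0), c(1, 3)))
  expect_equal(swapped$bias, -2)
  expect_error(bland_altman(cbind(1, 2)), "at least 2")
})

test_that("linear fits recover exact and hand-computed OLS solutions", {
  x <- 0:5
  f <- linear_fit(cbind(x, 2 * x + 1))
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(f$r_squared, 1)

  sym <- linear_fit(cbind(c(-2, -1, 1, 2), c(3, 5, 5, 3)))
  expect_equal(sym$slope, 0)

  ols <- linear_fit(cbind(0:3, c(0, 1, 1, 2)))
  expect_equal(ols$slope, 0.6)
  expect_equal(ols$intercept, 0.1)
  expect_true(all(ols$band$lwr <= ols$band$fit & ols$band$fit <= ols$band$upr))
  expect_error(linear_fit(cbind(c(1, 1, 1), 1:3)), "x-variance")
  expect_error(linear_fit(cbind(1:2, 1:2)), "at least 3")
})

test_that("metric identities hold on random mask pairs", {
  set.seed(12)
  for (i in 1:20) {
    a <- random_mask(c(10, 10, 6))
    b <- random_mask(c(10, 10, 6))
    m_ab <- overlap_metrics(a, b)
    m_ba <- overlap_metrics(b, a)
    if (!is.na(m_ab$dice)) {
      expect_equal(m_ab$jaccard, m_ab$dice / (2 - m_ab$dice),
                   tolerance = 1e-9)
      expect_equal(m_ab$dice, m_ba$dice)
      expect_equal(m_ab$jaccard, m_ba$jaccard)
    }
    if (!is.na(m_ab$sensitivity) && !is.na(m_ba$precision))
      expect_equal(m_ab$sensitivity, m_ba$precision)
    if (sum(a$voxels) > 0 && sum(b$voxels) > 0)
      expect_equal(hausdorff_vox(a, b), hausdorff_vox(b, a))
  }
})

test_that("cohort evaluation assembles per-case rows and excludes undefined metrics", {
  co <- small_cohort(4)
  cases <- lapply(co, function(cs) {
    cs$cyst_by_source$reader2 <-
      simulate_second_reader(cs$cyst_by_source$truth, 1,
                             seed = nchar(cs$image$case_id))
    cs
  })
  rep_self <- evaluate_test_set(cases, "truth", "truth")
  expect_true(all(rep_self$per_case$dice == 1))
  expect_true(all(rep_self$per_case$tcv_percent_difference == 0))

  rep2 <- evaluate_test_set(cases, "reader2", "truth")
  expect_equal(nrow(rep2$per_case), 4)
  # summary row equals direct mean of per-case values
  s <- rep2$summary
  expect_equal(s$mean[s$metric == "dice"], mean(rep2$per_case$dice))
  expect_equal(s$sd[s$metric == "dice"], sd(rep2$per_case$dice))
  expect_s3_class(rep2$bland_altman_cystic_index, "bland_altman")
  expect_error(evaluate_test_set(cases, "readerX", "truth"), "case001")
})

test_that("overlay rendering writes a PNG with the expected color regions", {
  cs <- small_case()
  truth <- cs$cyst_by_source$truth
  k <- which(apply(truth$voxels, 3, sum) > 0)[1]
  tmp <- withr::local_tempdir()
  p1 <- file.path(tmp, "same.png")
  render_overlay(cs$image, truth, truth, k, p1)
  img <- png::readPNG(p1)
  expect_equal(dim(img)[3], 3)
  # perfect agreement: no green-dominant and no violet-dominant pixels
  greenish <- img[, , 2] > img[, , 1] + 0.2 & img[, , 2] > img[, , 3] + 0.2
  expect_equal(sum(greenish), 0)

  other <- simulate_second_reader(truth, 2, seed = 1)
  p2 <- file.path(tmp, "diff.png")
  render_overlay(cs$image, truth, other, k, p2)
  expect_true(file.exists(p2))
  expect_error(render_overlay(cs$image, truth, truth, 999, p1),
               "out of range")
})
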