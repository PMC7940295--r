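test_that("soft Dice loss matches its closed form on hand-computable cases", {
  y <- array(0, c(4, 4, 1, 2))
  y[1:2, , 1, ] <- 1                      # half the pixels positive
  # perfect binary overlap: loss tends to 0 as smoothing vanishes
  expect_lt(soft_dice_loss(y, y, smooth = 1e-9), 1e-9)
  # empty prediction vs empty target is perfect by the smoothing convention
  z <- array(0, c(4, 4, 1, 2))
  expect_equal(soft_dice_loss(z, z, smooth = 0.5), 0)
  # uniform 0.5 prediction on a half-ones target: 1 - (2*0.25N+s)/(N+s)
  p <- array(0.5, c(4, 4, 1, 2))
  n <- length(p)
  s <- 1
  expect_equal(soft_dice_loss(p, y, s),
               1 - (2 * 0.25 * n + s) / (0.5 * n + 0.5 * n + s))
  expect_error(soft_dice_loss(p, y[, , , 1, drop = FALSE]), "disagree")
  expect_error(soft_dice_loss(p, y, smooth = 0), "positive")
})

test_that("soft Dice loss stays within [0, 1] over random inputs", {
  set.seed(3)
  for (i in 1:25) {
    p <- array(runif(64), c(8, 8, 1, 1))
    y <- array(rbinom(64, 1, runif(1)), c(8, 8, 1, 1))
    l <- soft_dice_loss(p, y, smooth = runif(1, 0.1, 2))
    expect_gte(l, 0)
    expect_lte(l, 1)
  }
})

fake_cases <- function(tkv_vox, fat = rep(TRUE, length(tkv_vox))) {
  lapply(seq_along(tkv_vox), function(i) {
    m <- array(0, c(12, 12, 8))
    m[seq_len(tkv_vox[i])] <- 1
    img <- voxel_volume(array(rnorm(12 * 12 * 8), c(12, 12, 8)),
                        c(1, 1, 1), case_id = sprintf("c%02d", i),
                        fat_saturated = fat[i])
    study_case(img, binary_mask(m, c(1, 1, 1), "kidney"))
  })
}

test_that("stratification partitions cases with balanced kidney volumes", {
  cases <- fake_cases(1:60)
  plan <- stratify_cases(cases, n_test = 20, n_folds = 3, seed = 1,
                         by_fat_saturation = FALSE)
  expect_length(plan$test_ids, 20)
  val_sizes <- sort(vapply(plan$folds, function(f) length(f$val_ids), 0L))
  expect_equal(sum(val_sizes), 40)
  expect_true(all(val_sizes %in% 13:14))
  # disjointness and coverage
  all_val <- unlist(lapply(plan$folds, `[[`, "val_ids"))
  expect_length(all_val, 40)
  expect_false(any(duplicated(all_val)))
  expect_length(intersect(plan$test_ids, all_val), 0)
  for (f in plan$folds) {
    expect_length(intersect(f$train_ids, f$val_ids), 0)
    expect_setequal(c(f$train_ids, f$val_ids), setdiff(
      vapply(cases, function(cs) cs$image$case_id, ""), plan$test_ids))
  }
  # TKV balance: every partition mean within 15% of the global mean
  tkv <- stats::setNames(1:60, vapply(cases, function(cs)
    cs$image$case_id, ""))
  parts <- c(list(plan$test_ids), lapply(plan$folds, `[[`, "val_ids"))
  for (p in parts)
    expect_lt(abs(mean(tkv[p]) - mean(tkv)) / mean(tkv), 0.15)
})

test_that("stratification is deterministic and rejects duplicate ids", {
  cases <- fake_cases(1:30)
  p1 <- stratify_cases(cases, 10, 3, seed = 5)
  p2 <- stratify_cases(cases, 10, 3, seed = 5)
  expect_identical(p1, p2)
  dup <- c(cases, cases[1])
  expect_error(stratify_cases(dup, 5, 3), "duplicate")
  expect_error(stratify_cases(cases, 30, 3), "n_test")
  expect_error(stratify_cases(cases, 5, 1), "n_folds")
})

test_that("fat-saturation stratification preserves class proportions", {
  cases <- fake_cases(1:60, fat = rep(c(TRUE, TRUE, FALSE, TRUE, TRUE), 12))
  # 48 fat-saturated of 60; n_test 20 -> 16 fat-saturated test cases
  plan <- stratify_cases(cases, 20, 3, seed = 2)
  fat <- stats::setNames(vapply(cases, function(cs)
    cs$image$fat_saturated, NA),
    vapply(cases, function(cs) cs$image$case_id, ""))
  expect_equal(sum(fat[plan$test_ids]), 16)
})

test_that("fold training checkpoints the best validation epoch and is reproducible", {
  co <- tiny_cohort()
  ids <- vapply(co, function(cs) cs$image$case_id, "")
  fold <- list(train_ids = ids[1:5], val_ids = ids[6:8])
  nc <- network_config(base_filters = 4, input_shape = c(32, 32))
  tc <- train_config(epochs = 4, seed = 3)
  r1 <- train_fold(fold, co, nc, tc)
  expect_equal(nrow(r1$curve), 4)
  expect_equal(r1$best_epoch, which.max(r1$curve$val_dice))

  # reloading the checkpoint reproduces the recorded best validation Dice
  best_val <- max(r1$curve$val_dice)
  vd <- vapply(co[match(fold$val_ids, ids)], function(cs) {
    samples <- preprocess_case(cs, with_targets = FALSE,
                               out_shape = c(32, 32))
    pv <- cystseg:::predict_volume_grid(r1$model, samples, 0.5)
    cystseg:::hard_dice(pv, cystseg:::truth_at_grid(cs, "truth", c(32, 32)))
  }, 0)
  expect_equal(mean(vd), best_val, tolerance = 1e-5)

  r2 <- train_fold(fold, co, nc, tc)
  expect_identical(r1$curve, r2$curve)
})

test_that("cross-validation demands an odd fold count and returns one model per fold", {
  co <- tiny_cohort()
  plan <- stratify_cases(co, n_test = 2, n_folds = 3, seed = 1)
  bad_plan <- plan
  bad_plan$folds <- plan$folds[1]
  expect_error(run_cross_validation(bad_plan, co, network_config(),
                                    train_config()), "odd")
  nc <- network_config(base_filters = 4, input_shape = c(32, 32))
  tc <- train_config(epochs = 2, seed = 1)
  res <- run_cross_validation(plan, co, nc, tc)
  expect_length(res, 3)
  for (r in res) expect_equal(nrow(r$curve), 2)
})
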