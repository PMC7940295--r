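test_that("convolution kernels agree with a direct quadruple-loop reference", {
  set.seed(5)
  x <- array(rnorm(10 * 8 * 3 * 2), c(10, 8, 3, 2))
  w <- array(rnorm(5 * 5 * 3 * 4), c(5, 5, 3, 4))
  b <- rnorm(4)
  expect_equal(cystseg:::.cn_conv2d_fw(x, w, b), oracle_conv2d(x, w, b),
               tolerance = 1e-12)
})

test_that("configuration invariants are enforced", {
  expect_error(network_config(kernel_schedule = c(7, 4, 3)), "odd")
  expect_error(network_config(input_shape = c(100, 100)), "divisible")
  cfg <- network_config()
  expect_length(cfg$kernel_schedule, 3)
  expect_identical(cfg$in_channels, 2L)
})

test_that("the network preserves spatial shape and outputs probabilities in (0, 1)", {
  cfg <- network_config(base_filters = 4, input_shape = c(64, 64))
  m <- build_network(cfg, seed = 2)
  z <- array(0, c(64, 64, 2, 2))
  p <- cystseg:::net_forward(m, z, training = FALSE)$p
  expect_equal(dim(p), c(64, 64, 2))
  expect_true(all(is.finite(p)) && all(p > 0) && all(p < 1))

  cfg2 <- network_config(base_filters = 2, input_shape = c(256, 256))
  m2 <- build_network(cfg2, seed = 2)
  p2 <- cystseg:::net_forward(m2, array(0, c(256, 256, 2, 1)), FALSE)$p
  expect_equal(dim(p2), c(256, 256, 1))
})

test_that("inference is deterministic with fixed weights", {
  cfg <- network_config(base_filters = 4, input_shape = c(32, 32))
  m <- build_network(cfg, seed = 9)
  x <- array(rnorm(32 * 32 * 2 * 3), c(32, 32, 2, 3))
  p1 <- cystseg:::net_forward(m, x, FALSE)$p
  p2 <- cystseg:::net_forward(m, x, FALSE)$p
  expect_identical(p1, p2)
})

test_that("analytic gradients match numerical differentiation", {
  cfg <- network_config(kernel_schedule = c(5, 3), base_filters = 2,
                        input_shape = c(16, 16), dropout_rate = 0)
  model <- build_network(cfg, seed = 3)
  set.seed(42)
  x <- array(rnorm(16 * 16 * 2 * 2), c(16, 16, 2, 2))
  y <- array(rbinom(16 * 16 * 2, 1, 0.3), c(16, 16, 1, 2))
  fw <- cystseg:::net_forward(model, x, training = TRUE)
  gp <- cystseg:::soft_dice_grad(array(fw$p, dim(y)), y, 1)
  G <- cystseg:::net_backward(model, fw$cache, gp)

  eps <- 1e-5
  loss_at <- function(m) soft_dice_loss(cystseg:::net_forward(m, x, TRUE)$p,
                                        y, 1)
  for (nm in c("enc1_conv1_W", "enc2_bn_gamma", "bot_conv2_W", "dec2_up_W",
               "dec1_skip_W", "dec1_conv2_b", "out_W")) {
    for (i in sample(length(model$params[[nm]]), 2)) {
      m2 <- model
      m2$params[[nm]][i] <- model$params[[nm]][i] + eps
      l1 <- loss_at(m2)
      m2$params[[nm]][i] <- model$params[[nm]][i] - eps
      l2 <- loss_at(m2)
      num <- (l1 - l2) / (2 * eps)
      expect_equal(G[[nm]][i], num, tolerance = 1e-4,
                   label = paste("gradient of", nm))
    }
  }
})

test_that("one optimization step reduces the batch loss", {
  cfg <- network_config(kernel_schedule = c(5, 3), base_filters = 2,
                        input_shape = c(16, 16), dropout_rate = 0)
  model <- build_network(cfg, seed = 8)
  set.seed(1)
  x <- array(rnorm(16 * 16 * 2 * 4), c(16, 16, 2, 4))
  y <- array(0, c(16, 16, 1, 4))
  y[5:12, 5:12, 1, ] <- 1
  fw <- cystseg:::net_forward(model, x, TRUE)
  l0 <- soft_dice_loss(fw$p, y, 1)
  gp <- cystseg:::soft_dice_grad(array(fw$p, dim(y)), y, 1)
  G <- cystseg:::net_backward(model, fw$cache, gp)
  opt <- cystseg:::adam_init(model$params)
  upd <- cystseg:::adam_step(model$params, G, opt, lr = 1e-3)
  model$params <- upd$params
  l1 <- soft_dice_loss(cystseg:::net_forward(model, x, TRUE)$p, y, 1)
  expect_lt(l1, l0)
})

test_that("predict_slices thresholds correctly and validates shapes", {
  cfg <- network_config(base_filters = 4, input_shape = c(32, 32))
  m <- build_network(cfg, seed = 1)
  co <- tiny_cohort()
  samples <- preprocess_case(co[[1]], with_targets = FALSE,
                             out_shape = c(32, 32))
  all_zero <- predict_slices(m, samples, threshold = 1.0)
  all_one <- predict_slices(m, samples, threshold = 0.0)
  expect_true(all(vapply(all_zero, sum, 0) == 0))
  expect_true(all(vapply(all_one, function(p) all(p == 1), NA)))

  bad <- preprocess_case(co[[1]], with_targets = FALSE,
                         out_shape = c(64, 64))
  expect_error(predict_slices(m, bad), "does not match")
})

test_that("checkpoints round-trip through disk", {
  cfg <- network_config(base_filters = 2, input_shape = c(16, 16))
  m <- build_network(cfg, seed = 4)
  tmp <- withr::local_tempdir()
  p <- file.path(tmp, "fold1.rds")
  save_checkpoint(m, p)
  expect_true(file.exists(file.path(tmp, "fold1_config.json")))
  m2 <- load_checkpoint(p)
  expect_equal(m2$params, m$params)
  x <- array(rnorm(16 * 16 * 2), c(16, 16, 2, 1))
  expect_identical(cystseg:::net_forward(m, x, FALSE)$p,
                   cystseg:::net_forward(m2, x, FALSE)$p)
})
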