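## Two-channel 2-D encoder-decoder segmentation network.
##
## Built from first principles on the Rcpp convolution kernels: each encoder
## block is conv -> dropout -> batch norm -> conv -> max pool, with kernel
## sizes shrinking down the encoder (default 7x7 -> 5x5 -> 3x3) and growing
## back up the decoder; skip connections are additive (ResNet-like), with a
## 1x1 projection so channel counts match; upsampling is nearest-neighbour
## followed by a convolution of the level's kernel size; the head is a 1x1
## convolution with a sigmoid.  ReLU follows every convolution.  Forward and
## backward passes are explicit so training needs no autodiff framework.

#' Network configuration
#'
#' @param kernel_schedule Odd kernel sizes down the encoder; mirrored up the
#'   decoder.  Its length sets the number of resolution-reducing levels.
#' @param dropout_rate Dropout probability between the two convolutions of
#'   each block.
#' @param pool_size Max-pool window (isotropic); only 2 is supported.
#' @param base_filters Channels of the first level; doubled per level, with a
#'   bottleneck at `base_filters * 2^length(kernel_schedule)`.  32 at full
#'   scale, 8 at test scale.
#' @param input_shape Spatial input size (rows, columns); must be divisible
#'   by `pool_size^length(kernel_schedule)`.
#' @return An object of class `network_config`.
#' @export
network_config <- function(kernel_schedule = c(7L, 5L, 3L),
                           dropout_rate = 0.1,
                           pool_size = 2L,
                           base_filters = 32L,
                           input_shape = c(256L, 256L)) {
  if (any(kernel_schedule %% 2 != 1) || any(kernel_schedule < 1))
    stop("kernel sizes must be odd positive integers")
  if (pool_size != 2L) stop("only pool_size = 2 is supported")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must lie in [0, 1)")
  L <- length(kernel_schedule)
  if (any(input_shape %% (pool_size^L) != 0))
    stop("input_shape must be divisible by ", pool_size^L,
         " (pool_size^levels)")
  structure(list(kernel_schedule = as.integer(kernel_schedule),
                 dropout_rate = dropout_rate,
                 pool_size = as.integer(pool_size),
                 base_filters = as.integer(base_filters),
                 input_shape = as.integer(input_shape),
                 in_channels = 2L, out_channels = 1L),
            class = "network_config")
}

net_channels <- function(config) {
  L <- length(config$kernel_schedule)
  list(enc = config$base_filters * 2^(seq_len(L) - 1),
       bottleneck = config$base_filters * 2^L)
}

he_init <- function(k, cin, cout) {
  array(rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
        dim = c(k, k, cin, cout))
}

#' Build an untrained segmentation model
#'
#' Weights use He-normal initialization; batch-norm scale/shift start at
#' 1/0 with zeroed running statistics.
#'
#' @param config A [network_config()].
#' @param seed Integer seed for the weight draw.
#' @return An object of class `cyst_net` holding `config`, `params` (all
#'   learnable arrays) and `state` (batch-norm running statistics).
#' @export
build_network <- function(config, seed = 1L) {
  stopifnot(inherits(config, "network_config"))
  set.seed(seed)
  ks <- config$kernel_schedule
  L <- length(ks)
  ch <- net_channels(config)
  P <- list()
  S <- list()
  cin <- config$in_channels
  for (i in seq_len(L)) {
    k <- ks[i]; co <- ch$enc[i]; nm <- paste0("enc", i)
    P[[paste0(nm, "_conv1_W")]] <- he_init(k, cin, co)
    P[[paste0(nm, "_conv1_b")]] <- numeric(co)
    P[[paste0(nm, "_bn_gamma")]] <- rep(1, co)
    P[[paste0(nm, "_bn_beta")]] <- numeric(co)
    P[[paste0(nm, "_conv2_W")]] <- he_init(k, co, co)
    P[[paste0(nm, "_conv2_b")]] <- numeric(co)
    S[[paste0(nm, "_bn")]] <- list(mean = numeric(co), var = rep(1, co))
    cin <- co
  }
  cb <- ch$bottleneck
  P$bot_conv1_W <- he_init(3L, cin, cb)
  P$bot_conv1_b <- numeric(cb)
  P$bot_bn_gamma <- rep(1, cb)
  P$bot_bn_beta <- numeric(cb)
  P$bot_conv2_W <- he_init(3L, cb, cb)
  P$bot_conv2_b <- numeric(cb)
  S$bot_bn <- list(mean = numeric(cb), var = rep(1, cb))
  cup <- cb
  for (i in rev(seq_len(L))) {
    k <- ks[i]; co <- ch$enc[i]; nm <- paste0("dec", i)
    P[[paste0(nm, "_up_W")]] <- he_init(k, cup, co)
    P[[paste0(nm, "_up_b")]] <- numeric(co)
    P[[paste0(nm, "_skip_W")]] <- he_init(1L, co, co)
    P[[paste0(nm, "_skip_b")]] <- numeric(co)
    P[[paste0(nm, "_bn_gamma")]] <- rep(1, co)
    P[[paste0(nm, "_bn_beta")]] <- numeric(co)
    P[[paste0(nm, "_conv2_W")]] <- he_init(k, co, co)
    P[[paste0(nm, "_conv2_b")]] <- numeric(co)
    S[[paste0(nm, "_bn")]] <- list(mean = numeric(co), var = rep(1, co))
    cup <- co
  }
  P$out_W <- he_init(1L, cup, 1L)
  P$out_b <- numeric(1L)
  structure(list(config = config, params = P, state = S), class = "cyst_net")
}

#' @export
print.cyst_net <- function(x, ...) {
  npar <- sum(vapply(x$params, length, 0L))
  cat(sprintf("<cyst_net: %d levels, kernels [%s], %d parameters, input %s>\n",
              length(x$config$kernel_schedule),
              paste(x$config$kernel_schedule, collapse = ","), npar,
              paste(x$config$input_shape, collapse = "x")))
  invisible(x)
}

## ---- layer primitives (R side) ---------------------------------------------

relu_f <- function(x) list(y = pmax(x, 0), mask = x > 0)
relu_b <- function(gy, mask) gy * mask

drop_f <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(y = x, mask = NULL))
  mask <- (array(runif(length(x)), dim(x)) >= rate) / (1 - rate)
  list(y = x * mask, mask = mask)
}
drop_b <- function(gy, mask) if (is.null(mask)) gy else gy * mask

## per-channel sum/broadcast for (H, W, C, N) arrays
chan_sum <- function(x) {
  d <- dim(x)
  rowSums(matrix(colSums(matrix(x, d[1] * d[2])), d[3]))
}
chan_bc <- function(v, d) rep(v, each = d[1] * d[2])  # recycles over N

bn_f <- function(x, gamma, beta, training, rs, momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  m <- d[1] * d[2] * d[4]
  if (training) {
    mu <- chan_sum(x) / m
    va <- chan_sum(x * x) / m - mu^2
    va <- pmax(va, 0)
    rs$mean <- (1 - momentum) * rs$mean + momentum * mu
    rs$var <- (1 - momentum) * rs$var + momentum * va
  } else {
    mu <- rs$mean; va <- rs$var
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- (x - chan_bc(mu, d)) * chan_bc(istd, d)
  y <- xhat * chan_bc(gamma, d) + chan_bc(beta, d)
  list(y = y, cache = list(xhat = xhat, istd = istd, gamma = gamma,
                           training = training),
       state = rs)
}

bn_b <- function(gy, cache) {
  d <- dim(gy)
  m <- d[1] * d[2] * d[4]
  xhat <- cache$xhat
  dgamma <- chan_sum(gy * xhat)
  dbeta <- chan_sum(gy)
  coefs <- chan_bc(cache$gamma * cache$istd, d)
  if (cache$training) {
    gx <- coefs * (gy - chan_bc(dbeta / m, d) - xhat * chan_bc(dgamma / m, d))
  } else {
    gx <- coefs * gy  # running stats are constants at inference
  }
  list(gx = gx, dgamma = dgamma, dbeta = dbeta)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

## ---- full forward / backward ----------------------------------------------

## Forward pass.  Returns per-pixel probabilities (H, W, N), the cache needed
## for the backward pass (training mode), and the updated batch-norm state.
net_forward <- function(model, x, training = FALSE) {
  cfg <- model$config; P <- model$params; S <- model$state
  L <- length(cfg$kernel_schedule)
  rate <- cfg$dropout_rate
  cc <- list(enc = vector("list", L), dec = vector("list", L))
  h <- x

  block_front <- function(h, nm) {
    t1 <- .cn_conv2d_fw(h, P[[paste0(nm, "_conv1_W")]],
                        P[[paste0(nm, "_conv1_b")]])
    r1 <- relu_f(t1)
    d1 <- drop_f(r1$y, rate, training)
    n1 <- bn_f(d1$y, P[[paste0(nm, "_bn_gamma")]],
               P[[paste0(nm, "_bn_beta")]], training, S[[paste0(nm, "_bn")]])
    S[[paste0(nm, "_bn")]] <<- n1$state
    t2 <- .cn_conv2d_fw(n1$y, P[[paste0(nm, "_conv2_W")]],
                        P[[paste0(nm, "_conv2_b")]])
    r2 <- relu_f(t2)
    list(y = r2$y, cache = list(x_in = h, r1 = r1$mask, d1 = d1$mask,
                                bn = n1$cache, n1y = n1$y, r2 = r2$mask))
  }

  for (i in seq_len(L)) {
    b <- block_front(h, paste0("enc", i))
    mp <- .cn_maxpool_fw(b$y)
    cc$enc[[i]] <- c(b$cache, list(skip = b$y, pool_idx = mp$idx,
                                   pre_pool_dim = dim(b$y)))
    h <- mp$y
  }

  b <- block_front(h, "bot")
  cc$bot <- b$cache
  h <- b$y

  for (i in rev(seq_len(L))) {
    nm <- paste0("dec", i)
    u <- .cn_upsample_fw(h)
    a <- .cn_conv2d_fw(u, P[[paste0(nm, "_up_W")]], P[[paste0(nm, "_up_b")]])
    ra <- relu_f(a)
    da <- drop_f(ra$y, rate, training)
    na <- bn_f(da$y, P[[paste0(nm, "_bn_gamma")]], P[[paste0(nm, "_bn_beta")]],
               training, S[[paste0(nm, "_bn")]])
    S[[paste0(nm, "_bn")]] <- na$state
    sk <- .cn_conv2d_fw(cc$enc[[i]]$skip, P[[paste0(nm, "_skip_W")]],
                        P[[paste0(nm, "_skip_b")]])
    z <- na$y + sk
    t2 <- .cn_conv2d_fw(z, P[[paste0(nm, "_conv2_W")]],
                        P[[paste0(nm, "_conv2_b")]])
    r2 <- relu_f(t2)
    cc$dec[[i]] <- list(u = u, ra = ra$mask, da = da$mask, bn = na$cache,
                        z = z, r2 = r2$mask)
    h <- r2$y
  }

  logits <- .cn_conv2d_fw(h, P$out_W, P$out_b)
  p <- sigmoid(logits)
  cc$head <- list(x_in = h, p = p)
  list(p = array(p, dim(p)[c(1, 2, 4)]), cache = cc, state = S)
}

## Backward pass from dL/dp (same shape as the probability output).
## Returns the gradient list, keyed like `params`.
net_backward <- function(model, cache, gp) {
  cfg <- model$config; P <- model$params
  L <- length(cfg$kernel_schedule)
  G <- list()
  p <- cache$head$p
  gz <- array(gp, dim(p)) * p * (1 - p)

  bw <- .cn_conv2d_bw(cache$head$x_in, P$out_W, gz)
  G$out_W <- bw$gw; G$out_b <- bw$gb
  gh <- bw$gx

  gskip <- vector("list", L)
  for (i in seq_len(L)) {
    nm <- paste0("dec", i); cc <- cache$dec[[i]]
    gt2 <- relu_b(gh, cc$r2)
    bw <- .cn_conv2d_bw(cc$z, P[[paste0(nm, "_conv2_W")]], gt2)
    G[[paste0(nm, "_conv2_W")]] <- bw$gw
    G[[paste0(nm, "_conv2_b")]] <- bw$gb
    gz2 <- bw$gx
    skc <- .cn_conv2d_bw(cache$enc[[i]]$skip, P[[paste0(nm, "_skip_W")]], gz2)
    G[[paste0(nm, "_skip_W")]] <- skc$gw
    G[[paste0(nm, "_skip_b")]] <- skc$gb
    gskip[[i]] <- skc$gx
    bnb <- bn_b(gz2, cc$bn)
    G[[paste0(nm, "_bn_gamma")]] <- bnb$dgamma
    G[[paste0(nm, "_bn_beta")]] <- bnb$dbeta
    ga <- relu_b(drop_b(bnb$gx, cc$da), cc$ra)
    bw <- .cn_conv2d_bw(cc$u, P[[paste0(nm, "_up_W")]], ga)
    G[[paste0(nm, "_up_W")]] <- bw$gw
    G[[paste0(nm, "_up_b")]] <- bw$gb
    gh <- .cn_upsample_bw(bw$gx)
  }

  block_back <- function(gh, nm, cc, need_input_grad = TRUE) {
    gt2 <- relu_b(gh, cc$r2)
    bw <- .cn_conv2d_bw(cc$n1y, P[[paste0(nm, "_conv2_W")]], gt2)
    G[[paste0(nm, "_conv2_W")]] <<- bw$gw
    G[[paste0(nm, "_conv2_b")]] <<- bw$gb
    bnb <- bn_b(bw$gx, cc$bn)
    G[[paste0(nm, "_bn_gamma")]] <<- bnb$dgamma
    G[[paste0(nm, "_bn_beta")]] <<- bnb$dbeta
    g1 <- relu_b(drop_b(bnb$gx, cc$d1), cc$r1)
    bw <- .cn_conv2d_bw(cc$x_in, P[[paste0(nm, "_conv1_W")]], g1,
                        need_gx = need_input_grad)
    G[[paste0(nm, "_conv1_W")]] <<- bw$gw
    G[[paste0(nm, "_conv1_b")]] <<- bw$gb
    bw$gx
  }

  gh <- block_back(gh, "bot", cache$bot)

  for (i in rev(seq_len(L))) {
    cc <- cache$enc[[i]]
    gr2 <- .cn_maxpool_bw(gh, cc$pool_idx, cc$pre_pool_dim) + gskip[[i]]
    gh <- block_back(gr2, paste0("enc", i), cc, need_input_grad = i > 1)
  }
  G
}

#' Predict binary cyst masks for a list of slice samples
#'
#' Runs the network in evaluation mode (dropout off, batch-norm running
#' statistics) and thresholds the per-pixel probabilities.
#'
#' @param model A trained (or untrained) `cyst_net`.
#' @param samples List of slice samples from [assemble_samples()].
#' @param threshold Probability threshold in `[0, 1]`.
#' @param batch_size Forward-pass batch size.
#' @return List of \{0, 1\} matrices, one per sample, in input order.
#' @export
predict_slices <- function(model, samples, threshold = 0.5,
                           batch_size = 16L) {
  stopifnot(inherits(model, "cyst_net"))
  if (!length(samples)) return(list())
  hw <- dim(samples[[1]]$input_image)
  if (!all(hw == model$config$input_shape))
    stop("sample shape ", paste(hw, collapse = "x"),
         " does not match network input ",
         paste(model$config$input_shape, collapse = "x"))
  out <- vector("list", length(samples))
  for (start in seq(1, length(samples), by = batch_size)) {
    idx <- start:min(start + batch_size - 1, length(samples))
    xb <- samples_to_batch(samples[idx])$x
    p <- net_forward(model, xb, training = FALSE)$p
    for (j in seq_along(idx))
      out[[idx[j]]] <- (p[, , j] >= threshold) * 1
  }
  out
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS file holding weights, batch-norm state and
#' the configuration; the configuration is additionally written as a JSON
#' sidecar for inspection and reproducible reload.
#'
#' @param model A `cyst_net`.
#' @param path Checkpoint path (`.rds`).
#' @return `save_checkpoint` returns the path invisibly; `load_checkpoint`
#'   returns the model.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "cyst_net"))
  saveRDS(model, path)
  cfg_path <- paste0(sub("\\.rds$", "", path), "_config.json")
  jsonlite::write_json(unclass(model$config), cfg_path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "cyst_net"))
  model
}
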