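## TKV-stratified splitting, soft Dice loss, Adam, and the per-fold training
## loop with best-validation checkpoint retention.

#' Training configuration
#'
#' Defaults follow the reference protocol: Adam with initial learning rate
#' 1e-3 and additive decay 1e-5 (interpreted as `lr_t = lr0 / (1 + decay * t)`
#' per update step), 200 epochs, batch size 8.  Test-scale runs override
#' `epochs`.
#'
#' @param learning_rate Initial Adam learning rate.
#' @param lr_decay Additive per-step learning-rate decay.
#' @param epochs Number of training epochs.
#' @param batch_size Slices per optimization step.
#' @param dice_smooth Smoothing constant of the soft Dice loss.
#' @param seed Seed controlling initialization, shuffling and dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, lr_decay = 1e-5,
                         epochs = 200L, batch_size = 8L, dice_smooth = 1,
                         seed = 1L) {
  stopifnot(learning_rate > 0, lr_decay >= 0, epochs >= 1, batch_size >= 1,
            dice_smooth > 0)
  structure(list(learning_rate = learning_rate, lr_decay = lr_decay,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 dice_smooth = dice_smooth, seed = as.integer(seed)),
            class = "train_config")
}

#' TKV-stratified split into hold-out test set and cross-validation folds
#'
#' Cases are ranked by total kidney volume and allocated by systematic
#' strided sampling with seeded within-stratum shuffling, so the TKV
#' distribution of the test set and of every fold matches the remainder.
#' With `by_fat_saturation = TRUE` (default) the allocation additionally
#' preserves the fat-saturated/non-fat-saturated proportion in every
#' partition.
#'
#' @param cases List of [study_case()] objects with unique case ids.
#' @param n_test Hold-out test set size (`< length(cases)`).
#' @param n_folds Number of cross-validation folds, at least 2.
#' @param seed Integer seed.
#' @param by_fat_saturation Stratify jointly by fat saturation.
#' @return An object of class `split_plan` with `test_ids` and `folds`, a
#'   list of `(train_ids, val_ids)` pairs; every non-test id appears in
#'   exactly one fold's validation set.
#' @export
stratify_cases <- function(cases, n_test, n_folds = 3L, seed = 1L,
                           by_fat_saturation = TRUE) {
  ids <- vapply(cases, function(cs) cs$image$case_id, "")
  if (anyDuplicated(ids)) stop("duplicate case ids: ",
                               paste(unique(ids[duplicated(ids)]),
                                     collapse = ", "))
  if (n_test >= length(cases)) stop("n_test must be < number of cases")
  if (n_folds < 2) stop("n_folds must be at least 2")
  tkv <- vapply(cases, function(cs)
    volume_stats(cs$kidney, cs$kidney)$tkv_ml, 0)
  fat <- vapply(cases, function(cs) cs$image$fat_saturated, NA)

  set.seed(seed)
  classes <- if (by_fat_saturation) split(seq_along(cases), fat)
             else list(all = seq_along(cases))
  ## largest-remainder apportionment of the test quota across classes
  sizes <- lengths(classes)
  quota <- n_test * sizes / length(cases)
  n_test_c <- floor(quota)
  rem <- n_test - sum(n_test_c)
  if (rem > 0) {
    ord <- order(quota - n_test_c, sizes, decreasing = TRUE)
    n_test_c[ord[seq_len(rem)]] <- n_test_c[ord[seq_len(rem)]] + 1
  }

  test_idx <- integer(0)
  val_idx <- vector("list", n_folds)
  for (ci in seq_along(classes)) {
    members <- classes[[ci]][order(tkv[classes[[ci]]])]
    nt <- n_test_c[ci]
    if (nt > 0) {
      stratum <- ceiling(seq_along(members) * nt / length(members))
      picked <- vapply(split(members, stratum), function(s)
        s[sample.int(length(s), 1)], 0L)
      test_idx <- c(test_idx, picked)
      members <- setdiff(members, picked)
    }
    if (length(members)) {
      stratum <- ceiling(seq_along(members) / n_folds)
      for (s in split(members, stratum)) {
        fold_order <- sample.int(n_folds)[seq_along(s)]
        for (j in seq_along(s))
          val_idx[[fold_order[j]]] <- c(val_idx[[fold_order[j]]], s[j])
      }
    }
  }

  non_test <- setdiff(seq_along(cases), test_idx)
  folds <- lapply(val_idx, function(v) {
    list(train_ids = ids[sort(setdiff(non_test, v))],
         val_ids = ids[sort(v)])
  })
  structure(list(test_ids = ids[sort(test_idx)], folds = folds),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan: %d test cases, %d folds (val sizes %s)>\n",
              length(x$test_ids), length(x$folds),
              paste(vapply(x$folds, function(f) length(f$val_ids), 0L),
                    collapse = "/")))
  invisible(x)
}

#' Soft Dice loss
#'
#' `1 - (2 * sum(pred * target) + smooth) / (sum(pred) + sum(target) +
#' smooth)`, with the sums running over every pixel of the batch.  The
#' smoothing constant keeps the empty-vs-empty case defined (loss 0) and the
#' loss in `[0, 1]`.
#'
#' @param pred Array of per-pixel probabilities in `[0, 1]`.
#' @param target Congruent binary array.
#' @param smooth Positive smoothing constant.
#' @return The scalar loss.
#' @export
soft_dice_loss <- function(pred, target, smooth = 1) {
  if (length(pred) != length(target))
    stop("pred and target shapes disagree")
  if (smooth <= 0) stop("smooth must be positive")
  p <- as.numeric(pred); t <- as.numeric(target)
  num <- 2 * sum(p * t) + smooth
  den <- sum(p) + sum(t) + smooth
  1 - num / den
}

## Gradient of the soft Dice loss with respect to pred.
soft_dice_grad <- function(pred, target, smooth = 1) {
  p <- as.numeric(pred); t <- as.numeric(target)
  num <- 2 * sum(p * t) + smooth
  den <- sum(p) + sum(t) + smooth
  array((num - 2 * t * den) / den^2, dim(target))
}

## ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  c1 <- 1 - beta1^opt$t
  c2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / c1) / (sqrt(opt$v[[nm]] / c2) + eps)
  }
  list(params = params, opt = opt)
}

## Hard volume-level Dice; the empty-vs-empty case counts as perfect
## agreement.
hard_dice <- function(a, b) {
  tp <- sum(a * b)
  den <- sum(a) + sum(b)
  if (den == 0) 1 else 2 * tp / den
}

## Nearest-resampled truth volume at the processing grid.
truth_at_grid <- function(case, truth_source, out_shape) {
  d <- dim(case$image$voxels)
  v <- array(0, c(out_shape[1], out_shape[2], d[3]))
  tr <- case$cyst_by_source[[truth_source]]$voxels
  for (k in seq_len(d[3]))
    v[, , k] <- resample_slice(tr[, , k], out_shape, "nearest")
  v
}

## Stack per-slice binary predictions into a volume at the processing grid.
predict_volume_grid <- function(model, samples, threshold = 0.5) {
  preds <- predict_slices(model, samples, threshold)
  hw <- dim(preds[[1]])
  v <- array(0, c(hw[1], hw[2], length(preds)))
  for (k in seq_along(preds)) v[, , k] <- preds[[k]]
  v
}

#' Train the network on one cross-validation fold
#'
#' Slice samples from all training cases are shuffled across cases each
#' epoch and consumed in batches.  After every epoch the hard volume-level
#' Dice (threshold 0.5, per-case over reassembled volumes, empty-vs-empty
#' counting as 1) is computed on the validation cases, and the weights at
#' the epoch maximizing it are retained as the fold checkpoint.
#'
#' @param fold A `(train_ids, val_ids)` element of a [stratify_cases()] plan.
#' @param cases List of [study_case()] objects covering those ids.
#' @param net_config A [network_config()].
#' @param tr_config A [train_config()].
#' @param truth_source Cyst-mask source used as the training target.
#' @param verbose Print per-epoch progress.
#' @return List with `model` (the best-validation checkpoint), `curve`
#'   (data frame of per-epoch training and validation Dice) and
#'   `best_epoch`.
#' @export
train_fold <- function(fold, cases, net_config, tr_config,
                       truth_source = "truth", verbose = FALSE) {
  stopifnot(length(fold$train_ids) > 0, length(fold$val_ids) > 0)
  ids <- vapply(cases, function(cs) cs$image$case_id, "")
  pick <- function(want) {
    miss <- setdiff(want, ids)
    if (length(miss)) stop("missing cases: ", paste(miss, collapse = ", "))
    cases[match(want, ids)]
  }
  out_shape <- net_config$input_shape
  train_samples <- unlist(lapply(pick(fold$train_ids), preprocess_case,
                                 with_targets = TRUE,
                                 truth_source = truth_source,
                                 out_shape = out_shape),
                          recursive = FALSE)
  if (!length(train_samples)) stop("no training slices intersect the kidney")
  if (all(vapply(train_samples, function(s) sum(s$target_cyst), 0) == 0))
    warning("all training targets are empty; loss is defined only through ",
            "the smoothing constant")
  val_cases <- pick(fold$val_ids)
  val_samples <- lapply(val_cases, preprocess_case, with_targets = FALSE,
                        out_shape = out_shape)
  val_truth <- lapply(val_cases, truth_at_grid, truth_source = truth_source,
                      out_shape = out_shape)

  model <- build_network(net_config, seed = tr_config$seed)
  set.seed(tr_config$seed)
  opt <- adam_init(model$params)
  n <- length(train_samples)
  bs <- tr_config$batch_size
  curve <- data.frame(epoch = seq_len(tr_config$epochs), train_dice = NA_real_,
                      val_dice = NA_real_)
  best <- list(val = -Inf, epoch = NA_integer_, model = NULL)

  for (ep in seq_len(tr_config$epochs)) {
    perm <- sample.int(n)
    loss_sum <- 0
    for (start in seq(1, n, by = bs)) {
      idx <- perm[start:min(start + bs - 1, n)]
      batch <- samples_to_batch(train_samples[idx])
      fw <- net_forward(model, batch$x, training = TRUE)
      model$state <- fw$state
      loss <- soft_dice_loss(fw$p, batch$y, tr_config$dice_smooth)
      gp <- soft_dice_grad(array(fw$p, dim(batch$y)), batch$y,
                           tr_config$dice_smooth)
      grads <- net_backward(model, fw$cache, gp)
      lr <- tr_config$learning_rate / (1 + tr_config$lr_decay * opt$t)
      upd <- adam_step(model$params, grads, opt, lr)
      model$params <- upd$params
      opt <- upd$opt
      loss_sum <- loss_sum + loss * length(idx)
    }
    curve$train_dice[ep] <- 1 - loss_sum / n

    vd <- vapply(seq_along(val_cases), function(i) {
      pv <- predict_volume_grid(model, val_samples[[i]], 0.5)
      hard_dice(pv, val_truth[[i]])
    }, 0)
    curve$val_dice[ep] <- mean(vd)
    if (curve$val_dice[ep] > best$val) {
      best <- list(val = curve$val_dice[ep], epoch = ep, model = model)
    }
    if (verbose)
      message(sprintf("epoch %3d: train Dice %.4f, val Dice %.4f", ep,
                      curve$train_dice[ep], curve$val_dice[ep]))
  }
  list(model = best$model, curve = curve, best_epoch = best$epoch)
}

#' Run k-fold cross-validation training
#'
#' Trains one model per fold (the ensemble requires an odd fold count of at
#' least 3 so a per-voxel majority is always defined).
#'
#' @inheritParams train_fold
#' @param plan A [stratify_cases()] split plan.
#' @return List with one `(model, curve, best_epoch)` element per fold.
#' @export
run_cross_validation <- function(plan, cases, net_config, tr_config,
                                 truth_source = "truth", verbose = FALSE) {
  stopifnot(inherits(plan, "split_plan"))
  nf <- length(plan$folds)
  if (nf < 3 || nf %% 2 == 0)
    stop("majority-vote ensembling requires an odd number of folds >= 3")
  lapply(seq_len(nf), function(i) {
    tc <- tr_config
    tc$seed <- tr_config$seed + i
    train_fold(plan$folds[[i]], cases, net_config, tc,
               truth_source = truth_source, verbose = verbose)
  })
}
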