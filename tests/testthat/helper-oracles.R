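# Independent brute-force reference implementations used to cross-check the
# package's metric and network code, plus small fixture builders.  These are
# deliberately naive (loops, exhaustive enumeration) and share no code with
# the implementations they check.

# Random blobby binary mask on a small grid: union of a few random boxes.
random_mask <- function(dims, n_boxes = 3, p_empty = 0.05,
                        spacing = c(1.5, 1.5, 3.0), role = "cyst") {
  m <- array(0, dims)
  if (runif(1) > p_empty) {
    for (b in seq_len(sample(n_boxes, 1))) {
      lo <- sapply(dims, function(d) sample(d, 1))
      hi <- pmin(lo + sapply(dims, function(d) sample(ceiling(d / 2), 1)),
                 dims)
      m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- 1
    }
  }
  binary_mask(m, spacing, role)
}

# Exhaustive overlap metrics from explicit voxel-set counting.
oracle_overlap <- function(test, reference) {
  a <- which(test$voxels != 0)
  b <- which(reference$voxels != 0)
  tp <- length(intersect(a, b))
  fp <- length(setdiff(a, b))
  fn <- length(setdiff(b, a))
  div <- function(num, den) if (den == 0) NA_real_ else num / den
  list(dice = div(2 * tp, 2 * tp + fp + fn),
       jaccard = div(tp, tp + fp + fn),
       sensitivity = div(tp, tp + fn),
       precision = div(tp, tp + fp))
}

# Exhaustive symmetric Hausdorff distance over all voxel pairs.
oracle_hausdorff <- function(test, reference) {
  a <- arrayInd(which(test$voxels != 0), dim(test$voxels))
  b <- arrayInd(which(reference$voxels != 0), dim(reference$voxels))
  dmat <- sqrt(outer(a[, 1], b[, 1], "-")^2 +
               outer(a[, 2], b[, 2], "-")^2 +
               outer(a[, 3], b[, 3], "-")^2)
  max(max(apply(dmat, 1, min)), max(apply(dmat, 2, min)))
}

# Direct 2-D "same"-padded convolution by quadruple loop.
oracle_conv2d <- function(x, w, b) {
  H <- dim(x)[1]; W <- dim(x)[2]; Cin <- dim(x)[3]; N <- dim(x)[4]
  k <- dim(w)[1]; Cout <- dim(w)[4]; p <- (k - 1) / 2
  y <- array(0, c(H, W, Cout, N))
  for (n in 1:N) for (co in 1:Cout) for (j in 1:W) for (i in 1:H) {
    acc <- b[co]
    for (ci in 1:Cin) for (dj in 1:k) for (di in 1:k) {
      ii <- i + di - 1 - p; jj <- j + dj - 1 - p
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W)
        acc <- acc + x[ii, jj, ci, n] * w[di, dj, ci, co]
    }
    y[i, j, co, n] <- acc
  }
  y
}

# Cached small phantom cohort shared across tests (built once per run).
.fixture_env <- new.env(parent = emptyenv())

small_cohort <- function(n = 6, seed = 2024, severity = c(0.05, 0.6)) {
  key <- paste("cohort", n, seed, paste(severity, collapse = "-"))
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- generate_cohort(n, severity, 0.7, seed = seed)
  .fixture_env[[key]]
}

small_case <- function(ci = 0.3, seed = 99, ...) {
  key <- paste("case", ci, seed, ...)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- generate_case(
      phantom_spec(target_cystic_index = ci, seed = seed, ...))
  .fixture_env[[key]]
}

# Tiny-scale cases used for fast training smoke tests.
tiny_cohort <- function(n = 8, seed = 7) {
  key <- paste("tiny", n, seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- generate_cohort(n, c(0.1, 0.5), 0.7, seed = seed,
                                           grid_shape = c(32, 32, 8))
  .fixture_env[[key]]
}
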