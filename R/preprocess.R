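## Slice-wise preprocessing: every case is converted into normalized
## two-channel samples (image slice + kidney-mask slice) with the cyst mask
## as the per-pixel target.  Intensity slices are resampled with cubic
## convolution, mask slices with nearest neighbour so binarity survives.

#' Resample a 2-D slice
#'
#' Cubic convolution (Keys kernel, the classical "inter-cubic" scheme) for
#' intensity slices; nearest neighbour for masks.  Cubic output is not
#' clipped to the input range -- standardization follows downstream and mild
#' over/undershoot at edges is expected.
#'
#' @param slice 2-D numeric matrix.
#' @param out_shape Integer pair (rows, columns), both positive.
#' @param method `"cubic"` or `"nearest"`.
#' @return A matrix of dimension `out_shape`.
#' @export
resample_slice <- function(slice, out_shape, method = c("cubic", "nearest")) {
  method <- match.arg(method)
  if (length(out_shape) != 2 || any(out_shape < 1))
    stop("out_shape must be two positive integers")
  slice <- as.matrix(slice)
  if (all(dim(slice) == out_shape)) return(slice)
  .cn_resample2d(slice, as.integer(out_shape[1]), as.integer(out_shape[2]),
                 if (method == "nearest") 0L else 1L)
}

#' Normalize the intensity of an MR volume
#'
#' Two steps, computed over all voxels of the volume: (1) rescale so the 95th
#' percentile equals `target_p95`; (2) standard scaling to zero mean and unit
#' standard deviation.  Step 2 makes the choice of `target_p95` immaterial
#' (the output is invariant to any positive rescaling of the input), so the
#' default is an arbitrary round number.
#'
#' @param volume A [voxel_volume()] with nonzero intensity variance.
#' @param target_p95 Positive percentile level for step 1.
#' @return A [voxel_volume()] with mean 0 and standard deviation 1.
#' @export
normalize_intensity <- function(volume, target_p95 = 1000) {
  stopifnot(inherits(volume, "voxel_volume"))
  if (target_p95 <= 0) stop("target_p95 must be positive")
  v <- volume$voxels
  if (sd(v) == 0) stop("constant volume: intensity variance is zero")
  p95 <- quantile(v, 0.95, names = FALSE)
  if (p95 > 0) v <- v * (target_p95 / p95)
  v <- (v - mean(v)) / sd(v)
  volume$voxels <- v
  volume
}

#' Assemble two-channel slice samples from a study case
#'
#' Each retained coronal slice yields one sample: the (already normalized)
#' image slice resampled cubically to `out_shape` as channel 1, the kidney
#' mask slice resampled nearest-neighbour as channel 2, and (in training
#' mode) the cyst mask of `truth_source` as the target.  Training mode keeps
#' only slices intersecting the kidney mask -- background-only slices carry
#' no gradient signal for a target constrained to the kidneys -- while
#' inference mode keeps every slice so volumes reassemble completely.
#'
#' @param case A [study_case()].
#' @param with_targets Logical; `TRUE` for training mode.
#' @param truth_source Name of the cyst mask used as target.
#' @param out_shape Processing grid, default 256x256.
#' @return List of `slice_sample` objects (possibly empty).
#' @export
assemble_samples <- function(case, with_targets = TRUE,
                             truth_source = "truth",
                             out_shape = c(256L, 256L)) {
  stopifnot(inherits(case, "study_case"))
  if (with_targets && is.null(case$cyst_by_source[[truth_source]]))
    stop("case ", case$image$case_id, " has no cyst source '", truth_source,
         "'")
  d <- dim(case$image$voxels)
  keep <- if (with_targets) {
    which(apply(case$kidney$voxels, 3, sum) > 0)
  } else seq_len(d[3])
  lapply(keep, function(k) {
    s <- list(
      input_image = resample_slice(case$image$voxels[, , k], out_shape,
                                   "cubic"),
      input_kidney = resample_slice(case$kidney$voxels[, , k], out_shape,
                                    "nearest"),
      target_cyst = if (with_targets)
        resample_slice(case$cyst_by_source[[truth_source]]$voxels[, , k],
                       out_shape, "nearest"),
      case_id = case$image$case_id,
      slice_index = k)
    class(s) <- "slice_sample"
    s
  })
}

#' Normalize a case and assemble its slice samples in one call
#'
#' @inheritParams assemble_samples
#' @param target_p95 Passed to [normalize_intensity()].
#' @return As [assemble_samples()].
#' @export
preprocess_case <- function(case, with_targets = TRUE,
                            truth_source = "truth",
                            out_shape = c(256L, 256L), target_p95 = 1000) {
  case$image <- normalize_intensity(case$image, target_p95)
  assemble_samples(case, with_targets = with_targets,
                   truth_source = truth_source, out_shape = out_shape)
}

## Stack slice samples into network batch arrays (H, W, 2, N) and, when
## targets are present, (H, W, 1, N).
samples_to_batch <- function(samples) {
  stopifnot(length(samples) > 0)
  hw <- dim(samples[[1]]$input_image)
  n <- length(samples)
  x <- array(0, c(hw[1], hw[2], 2L, n))
  has_y <- !is.null(samples[[1]]$target_cyst)
  y <- if (has_y) array(0, c(hw[1], hw[2], 1L, n))
  for (i in seq_len(n)) {
    x[, , 1, i] <- samples[[i]]$input_image
    x[, , 2, i] <- samples[[i]]$input_kidney
    if (has_y) y[, , 1, i] <- samples[[i]]$target_cyst
  }
  list(x = x, y = y)
}
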