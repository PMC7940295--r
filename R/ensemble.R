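## Majority-vote fusion of the cross-validation fold models.

#' Bundle fold models into a majority-vote ensemble
#'
#' @param members List of trained `cyst_net` models (odd count, at least 3)
#'   sharing one input shape.
#' @param member_threshold Probability threshold binarizing each member's
#'   output before voting.
#' @param vote_threshold Votes needed for a positive voxel; defaults to a
#'   strict majority `ceiling(members / 2)`.
#' @return An object of class `ensemble_model`.
#' @export
ensemble_model <- function(members, member_threshold = 0.5,
                           vote_threshold = NULL) {
  n <- length(members)
  if (n < 3 || n %% 2 == 0)
    stop("majority voting requires an odd member count >= 3")
  for (m in members) stopifnot(inherits(m, "cyst_net"))
  shapes <- vapply(members, function(m)
    paste(m$config$input_shape, collapse = "x"), "")
  if (length(unique(shapes)) != 1)
    stop("member configurations disagree on input shape: ",
         paste(unique(shapes), collapse = " vs "))
  if (is.null(vote_threshold)) vote_threshold <- ceiling(n / 2)
  if (vote_threshold < 1 || vote_threshold > n)
    stop("vote_threshold must lie in [1, members]")
  structure(list(members = members, member_threshold = member_threshold,
                 vote_threshold = as.integer(vote_threshold)),
            class = "ensemble_model")
}

#' Per-voxel majority vote over binary grids
#'
#' @param grids List of congruent \{0, 1\} arrays (one per member).
#' @param vote_threshold Minimum number of positive votes.
#' @return A \{0, 1\} array: 1 where at least `vote_threshold` grids are 1.
#' @export
majority_vote <- function(grids, vote_threshold) {
  stopifnot(length(grids) >= 1)
  votes <- Reduce(`+`, grids)
  (votes >= vote_threshold) * 1
}

#' Predict the cyst mask of a case with the fold ensemble
#'
#' The case is normalized and assembled into two-channel slices at the
#' members' processing grid; every member votes per pixel after
#' thresholding, the vote is taken on the binarized outputs, and the fused
#' slices are mapped back to the native grid by nearest-neighbour resampling
#' and stacked into a 3-D mask congruent with the input volume.
#'
#' `apply_kidney_mask` intersects the output with the kidney mask.  It is
#' off by default: constraining predictions to the kidney is a post-hoc
#' cleanup step, and leaving it off exposes how well the two-channel input
#' alone confines predictions to the kidney.
#'
#' @param ensemble An [ensemble_model()].
#' @param case A [study_case()] with image and kidney mask.
#' @param apply_kidney_mask Logical, default `FALSE`.
#' @param target_p95 Normalization level, as in [normalize_intensity()].
#' @return A [binary_mask()] with role `"cyst"`.
#' @export
predict_case <- function(ensemble, case, apply_kidney_mask = FALSE,
                         target_p95 = 1000) {
  stopifnot(inherits(ensemble, "ensemble_model"),
            inherits(case, "study_case"))
  in_shape <- ensemble$members[[1]]$config$input_shape
  samples <- preprocess_case(case, with_targets = FALSE,
                             out_shape = in_shape, target_p95 = target_p95)
  member_preds <- lapply(ensemble$members, predict_slices, samples = samples,
                         threshold = ensemble$member_threshold)
  d <- dim(case$image$voxels)
  fused <- array(0, d)
  for (k in seq_along(samples)) {
    vote <- majority_vote(lapply(member_preds, `[[`, k),
                          ensemble$vote_threshold)
    fused[, , k] <- resample_slice(vote, d[1:2], "nearest")
  }
  if (apply_kidney_mask) fused <- fused * case$kidney$voxels
  binary_mask(fused, case$image$spacing, "cyst")
}
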