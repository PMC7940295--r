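## Agreement statistics and volume measures: voxel-overlap metrics, exact
## Hausdorff distance in voxel-index units, TKV/TCV/cystic index, percent
## difference, Bland-Altman analysis, ordinary least-squares regression with
## a confidence band, cohort evaluation tables, and qualitative overlays.

#' Voxel-overlap agreement metrics between two masks
#'
#' With TP/FP/FN voxel counts taken with `reference` as ground truth:
#' Dice `2TP/(2TP+FP+FN)`, Jaccard `TP/(TP+FP+FN)`, sensitivity `TP/(TP+FN)`,
#' precision `TP/(TP+FP)`.  A metric whose denominator is zero (e.g. both
#' masks empty) is returned as `NA`, never as 0.
#'
#' @param test,reference Congruent [binary_mask()] objects.
#' @return List of class `segmentation_metrics` with fields `dice`,
#'   `jaccard`, `sensitivity`, `precision`.
#' @export
overlap_metrics <- function(test, reference) {
  stopifnot(inherits(test, "binary_mask"), inherits(reference, "binary_mask"))
  check_congruent(test, reference)
  tv <- test$voxels; rv <- reference$voxels
  tp <- sum(tv * rv)
  fp <- sum(tv) - tp
  fn <- sum(rv) - tp
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(list(dice = safe(2 * tp, 2 * tp + fp + fn),
                 jaccard = safe(tp, tp + fp + fn),
                 sensitivity = safe(tp, tp + fn),
                 precision = safe(tp, tp + fp)),
            class = "segmentation_metrics")
}

#' Exact symmetric Hausdorff distance in voxel-index units
#'
#' `max(h(A -> B), h(B -> A))` with `h(A -> B) = max_{a in A} min_{b in B}
#' ||a - b||` over 3-D voxel indices.  Spacing is deliberately ignored: the
#' unit is voxels.
#'
#' @param test,reference Congruent, non-empty [binary_mask()] objects.
#' @return Non-negative distance in voxels.
#' @export
hausdorff_vox <- function(test, reference) {
  stopifnot(inherits(test, "binary_mask"), inherits(reference, "binary_mask"))
  check_congruent(test, reference)
  a <- which(test$voxels != 0)
  b <- which(reference$voxels != 0)
  if (!length(a) || !length(b))
    stop("Hausdorff distance is undefined when a mask is empty")
  d <- dim(test$voxels)
  .cn_hausdorff(arrayInd(a, d) * 1.0, arrayInd(b, d) * 1.0)
}

#' Kidney and cyst volume statistics
#'
#' TKV and TCV are voxel counts multiplied by the voxel volume (mm^3),
#' reported in mL; the cystic index is TCV/TKV (undefined, `NA`, when the
#' kidney mask is empty).
#'
#' @param kidney,cyst Congruent [binary_mask()] objects.
#' @return List of class `volume_stats` with `tkv_ml`, `tcv_ml`,
#'   `cystic_index`.
#' @export
volume_stats <- function(kidney, cyst) {
  stopifnot(inherits(kidney, "binary_mask"), inherits(cyst, "binary_mask"))
  check_congruent(kidney, cyst)
  vox_ml <- prod(kidney$spacing) / 1000
  tkv <- sum(kidney$voxels) * vox_ml
  tcv <- sum(cyst$voxels) * vox_ml
  structure(list(tkv_ml = tkv, tcv_ml = tcv,
                 cystic_index = if (tkv > 0) tcv / tkv else NA_real_),
            class = "volume_stats")
}

#' Signed percent difference of a test volume against a reference
#'
#' @param test_volume,reference_volume Volumes in mL; the reference must be
#'   positive.
#' @return `100 * (test - reference) / reference`.
#' @export
percent_difference <- function(test_volume, reference_volume) {
  if (reference_volume <= 0)
    stop("percent difference undefined for non-positive reference volume")
  100 * (test_volume - reference_volume) / reference_volume
}

#' Bland-Altman agreement analysis
#'
#' Differences are `a - b`; bias is their mean and the limits of agreement
#' are `bias +/- 1.96 * sd` (sample standard deviation, n-1 denominator).
#'
#' @param pairs Two-column matrix or data frame of paired measurements
#'   `(a, b)`, at least 2 pairs.
#' @return List of class `bland_altman` with `bias`, `loa_low`, `loa_high`
#'   and a `points` data frame of per-pair `(mean, difference)`.
#' @export
bland_altman <- function(pairs) {
  pairs <- as.matrix(pairs)
  if (nrow(pairs) < 2 || ncol(pairs) != 2)
    stop("bland_altman needs at least 2 pairs of measurements")
  d <- pairs[, 1] - pairs[, 2]
  bias <- mean(d)
  s <- sd(d)
  structure(list(bias = bias, loa_low = bias - 1.96 * s,
                 loa_high = bias + 1.96 * s,
                 points = data.frame(mean = rowMeans(pairs), difference = d)),
            class = "bland_altman")
}

#' Ordinary least-squares fit with a 95\% confidence band
#'
#' Fits `y = m x + b` and reports the slope, intercept, r-squared and the
#' pointwise 95\% confidence band of the mean response at the observed `x`.
#'
#' @param pairs Two-column matrix or data frame of `(x, y)` points, at least
#'   3, with nonzero x-variance.
#' @return List of class `linear_fit` with `slope`, `intercept`,
#'   `r_squared` and `band` (data frame `x`, `fit`, `lwr`, `upr`).
#' @export
linear_fit <- function(pairs) {
  pairs <- as.data.frame(as.matrix(pairs))
  names(pairs) <- c("x", "y")
  if (nrow(pairs) < 3) stop("linear_fit needs at least 3 points")
  if (sd(pairs$x) == 0) stop("linear_fit needs nonzero x-variance")
  fit <- lm(y ~ x, data = pairs)
  ord <- order(pairs$x)
  ## exactly collinear input is legitimate here; muffle lm's perfect-fit note
  quiet <- function(expr) withCallingHandlers(expr, warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
  band <- quiet(as.data.frame(predict(fit, newdata = pairs[ord, ],
                                      interval = "confidence",
                                      level = 0.95)))
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = quiet(summary(fit)$r.squared),
                 band = data.frame(x = pairs$x[ord], fit = band$fit,
                                   lwr = band$lwr, upr = band$upr)),
            class = "linear_fit")
}

#' Evaluate one segmentation source against a reference over a cohort
#'
#' Produces one metrics row per case (Dice, Jaccard, sensitivity, precision,
#' Hausdorff in voxels, signed TCV percent difference, per-source TCV and
#' cystic index), a cohort summary of mean and sample standard deviation per
#' metric, a Bland-Altman analysis of the cystic index (on the fraction
#' scale) and least-squares regressions of test-vs-reference TCV and cystic
#' index.  Metrics undefined on a case (empty masks) are `NA`, excluded from
#' the summary, and counted in its `n_missing` column.
#'
#' @param cases List of [study_case()] objects carrying both sources.
#' @param test_source,reference_source Names in each case's
#'   `cyst_by_source`; the reference denominates the percent difference.
#' @return List of class `evaluation_report` with `per_case`, `summary`,
#'   `bland_altman_cystic_index`, `regression_tcv`,
#'   `regression_cystic_index`.
#' @export
evaluate_test_set <- function(cases, test_source = "auto",
                              reference_source = "truth") {
  rows <- lapply(cases, function(cs) {
    id <- cs$image$case_id
    tm <- cs$cyst_by_source[[test_source]]
    rm_ <- cs$cyst_by_source[[reference_source]]
    if (is.null(tm)) stop("case ", id, " lacks cyst source '", test_source,
                          "'")
    if (is.null(rm_)) stop("case ", id, " lacks cyst source '",
                           reference_source, "'")
    om <- overlap_metrics(tm, rm_)
    hd <- if (sum(tm$voxels) > 0 && sum(rm_$voxels) > 0)
      hausdorff_vox(tm, rm_) else NA_real_
    vt <- volume_stats(cs$kidney, tm)
    vr <- volume_stats(cs$kidney, rm_)
    pd <- if (vr$tcv_ml > 0) percent_difference(vt$tcv_ml, vr$tcv_ml)
          else NA_real_
    data.frame(case_id = id, dice = om$dice, jaccard = om$jaccard,
               sensitivity = om$sensitivity, precision = om$precision,
               hausdorff_vox = hd, tcv_percent_difference = pd,
               tcv_test_ml = vt$tcv_ml, tcv_ref_ml = vr$tcv_ml,
               cystic_index_test = vt$cystic_index,
               cystic_index_ref = vr$cystic_index)
  })
  per_case <- do.call(rbind, rows)
  metric_cols <- c("dice", "jaccard", "sensitivity", "precision",
                   "hausdorff_vox", "tcv_percent_difference")
  summary_df <- do.call(rbind, lapply(metric_cols, function(mc) {
    v <- per_case[[mc]]
    data.frame(metric = mc, mean = mean(v, na.rm = TRUE),
               sd = sd(v, na.rm = TRUE), n = sum(!is.na(v)),
               n_missing = sum(is.na(v)))
  }))
  ci_pairs <- cbind(per_case$cystic_index_test, per_case$cystic_index_ref)
  ok <- stats::complete.cases(ci_pairs)
  structure(list(
    per_case = per_case,
    summary = summary_df,
    bland_altman_cystic_index = if (sum(ok) >= 2) bland_altman(ci_pairs[ok, ,
                                                                        drop = FALSE]),
    regression_tcv = if (nrow(per_case) >= 3 && sd(per_case$tcv_ref_ml) > 0)
      linear_fit(per_case[, c("tcv_ref_ml", "tcv_test_ml")]),
    regression_cystic_index = if (sum(ok) >= 3 && sd(ci_pairs[ok, 2]) > 0)
      linear_fit(ci_pairs[ok, c(2, 1)])),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Cohort agreement summary (mean ± sd):\n")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-24s %8.3f ± %.3f  (n = %d%s)\n", s$metric[i],
                s$mean[i], s$sd[i], s$n[i],
                if (s$n_missing[i] > 0)
                  paste0(", ", s$n_missing[i], " undefined") else ""))
  invisible(x)
}

#' Render a qualitative two-mask overlay of one slice
#'
#' The background slice is darkened; agreement between the two masks is
#' shown dark gray/translucent, reference-only voxels violet and test-only
#' voxels green.
#'
#' @param image A [voxel_volume()].
#' @param mask_a,mask_b Congruent [binary_mask()] objects (a = reference,
#'   b = test).
#' @param slice_index Coronal slice to render.
#' @param path Output PNG path.
#' @return The path, invisibly.
#' @export
render_overlay <- function(image, mask_a, mask_b, slice_index, path) {
  stopifnot(inherits(image, "voxel_volume"))
  check_congruent(image, mask_a)
  check_congruent(image, mask_b)
  d <- dim(image$voxels)
  if (slice_index < 1 || slice_index > d[3])
    stop("slice_index out of range 1..", d[3])
  sl <- image$voxels[, , slice_index]
  rng <- quantile(sl, c(0.01, 0.99), names = FALSE)
  g <- (sl - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps)
  g <- pmin(pmax(g, 0), 1) * 0.45          # darkened background
  a <- mask_a$voxels[, , slice_index] != 0
  b <- mask_b$voxels[, , slice_index] != 0
  rgb <- array(rep(g, 3), c(d[1], d[2], 3))
  paint <- function(rgb, region, col, alpha = 0.55) {
    for (ch in 1:3) {
      plane <- rgb[, , ch]
      plane[region] <- (1 - alpha) * plane[region] + alpha * col[ch]
      rgb[, , ch] <- plane
    }
    rgb
  }
  rgb <- paint(rgb, a & b, c(0.35, 0.35, 0.35))   # agreement: dark gray
  rgb <- paint(rgb, a & !b, c(0.56, 0.27, 0.93))  # reference only: violet
  rgb <- paint(rgb, b & !a, c(0.20, 0.85, 0.30))  # test only: green
  png::writePNG(rgb, path)
  invisible(path)
}
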