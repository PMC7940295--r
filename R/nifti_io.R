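## Containers and NIfTI-1 input/output.
##
## All geometry is carried in voxel-index space with an explicit (row, column,
## slice) spacing in mm; coronal slices lie along the third axis.  On-disk
## orientation matrices are passed through untouched -- no resampling is ever
## driven by them.

#' Construct an MR intensity volume
#'
#' A `voxel_volume` is a 3-D grid of finite real intensities together with the
#' physical voxel spacing in mm (in-plane row, in-plane column, slice) and a
#' flag recording whether the acquisition was fat saturated.
#'
#' @param voxels 3-D numeric array of finite intensities (arbitrary units).
#' @param spacing Numeric length-3, all positive, in mm.
#' @param case_id Opaque case identifier.
#' @param fat_saturated Logical flag; fat-saturated acquisitions have a dark
#'   background, non-fat-saturated ones a bright, higher-variance background.
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(voxels, spacing = c(1.5, 1.5, 3.0),
                         case_id = "case", fat_saturated = TRUE) {
  voxels <- as_grid3d(voxels)
  if (!all(is.finite(voxels)))
    stop("volume contains non-finite intensities")
  check_spacing(spacing)
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 case_id = as.character(case_id),
                 fat_saturated = isTRUE(fat_saturated)),
            class = "voxel_volume")
}

#' Construct a binary segmentation mask
#'
#' @param voxels 3-D array over \{0, 1\} (any nonzero value is coerced to 1).
#' @param spacing Voxel spacing in mm, as for [voxel_volume()].
#' @param label_role `"kidney"` or `"cyst"`.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(voxels, spacing = c(1.5, 1.5, 3.0),
                        label_role = c("kidney", "cyst")) {
  label_role <- match.arg(label_role)
  voxels <- as_grid3d(voxels)
  if (!all(is.finite(voxels))) stop("mask contains non-finite values")
  voxels <- (voxels != 0) * 1
  check_spacing(spacing)
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 label_role = label_role),
            class = "binary_mask")
}

#' Bundle an image with its kidney mask and any cyst tracings
#'
#' A study case pairs one MR volume with its kidney mask and a named set of
#' cyst masks, keyed by source (`"truth"`, `"reader1"`, `"reader2"`, `"auto"`,
#' ...).  All masks must be congruent with the image.
#'
#' @param image A [voxel_volume()].
#' @param kidney A [binary_mask()] with role `"kidney"`.
#' @param cyst_by_source Named list of cyst [binary_mask()] objects.
#' @return An object of class `study_case`.
#' @export
study_case <- function(image, kidney, cyst_by_source = list()) {
  stopifnot(inherits(image, "voxel_volume"), inherits(kidney, "binary_mask"))
  check_congruent(image, kidney)
  if (length(cyst_by_source)) {
    if (is.null(names(cyst_by_source)) || any(names(cyst_by_source) == ""))
      stop("cyst masks must be named by source")
    for (m in cyst_by_source) check_congruent(image, m)
  }
  structure(list(image = image, kidney = kidney,
                 cyst_by_source = cyst_by_source),
            class = "study_case")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<voxel_volume %s: %dx%dx%d, spacing %.2fx%.2fx%.2f mm, %s>\n",
              x$case_id, d[1], d[2], d[3], x$spacing[1], x$spacing[2],
              x$spacing[3],
              if (x$fat_saturated) "fat-sat" else "non-fat-sat"))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<binary_mask [%s]: %dx%dx%d, %d positive voxels>\n",
              x$label_role, d[1], d[2], d[3], sum(x$voxels)))
  invisible(x)
}

#' @export
print.study_case <- function(x, ...) {
  cat(sprintf("<study_case %s: cyst sources [%s]>\n", x$image$case_id,
              paste(names(x$cyst_by_source), collapse = ", ")))
  invisible(x)
}

as_grid3d <- function(voxels) {
  voxels <- unclass(voxels)
  if (is.null(dim(voxels)) || length(dim(voxels)) != 3)
    stop("expected a 3-D array, got ",
         if (is.null(dim(voxels))) "a vector"
         else paste0(length(dim(voxels)), "-D"))
  storage.mode(voxels) <- "double"
  array(as.numeric(voxels), dim = dim(voxels))
}

check_spacing <- function(spacing) {
  if (length(spacing) != 3 || !all(is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive lengths in mm")
  invisible(spacing)
}

check_congruent <- function(a, b) {
  if (!identical(dim(a$voxels), dim(b$voxels)))
    stop("grids are not congruent: ",
         paste(dim(a$voxels), collapse = "x"), " vs ",
         paste(dim(b$voxels), collapse = "x"))
  if (max(abs(a$spacing - b$spacing)) > 1e-6)
    stop("voxel spacings disagree")
  invisible(TRUE)
}

nifti_array <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  nd <- length(dim(arr))
  if (nd == 4 && dim(arr)[4] == 1) {
    arr <- arr[, , , 1, drop = TRUE]
    nd <- 3
  }
  if (nd != 3)
    stop("expected a 3-D image, got ", nd, "-D: ", path)
  sp <- RNifti::pixdim(img)[seq_len(3)]
  list(arr = arr, spacing = as.numeric(sp))
}

#' Read an MR volume from a NIfTI-1 file
#'
#' @param path Path to a `.nii` or `.nii.gz` file holding a 3-D image.
#' @param case_id Identifier to attach; defaults to the file stem.
#' @param fat_saturated Acquisition flag to attach (not stored in NIfTI).
#' @return A [voxel_volume()] with spacing taken from the file header (mm).
#' @export
read_volume <- function(path, case_id = NULL, fat_saturated = TRUE) {
  x <- nifti_array(path)
  if (is.null(case_id))
    case_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  voxel_volume(x$arr, x$spacing, case_id = case_id,
               fat_saturated = fat_saturated)
}

#' Read a segmentation mask from a NIfTI-1 file
#'
#' Any nonzero on-disk value is mapped to 1, so masks stored as \{0, 255\} or
#' probabilistic outputs already thresholded upstream read identically.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param role `"kidney"` or `"cyst"`.
#' @return A [binary_mask()].
#' @export
read_mask <- function(path, role = c("kidney", "cyst")) {
  x <- nifti_array(path)
  binary_mask(x$arr, x$spacing, label_role = match.arg(role))
}

#' Write a volume or mask to a NIfTI-1 file
#'
#' Masks are stored as unsigned 8-bit \{0, 1\}; volumes as 64-bit float so a
#' round trip is lossless.
#' Spacing is written to `pixdim` so a write/read round trip preserves both
#' voxels and geometry.
#'
#' @param mask A [binary_mask()].
#' @param volume A [voxel_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  arr <- array(as.integer(mask$voxels), dim = dim(mask$voxels))
  attr(arr, "pixdim") <- mask$spacing
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "uint8"), path)
  invisible(path)
}

#' @rdname write_mask
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "voxel_volume"))
  arr <- volume$voxels
  attr(arr, "pixdim") <- volume$spacing
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "double"), path)
  invisible(path)
}
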