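## Synthetic ADPKD-like T2 phantom generator.
##
## The phantoms are geometric stand-ins for coronal T2-weighted abdominal
## slices: two ellipsoidal kidney bodies, spherical cysts placed strictly
## inside them, T2-bright simple cysts and T2-dark complex cysts, and a
## background whose contrast depends on fat saturation.  Only the intensity
## ORDERING (bright cyst > parenchyma > complex cyst) is contractual; the
## absolute levels are arbitrary units.

INTENSITY <- list(bg_fat_sat = 50, bg_non_fat_sat = 400, bg_texture_sd = 80,
                  parenchyma = 300, bright_cyst = 800, complex_cyst = 100)

#' Specification of one synthetic phantom case
#'
#' @param grid_shape Integer length-3 grid size (rows, columns, slices);
#'   64x64x16 is the test scale, 256x256xZ the demo scale.
#' @param spacing Voxel spacing in mm.
#' @param n_cysts Maximum number of cysts placed while chasing the target
#'   cystic index; `0` yields a cyst-free kidney.
#' @param cyst_radius_range Sphere radius interval in mm.
#' @param complex_cyst_fraction Probability that a cyst is rendered T2-dark
#'   (complex) rather than T2-bright.
#' @param target_cystic_index Desired cyst/kidney volume fraction in `[0, 1)`;
#'   the generator stops within 10\% relative of it or raises a feasibility
#'   error naming the binding constraint.
#' @param fat_saturated Logical; selects dark vs bright-textured background.
#' @param noise_sigma Additive Gaussian noise standard deviation (intensity
#'   units).
#' @param seed Integer; a fixed seed makes the case fully reproducible.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 16),
                         spacing = c(1.5, 1.5, 3.0),
                         n_cysts = 200,
                         cyst_radius_range = c(2, 15),
                         complex_cyst_fraction = 0.15,
                         target_cystic_index = 0.25,
                         fat_saturated = TRUE,
                         noise_sigma = 30,
                         seed = 1L) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 1))
  check_spacing(spacing)
  if (n_cysts < 0) stop("n_cysts must be non-negative")
  if (length(cyst_radius_range) != 2 || any(cyst_radius_range <= 0) ||
      diff(cyst_radius_range) < 0)
    stop("cyst_radius_range must be a positive mm interval")
  if (complex_cyst_fraction < 0 || complex_cyst_fraction > 1)
    stop("complex_cyst_fraction must lie in [0, 1]")
  if (target_cystic_index < 0 || target_cystic_index >= 1)
    stop("target_cystic_index must lie in [0, 1)")
  if (noise_sigma < 0) stop("noise_sigma must be non-negative")
  structure(list(grid_shape = as.integer(grid_shape),
                 spacing = as.numeric(spacing),
                 n_cysts = as.integer(n_cysts),
                 cyst_radius_range = as.numeric(cyst_radius_range),
                 complex_cyst_fraction = complex_cyst_fraction,
                 target_cystic_index = target_cystic_index,
                 fat_saturated = isTRUE(fat_saturated),
                 noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

## Ellipsoid indicator evaluated on voxel-index coordinates.
ellipsoid_mask <- function(dims, center, semi_axes) {
  r <- ((seq_len(dims[1]) - center[1]) / semi_axes[1])^2
  c2 <- ((seq_len(dims[2]) - center[2]) / semi_axes[2])^2
  s <- ((seq_len(dims[3]) - center[3]) / semi_axes[3])^2
  e <- outer(outer(r, c2, `+`), s, `+`)
  e <= 1
}

#' Generate one synthetic phantom case
#'
#' Places two jittered ellipsoidal kidneys, then adds spherical cysts (clipped
#' to the kidney, so containment is exact) until the achieved cystic index is
#' within 10\% relative of `target_cystic_index`.  When the remaining deficit
#' is small, candidate radii shrink toward the deficit-matching radius so the
#' target is approached from below without overshoot.
#'
#' @param spec A [phantom_spec()].
#' @param case_id Identifier attached to the emitted volume.
#' @return A [study_case()] whose `cyst_by_source` holds the ground-truth
#'   cyst mask under source `"truth"`.
#' @export
generate_case <- function(spec, case_id = "phantom") {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  d <- spec$grid_shape
  sp <- spec$spacing

  jit <- function() runif(1, -0.08, 0.08)
  kidney <- array(FALSE, d)
  for (col_frac in c(0.28, 0.72)) {
    center <- c(d[1] * (0.5 + 0.1 * jit()), d[2] * col_frac + d[2] * 0.02 * jit(),
                d[3] * (0.5 + 0.1 * jit()))
    semi <- c(0.32 * d[1] * (1 + jit()), 0.15 * d[2] * (1 + jit()),
              0.30 * d[3] * (1 + jit()))
    kidney <- kidney | ellipsoid_mask(d, center, semi)
  }
  K <- sum(kidney)

  ## label grid: 0 background, 1 parenchyma, 2 bright cyst, 3 complex cyst
  lab <- array(0L, d)
  lab[kidney] <- 1L

  cyst <- array(FALSE, d)
  target_vox <- spec$target_cystic_index * K
  if (spec$n_cysts > 0 && target_vox > 0) {
    vox_mm3 <- prod(sp)
    placed <- 0L
    stalled <- 0L
    while (placed < spec$n_cysts && stalled < 25L) {
      n_cyst <- sum(cyst)
      deficit <- target_vox - n_cyst
      if (deficit <= 0.03 * target_vox) break
      r_need <- (3 * deficit * vox_mm3 / (4 * pi))^(1 / 3)
      r <- runif(1, spec$cyst_radius_range[1], spec$cyst_radius_range[2])
      r <- min(r, max(spec$cyst_radius_range[1], r_need))
      free_idx <- which(kidney & !cyst)
      if (!length(free_idx)) break
      ctr <- arrayInd(free_idx[sample.int(length(free_idx), 1)], d)[1, ]
      committed <- FALSE
      for (try in 1:6) {
        rv <- pmax(r / sp, 0.55)           # voxel radii, keep >= half a voxel
        lo <- pmax(floor(ctr - rv), 1)
        hi <- pmin(ceiling(ctr + rv), d)
        bd <- hi - lo + 1
        sphere <- ellipsoid_mask(bd, ctr - lo + 1, rv)
        box <- list(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3])
        inside <- sphere & kidney[box[[1]], box[[2]], box[[3]]]
        add <- inside & !cyst[box[[1]], box[[2]], box[[3]]]
        new_total <- n_cyst + sum(add)
        if (new_total <= 1.05 * target_vox) {
          cyst[box[[1]], box[[2]], box[[3]]] <-
            cyst[box[[1]], box[[2]], box[[3]]] | inside
          is_complex <- runif(1) < spec$complex_cyst_fraction
          sub <- lab[box[[1]], box[[2]], box[[3]]]
          sub[inside] <- if (is_complex) 3L else 2L
          lab[box[[1]], box[[2]], box[[3]]] <- sub
          committed <- TRUE
          break
        }
        r <- r * 0.7
        if (r < spec$cyst_radius_range[1] * 0.999) break
      }
      if (committed) {
        placed <- placed + 1L
        stalled <- 0L
      } else stalled <- stalled + 1L
    }
    achieved <- sum(cyst) / K
    if (abs(achieved - spec$target_cystic_index) >
        0.10 * spec$target_cystic_index)
      stop(sprintf(paste0("cystic index target %.3f infeasible: achieved ",
                          "%.3f with n_cysts = %d and radius range ",
                          "[%.1f, %.1f] mm"),
                   spec$target_cystic_index, achieved, spec$n_cysts,
                   spec$cyst_radius_range[1], spec$cyst_radius_range[2]))
  }

  img <- array(0, d)
  n_bg <- sum(lab == 0L)
  if (spec$fat_saturated) {
    img[lab == 0L] <- INTENSITY$bg_fat_sat
  } else {
    img[lab == 0L] <- INTENSITY$bg_non_fat_sat +
      rnorm(n_bg, 0, INTENSITY$bg_texture_sd)
  }
  img[lab == 1L] <- INTENSITY$parenchyma
  img[lab == 2L] <- INTENSITY$bright_cyst
  img[lab == 3L] <- INTENSITY$complex_cyst
  if (spec$noise_sigma > 0)
    img <- img + rnorm(length(img), 0, spec$noise_sigma)

  vol <- voxel_volume(img, sp, case_id = case_id,
                      fat_saturated = spec$fat_saturated)
  study_case(vol,
             binary_mask(kidney * 1, sp, "kidney"),
             list(truth = binary_mask(cyst * 1, sp, "cyst")))
}

#' Generate a cohort of phantom cases spanning a severity range
#'
#' Cystic-index targets are geometrically spaced across `severity_range`
#' (disease severity spans orders of magnitude, from sub-percent to near-total
#' cystic replacement), and exactly `round(fat_sat_fraction * n_cases)` cases
#' are flagged fat saturated, with the pairing of severity and fat saturation
#' shuffled under the seed.
#'
#' @param n_cases Number of cases, at least 1.
#' @param severity_range Cystic-index interval, e.g. `c(0.005, 0.9)`.
#' @param fat_sat_fraction Proportion of fat-saturated cases.
#' @param seed Master seed; per-case seeds are drawn from it.
#' @param ... Further arguments passed to [phantom_spec()] (e.g.
#'   `grid_shape`, `noise_sigma`).
#' @return List of [study_case()] objects.
#' @export
generate_cohort <- function(n_cases, severity_range = c(0.005, 0.9),
                            fat_sat_fraction = 0.7, seed = 1L, ...) {
  if (n_cases < 1) stop("n_cases must be at least 1")
  if (length(severity_range) != 2 || any(severity_range <= 0) ||
      diff(severity_range) < 0)
    stop("severity_range must be a non-empty positive cystic-index interval")
  if (fat_sat_fraction < 0 || fat_sat_fraction > 1)
    stop("fat_sat_fraction must lie in [0, 1]")
  sev <- if (n_cases == 1) exp(mean(log(severity_range))) else
    exp(seq(log(severity_range[1]), log(severity_range[2]),
            length.out = n_cases))
  n_fs <- round(fat_sat_fraction * n_cases)
  set.seed(seed)
  fat <- sample(c(rep(TRUE, n_fs), rep(FALSE, n_cases - n_fs)))
  case_seeds <- sample.int(.Machine$integer.max - 1L, n_cases)
  lapply(seq_len(n_cases), function(i) {
    generate_case(phantom_spec(target_cystic_index = sev[i],
                               fat_saturated = fat[i],
                               seed = case_seeds[i], ...),
                  case_id = sprintf("case%03d", i))
  })
}

## 6-neighbourhood count of positive voxels, zero-padded borders.
neighbour_count <- function(m) {
  d <- dim(m)
  nb <- array(0, d)
  nb[-1, , ] <- nb[-1, , ] + m[-d[1], , ]
  nb[-d[1], , ] <- nb[-d[1], , ] + m[-1, , ]
  nb[, -1, ] <- nb[, -1, ] + m[, -d[2], ]
  nb[, -d[2], ] <- nb[, -d[2], ] + m[, -1, ]
  if (d[3] > 1) {
    nb[, , -1] <- nb[, , -1] + m[, , -d[3]]
    nb[, , -d[3]] <- nb[, , -d[3]] + m[, , -1]
  }
  nb
}

#' Simulate an alternate reader tracing by stochastic boundary perturbation
#'
#' Emulates interobserver variability: in `ceiling(level)` passes, surface
#' voxels of the mask are randomly eroded and background voxels adjacent to
#' the mask randomly dilated, with per-voxel flip probability proportional to
#' `level`.  Expected Dice against the input decreases monotonically in
#' `level`; `level = 0` returns the input unchanged.
#'
#' @param truth A [binary_mask()].
#' @param perturbation_level Non-negative real perturbation strength.
#' @param seed Integer seed.
#' @return A [binary_mask()] with the same role and spacing.
#' @export
simulate_second_reader <- function(truth, perturbation_level, seed = 1L) {
  stopifnot(inherits(truth, "binary_mask"))
  if (perturbation_level < 0) stop("perturbation_level must be non-negative")
  if (perturbation_level == 0) return(truth)
  set.seed(seed)
  m <- truth$voxels
  rounds <- ceiling(perturbation_level)
  p <- 0.35 * perturbation_level / rounds
  for (r in seq_len(rounds)) {
    nb <- neighbour_count(m)
    surf_in <- m == 1 & nb < 6
    surf_out <- m == 0 & nb > 0
    u <- array(runif(length(m)), dim(m))
    m[surf_in & u < p] <- 0
    m[surf_out & u < p] <- 1
  }
  binary_mask(m, truth$spacing, truth$label_role)
}
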