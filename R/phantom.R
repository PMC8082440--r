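## Synthetic female-thorax phantom factory.
##
## Stand-in for the contoured planning CTs of a mediastinal-lymphoma cohort:
## parameterized geometric primitives on a voxel grid (elliptic-cylinder
## torso, ellipsoidal lungs at reduced density, ellipsoidal heart, anterior
## hemispherical breasts, and a mediastinal PTV tube with optional
## supraclavicular / axillary lobes). Geometry is deterministic given
## (spec, seed); the PTV is realized by thresholding a continuous
## membership field at the exact target voxel count.

#' Anatomy specification for one synthetic patient
#'
#' @param ptv_target_volume_cc requested PTV volume in cc.
#' @param superior_extent,inferior_extent cranio-caudal extent of the PTV in
#'   mm (isocenter-centered z axis, positive = superior). Must lie inside the
#'   grid passed to [generate_patient()].
#' @param supraclavicular logical length 2 (left, right): supraclavicular
#'   nodal involvement per side.
#' @param axillary logical length 2 (left, right): axillary involvement.
#' @param bulky logical, bulky mediastinal disease (wider tube cross-section).
#' @param lateral_offset_mm signed mm offset of the PTV centroid from the
#'   midline (positive = patient left).
#' @return an `anatomy_spec` object.
#' @export
anatomy_spec <- function(ptv_target_volume_cc = 605,
                         superior_extent = 90,
                         inferior_extent = -90,
                         supraclavicular = c(FALSE, FALSE),
                         axillary = c(FALSE, FALSE),
                         bulky = FALSE,
                         lateral_offset_mm = 0) {
  stopifnot(ptv_target_volume_cc > 0,
            superior_extent > inferior_extent,
            length(supraclavicular) == 2L, length(axillary) == 2L,
            is.logical(bulky) || bulky %in% c(0, 1))
  structure(list(ptv_target_volume_cc = as.numeric(ptv_target_volume_cc),
                 superior_extent = as.numeric(superior_extent),
                 inferior_extent = as.numeric(inferior_extent),
                 supraclavicular = as.logical(supraclavicular),
                 axillary = as.logical(axillary),
                 bulky = as.logical(bulky),
                 lateral_offset_mm = as.numeric(lateral_offset_mm)),
            class = "anatomy_spec")
}

#' Cohort specification
#'
#' PTV volumes are drawn log-normally with the given median, clipped to
#' `volume_range_cc`; with the default log-sd of 0.5 clipping affects about
#' 2% of draws. Anatomical variability flags are independent Bernoulli draws.
#'
#' @param n_patients number of patients.
#' @param seed master seed (integer in `[0, 2^30]`); patient i uses seed
#'   `seed + i`.
#' @param volume_median_cc median of the PTV volume distribution (cc).
#' @param volume_sigma_log standard deviation of log-volume.
#' @param volume_range_cc clipping range in cc.
#' @param flag_probabilities named list with per-flag Bernoulli rates
#'   `supraclavicular`, `axillary` (each per side) and `bulky`. The source
#'   study does not print prevalences; these defaults are configurable
#'   choices, not inferences.
#' @return a `cohort_spec` object.
#' @export
cohort_spec <- function(n_patients = 25L, seed = 1L,
                        volume_median_cc = 605,
                        volume_sigma_log = 0.5,
                        volume_range_cc = c(97, 1654),
                        flag_probabilities = list(supraclavicular = 0.3,
                                                  axillary = 0.2,
                                                  bulky = 0.25)) {
  stopifnot(n_patients >= 1, seed >= 0, seed <= 2^30,
            volume_median_cc > 0, volume_sigma_log > 0,
            length(volume_range_cc) == 2L,
            volume_range_cc[1] > 0, diff(volume_range_cc) > 0)
  p <- unlist(flag_probabilities)
  stopifnot(all(p >= 0 & p <= 1))
  structure(list(n_patients = as.integer(n_patients), seed = as.integer(seed),
                 volume_median_cc = volume_median_cc,
                 volume_sigma_log = volume_sigma_log,
                 volume_range_cc = as.numeric(volume_range_cc),
                 flag_probabilities = flag_probabilities),
            class = "cohort_spec")
}

## --- mask primitives (vectorized over the full grid) ---------------------

.ellipse2d <- function(ax_x, ax_y, center, semi) {
  outer(((ax_x - center[1]) / semi[1])^2,
        ((ax_y - center[2]) / semi[2])^2, "+") <= 1
}

.ellipsoid_mask <- function(axes, shape, center, semi) {
  m2 <- outer(((axes$x - center[1]) / semi[1])^2,
              ((axes$y - center[2]) / semi[2])^2, "+")
  array(outer(m2, ((axes$z - center[3]) / semi[3])^2, "+") <= 1, shape)
}

# elliptic cylinder along z restricted to z in [z0, z1]
.tube_mask <- function(axes, shape, center_xy, semi_xy, z0, z1) {
  arr <- array(FALSE, shape)
  zin <- which(axes$z >= z0 & axes$z <= z1)
  if (length(zin)) {
    e2 <- .ellipse2d(axes$x, axes$y, center_xy, semi_xy)
    arr[, , zin] <- e2
  }
  arr
}

.sphere_halfspace_mask <- function(axes, shape, center, radius, y_min) {
  m <- .ellipsoid_mask(axes, shape, center, rep(radius, 3))
  yok <- axes$y >= y_min
  m & array(rep(yok, each = shape[1]), shape)
}

## --- PTV construction with exact volume calibration ----------------------

# Continuous membership field of the PTV shape family: the PTV at lateral
# scale s is {F <= s^2}, so thresholding F at the k-th smallest value
# realizes exactly k voxels. Infinite outside the component z-ranges and
# outside the patient.
.ptv_field <- function(spec, axes, shape, patient) {
  big <- Inf
  q_tube <- function(center_xy, semi_xy, z0, z1) {
    q2 <- outer(((axes$x - center_xy[1]) / semi_xy[1])^2,
                ((axes$y - center_xy[2]) / semi_xy[2])^2, "+")
    F <- array(big, shape)
    zin <- which(axes$z >= z0 & axes$z <= z1)
    if (length(zin)) F[, , zin] <- q2
    F
  }
  base_xy <- if (spec$bulky) c(40, 50) else c(28, 35)
  F <- q_tube(c(spec$lateral_offset_mm, 10), base_xy,
              spec$inferior_extent, spec$superior_extent)
  side_sign <- c(1, -1) # (left, right) in +x = patient-left convention
  for (k in 1:2) {
    if (spec$supraclavicular[k]) {
      F <- pmin(F, q_tube(c(side_sign[k] * 45 + spec$lateral_offset_mm, 22),
                          c(16, 16),
                          spec$superior_extent - 50, spec$superior_extent))
    }
    if (spec$axillary[k]) {
      q3 <- outer(outer(((axes$x - side_sign[k] * 100) / 22)^2,
                        ((axes$y - 30) / 22)^2, "+"),
                  ((axes$z - (spec$superior_extent - 35)) / 32)^2, "+")
      F <- pmin(F, array(q3, shape))
    }
  }
  F[!patient] <- big
  F
}

#' Generate one synthetic patient model
#'
#' Builds all structure masks and the relative electron-density volume on the
#' given grid. The PTV is realized by thresholding its shape-family
#' membership field at the exact target voxel count, so the realized volume
#' matches the request to within half a voxel (the contract is +/-10%); if
#' the shape family cannot reach 90% of the request inside the patient
#' (envelope exhausted), an error is raised.
#'
#' @param spec an [anatomy_spec()].
#' @param seed integer seed controlling per-patient anatomical jitter.
#' @param grid an [rt_grid()].
#' @return a `patient_model`: list with `grid`, `masks` (named logical arrays
#'   `PTV`, `lung_L`, `lung_R`, `heart`, `breast_L`, `breast_R`, `patient`),
#'   `density` (numeric array), `flags` (the realized spec), `seed`.
#' @export
generate_patient <- function(spec, seed, grid = rt_grid()) {
  stopifnot(inherits(spec, "anatomy_spec"), inherits(grid, "rt_grid"))
  axes <- grid_axes(grid)
  half_mm <- grid$voxel_mm / 2
  if (spec$superior_extent > max(axes$z) + half_mm ||
      spec$inferior_extent < min(axes$z) - half_mm) {
    stop("anatomy_spec extents [", spec$inferior_extent, ", ",
         spec$superior_extent, "] mm do not fit the grid z range")
  }

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))

  shape <- grid$shape
  # mild per-patient anatomical jitter (mm)
  torso_a <- min(max(stats::rnorm(1, 145, 8), 125), 158)
  torso_b <- min(max(stats::rnorm(1, 92, 6), 78), 105)
  lung_scale <- stats::runif(1, 0.92, 1.08)
  breast_r <- 50 * stats::runif(1, 0.85, 1.15)
  heart_dx <- stats::rnorm(1, -12, 4)

  torso <- .tube_mask(axes, shape, c(0, 0), c(torso_a, torso_b),
                      min(axes$z) - 1, max(axes$z) + 1)
  lung_semi <- lung_scale * c(48, 66, 105)
  lung_L <- .ellipsoid_mask(axes, shape, c(75, 5, -20), lung_semi)
  lung_R <- .ellipsoid_mask(axes, shape, c(-75, 5, -20), lung_semi)
  heart <- .ellipsoid_mask(axes, shape, c(heart_dx, 12, -60), c(45, 38, 45))
  y_surf <- torso_b * sqrt(pmax(0, 1 - (65 / torso_a)^2))
  breast_L <- .sphere_halfspace_mask(axes, shape, c(65, y_surf, -45),
                                     breast_r, y_surf - 5)
  breast_R <- .sphere_halfspace_mask(axes, shape, c(-65, y_surf, -45),
                                     breast_r, y_surf - 5)

  patient <- torso | breast_L | breast_R
  # enforce pairwise disjoint OARs: heart takes precedence over lungs,
  # thoracic organs over breast tissue
  lung_L <- lung_L & !heart & patient
  lung_R <- lung_R & !heart & patient
  heart <- heart & patient
  breast_L <- breast_L & !lung_L & !lung_R & !heart
  breast_R <- breast_R & !lung_L & !lung_R & !heart

  # exact PTV volume calibration: threshold the membership field at the
  # k-th smallest value (realized count = k up to ties). The lateral scale
  # realized is sqrt of the threshold; shapes beyond scale 6 would leave
  # the mediastinal envelope entirely.
  target_vox <- max(1L, as.integer(round(spec$ptv_target_volume_cc /
                                           voxel_cc(grid))))
  F <- .ptv_field(spec, axes, shape, patient)
  fin_idx <- which(is.finite(F) & F <= 36)
  if (length(fin_idx) < ceiling(0.9 * target_vox)) {
    stop("infeasible anatomy_spec: requested PTV volume ",
         spec$ptv_target_volume_cc,
         " cc exceeds the mediastinal envelope on this grid")
  }
  k <- min(target_vox, length(fin_idx))
  # the tube field is z-invariant, so boundary values tie across slices;
  # a seeded random tie-break spreads the partial boundary ring
  tb <- stats::runif(length(fin_idx))
  sel <- fin_idx[order(F[fin_idx], tb)[seq_len(k)]]
  PTV <- array(FALSE, shape)
  PTV[sel] <- TRUE
  realized_cc <- mask_cc(PTV, grid)
  if (abs(realized_cc - spec$ptv_target_volume_cc) >
      0.1 * spec$ptv_target_volume_cc) {
    stop("PTV volume calibration failed: realized ", round(realized_cc, 1),
         " cc vs requested ", spec$ptv_target_volume_cc, " cc")
  }

  density <- array(0, shape)
  density[patient] <- 1
  density[lung_L | lung_R] <- 0.25

  structure(list(grid = grid,
                 masks = list(PTV = PTV, lung_L = lung_L, lung_R = lung_R,
                              heart = heart, breast_L = breast_L,
                              breast_R = breast_R, patient = patient),
                 density = density,
                 flags = spec,
                 ptv_cc = realized_cc,
                 seed = as.integer(seed)),
            class = "patient_model")
}

#' @exportS3Method base::print
print.patient_model <- function(x, ...) {
  cat(sprintf("<patient_model seed=%d, PTV %.1f cc, %d/%d voxels in patient>\n",
              x$seed, x$ptv_cc, sum(x$masks$patient), prod(x$grid$shape)))
  invisible(x)
}

#' Validate all patient-model invariants
#'
#' Checks mask subset relations, OAR pairwise disjointness, non-empty PTV and
#' the density support contract. Errors on the first violation.
#' @param model a `patient_model`.
#' @return `TRUE` invisibly.
#' @export
validate_patient_model <- function(model) {
  m <- model$masks
  stopifnot(sum(m$PTV) > 0)
  for (nm in c("PTV", "lung_L", "lung_R", "heart", "breast_L", "breast_R")) {
    if (any(m[[nm]] & !m$patient)) stop(nm, " not a subset of patient")
  }
  oars <- c("lung_L", "lung_R", "heart", "breast_L", "breast_R")
  for (i in seq_along(oars)) for (j in seq_along(oars)) {
    if (i < j && any(m[[oars[i]]] & m[[oars[j]]])) {
      stop(oars[i], " and ", oars[j], " overlap")
    }
  }
  if (any(model$density[m$patient] <= 0)) stop("nonpositive density inside patient")
  if (any(model$density[!m$patient] != 0)) stop("nonzero density outside patient")
  invisible(TRUE)
}

#' Generate a synthetic cohort
#'
#' Patient i is generated with seed `cohort$seed + i`; the anatomy draw uses
#' an offset stream so that volume/flag draws and within-patient geometric
#' jitter are independent.
#'
#' @param cohort a [cohort_spec()].
#' @param grid an [rt_grid()] shared by all patients.
#' @return list of `patient_model`s.
#' @export
generate_cohort <- function(cohort, grid = rt_grid()) {
  stopifnot(inherits(cohort, "cohort_spec"))
  lapply(seq_len(cohort$n_patients), function(i) {
    generate_patient(draw_anatomy_spec(cohort, i, grid),
                     seed = cohort$seed + i, grid = grid)
  })
}

#' Draw one anatomy spec from the cohort distribution
#' @param cohort a [cohort_spec()].
#' @param i patient index (1-based).
#' @param grid the target grid (bounds the drawn extents).
#' @return an `anatomy_spec`.
#' @export
draw_anatomy_spec <- function(cohort, i, grid = rt_grid()) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(cohort$seed + i + 1000000000L)

  v <- exp(stats::rnorm(1, log(cohort$volume_median_cc), cohort$volume_sigma_log))
  v <- min(max(v, cohort$volume_range_cc[1]), cohort$volume_range_cc[2])
  z_top <- (grid$shape[3] - 1) / 2 * grid$voxel_mm
  sup <- stats::runif(1, 50, min(110, z_top - 5))
  len <- stats::runif(1, 100, 235)
  len <- max(len, 90, v / 8.5)          # keep cross-section achievable
  inf <- max(sup - len, -(z_top - 8))
  p <- cohort$flag_probabilities
  anatomy_spec(ptv_target_volume_cc = v,
               superior_extent = sup, inferior_extent = inf,
               supraclavicular = stats::runif(2) < p$supraclavicular,
               axillary = stats::runif(2) < p$axillary,
               bulky = stats::runif(1) < p$bulky,
               lateral_offset_mm = min(max(stats::rnorm(1, 0, 12), -30), 30))
}
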