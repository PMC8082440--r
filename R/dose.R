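## Analytic beamlet dose-influence engine (kernel substitute for a Monte
## Carlo engine): parallel beam geometry, exponential attenuation in
## density-weighted (radiological) depth, Gaussian lateral penumbra, sparse
## storage with relative truncation.

#' Kernel parameters of the analytic dose engine
#'
#' @param mu effective linear attenuation per mm of water-equivalent depth
#'   (default 0.005/mm, representative of a 6 MV beam's falloff).
#' @param sigma_penumbra_mm lateral Gaussian spread in mm.
#' @param output_factor dose (Gy) per unit fluence at zero depth on the
#'   beamlet axis.
#' @param trunc_rel influence entries below this fraction of their beamlet's
#'   maximum are truncated to zero (sparsity contract).
#' @export
kernel_params <- function(mu = 0.005, sigma_penumbra_mm = 4,
                          output_factor = 1, trunc_rel = 1e-4) {
  stopifnot(mu > 0, sigma_penumbra_mm > 0, output_factor > 0,
            trunc_rel > 0, trunc_rel < 1)
  structure(list(mu = mu, sigma_penumbra_mm = sigma_penumbra_mm,
                 output_factor = output_factor, trunc_rel = trunc_rel),
            class = "kernel_params")
}

# beam's-eye-view orthonormal frame (e1, e2, u); deterministic function of
# the angles: e1 is the gantry-tangent direction, e2 completes the triad
.bev_frame <- function(beam) {
  g <- .deg2rad(beam$gantry_deg); cc <- .deg2rad(beam$couch_deg)
  u <- as.numeric(beam$unit_vector)
  e1 <- c(cos(g) * cos(cc), -sin(g), -cos(g) * sin(cc))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  list(u = u, e1 = e1, e2 = e2)
}

#' Beamlet lattice for one beam
#'
#' A rectangular, axis-aligned lattice in the beam's-eye-view plane covering
#' the orthographic projection of the PTV dilated by `margin_mm`, centered on
#' the projection's bounding box.
#'
#' @param model a `patient_model`.
#' @param beam a `beam_direction`.
#' @param beamlet_size_mm lateral beamlet spacing at isocenter.
#' @param margin_mm dilation of the PTV projection.
#' @return a `beamlet_grid` with the lattice geometry and BEV frame.
#' @export
build_beamlet_grid <- function(model, beam, beamlet_size_mm = 10,
                               margin_mm = 10) {
  idx <- which(model$masks$PTV)
  if (!length(idx)) stop("empty PTV")
  fr <- .bev_frame(beam)
  P <- voxel_coords(model$grid, idx)
  bu <- as.numeric(P %*% fr$e1)
  bv <- as.numeric(P %*% fr$e2)
  s <- beamlet_size_mm
  half <- model$grid$voxel_mm / 2
  lo_u <- min(bu) - margin_mm - half; hi_u <- max(bu) + margin_mm + half
  lo_v <- min(bv) - margin_mm - half; hi_v <- max(bv) + margin_mm + half
  nu <- max(1L, floor((hi_u - lo_u) / s) + 1L)
  nv <- max(1L, floor((hi_v - lo_v) / s) + 1L)
  u0 <- (lo_u + hi_u) / 2 - (nu - 1) / 2 * s
  v0 <- (lo_v + hi_v) / 2 - (nv - 1) / 2 * s
  structure(list(beam = beam, beamlet_size_mm = s, margin_mm = margin_mm,
                 u0 = u0, v0 = v0, nu = nu, nv = nv, frame = fr),
            class = "beamlet_grid")
}

#' Number of beamlets in a lattice
#' @param bg a `beamlet_grid`.
#' @export
n_beamlets <- function(bg) bg$nu * bg$nv

#' Beamlet center coordinates in the BEV plane
#' @param bg a `beamlet_grid`.
#' @return matrix with columns `u`, `v` (mm), one row per beamlet, column
#'   index order.
#' @export
beamlet_centers <- function(bg) {
  cu <- bg$u0 + (seq_len(bg$nu) - 1) * bg$beamlet_size_mm
  cv <- bg$v0 + (seq_len(bg$nv) - 1) * bg$beamlet_size_mm
  cbind(u = rep(cu, times = bg$nv), v = rep(cv, each = bg$nu))
}

#' Dose influence matrix of one beam
#'
#' For voxel v and beamlet j:
#' `D[v, j] = output_factor * exp(-mu * depth(v)) * exp(-r(v,j)^2 / (2 sigma^2))`
#' where `depth` is the density-weighted depth from the patient surface along
#' the beam axis and `r` the lateral distance from the beamlet ray. Rows for
#' voxels outside the patient are identically zero.
#'
#' @param model a `patient_model`.
#' @param bgrid a [build_beamlet_grid()] result for this model.
#' @param params [kernel_params()].
#' @param voxel_idx linear voxel indices the rows refer to (default: all
#'   voxels of the grid).
#' @param step_mm ray-marching step for radiological depth (default half a
#'   voxel).
#' @return a `dose_influence`: sparse `Matrix::dgCMatrix` (voxels x
#'   beamlets, Gy per unit fluence) plus `voxel_idx`, `beam`, `bgrid`.
#' @export
compute_influence <- function(model, bgrid, params = kernel_params(),
                              voxel_idx = NULL, step_mm = NULL) {
  grid <- model$grid
  if (is.null(voxel_idx)) voxel_idx <- seq_len(prod(grid$shape))
  if (is.null(step_mm)) step_mm <- grid$voxel_mm / 2
  inside <- which(model$masks$patient[voxel_idx])
  m <- length(voxel_idx)
  nb <- n_beamlets(bgrid)
  if (!length(inside)) {
    return(structure(list(matrix = Matrix::sparseMatrix(i = integer(), j = integer(),
                                                        x = numeric(), dims = c(m, nb)),
                          voxel_idx = voxel_idx, beam = bgrid$beam, bgrid = bgrid),
                     class = "dose_influence"))
  }
  P <- voxel_coords(grid, voxel_idx[inside])
  fr <- bgrid$frame
  depth <- cpp_radiological_depth(model$density, grid$shape, grid$voxel_mm,
                                  P, fr$u, step_mm)
  trip <- cpp_influence(depth, as.numeric(P %*% fr$e1), as.numeric(P %*% fr$e2),
                        bgrid$u0, bgrid$v0, bgrid$beamlet_size_mm,
                        bgrid$nu, bgrid$nv,
                        params$mu, params$sigma_penumbra_mm,
                        params$output_factor, params$trunc_rel)
  M <- Matrix::sparseMatrix(i = inside[trip$i + 1L], j = trip$j + 1L,
                            x = trip$x, dims = c(m, nb))
  structure(list(matrix = M, voxel_idx = voxel_idx, beam = bgrid$beam,
                 bgrid = bgrid),
            class = "dose_influence")
}

#' Total dose from a list of per-beam influences and a fluence vector
#'
#' @param influences list of `dose_influence` objects sharing one voxel set.
#' @param fluence nonnegative vector, concatenated per-beam beamlet weights.
#' @return per-voxel dose (Gy), aligned with the shared `voxel_idx`.
#' @export
total_dose <- function(influences, fluence) {
  if (inherits(influences, "dose_influence")) influences <- list(influences)
  nb <- vapply(influences, function(d) ncol(d$matrix), integer(1))
  if (length(fluence) != sum(nb)) {
    stop("fluence length ", length(fluence), " != total beamlet count ", sum(nb))
  }
  if (any(fluence < 0)) stop("negative fluence")
  m <- nrow(influences[[1]]$matrix)
  dose <- numeric(m)
  off <- 0L
  for (d in influences) {
    if (nrow(d$matrix) != m) stop("influences have inconsistent voxel sets")
    k <- ncol(d$matrix)
    if (k > 0) dose <- dose + as.numeric(d$matrix %*% fluence[(off + 1):(off + k)])
    off <- off + k
  }
  dose
}
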