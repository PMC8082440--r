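## Planning context: optimization voxel sampling and per-beam influence
## caching for one patient. Optimization runs on a down-sampled, per-
## structure-capped voxel sample; metric evaluation always uses the full
## grid.

#' Planning context for one patient
#'
#' @param model a `patient_model`.
#' @param kernel [kernel_params()].
#' @param beamlet_size_mm,margin_mm beamlet lattice settings.
#' @param downsample integer voxel decimation factor per axis applied to the
#'   optimization sample (2 per the design default).
#' @param sample_caps named integer vector: maximum sampled voxels per
#'   structure (`PTV`, `heart`, `lungs`, `breast_L`, `breast_R`, `patient`).
#' @return an `rt_context` with the voxel sample and a memoized
#'   `influence(beam)` accessor.
#' @export
planning_context <- function(model, kernel = kernel_params(),
                             beamlet_size_mm = 10, margin_mm = 10,
                             downsample = 2,
                             sample_caps = c(PTV = 250, heart = 120,
                                             lungs = 180, breast_L = 80,
                                             breast_R = 80, patient = 300)) {
  n <- model$grid$shape
  pick <- function(mask, cap, ds) {
    idx <- which(mask)
    if (!is.finite(cap)) return(idx)
    if (ds > 1) {
      i0 <- idx - 1L
      keep <- (i0 %% n[1]) %% ds == 0L &
        ((i0 %/% n[1]) %% n[2]) %% ds == 0L &
        (i0 %/% (n[1] * n[2])) %% ds == 0L
      if (any(keep)) idx <- idx[keep]
    }
    if (length(idx) > cap) idx <- idx[round(seq(1, length(idx), length.out = cap))]
    idx
  }
  vi <- sort(unique(c(
    pick(model$masks$PTV, sample_caps[["PTV"]], 1),
    pick(model$masks$heart, sample_caps[["heart"]], 1),
    pick(model$masks$lung_L | model$masks$lung_R, sample_caps[["lungs"]], 1),
    pick(model$masks$breast_L, sample_caps[["breast_L"]], 1),
    pick(model$masks$breast_R, sample_caps[["breast_R"]], 1),
    pick(model$masks$patient, sample_caps[["patient"]], downsample))))
  cache <- new.env(parent = emptyenv())
  ctx <- list(model = model, kernel = kernel,
              beamlet_size_mm = beamlet_size_mm, margin_mm = margin_mm,
              voxel_idx = vi, cache = cache)
  class(ctx) <- "rt_context"
  ctx
}

#' Optimization-tier influence for a beam, memoized per context
#' @param ctx an `rt_context`.
#' @param beam a `beam_direction`.
#' @export
ctx_influence <- function(ctx, beam) {
  key <- sprintf("g%.4f_c%.4f", beam$gantry_deg, beam$couch_deg)
  if (!is.null(ctx$cache[[key]])) return(ctx$cache[[key]])
  bg <- build_beamlet_grid(ctx$model, beam, ctx$beamlet_size_mm, ctx$margin_mm)
  infl <- compute_influence(ctx$model, bg, ctx$kernel, voxel_idx = ctx$voxel_idx)
  ctx$cache[[key]] <- infl
  infl
}

#' Solve a wish-list for a fixed beam set within a context
#' @param ctx an `rt_context`.
#' @param beams a `beam_set`.
#' @param wl a [wishlist()].
#' @param control a [solver_control()].
#' @export
plan_beams <- function(ctx, beams, wl = default_wishlist(),
                       control = solver_control()) {
  infl <- lapply(seq_len(n_beams(beams)), function(i)
    ctx_influence(ctx, beam_at(beams, i)))
  solve_wishlist(wl, infl, ctx$model, control = control)
}

#' Full-grid dose of a plan
#'
#' Recomputes the influence of each selected beam over all patient voxels
#' (same beamlet lattice as in optimization) and accumulates the fluence-
#' weighted dose. Voxels outside the patient receive zero dose.
#'
#' @param plan an `rt_plan`.
#' @param ctx the `rt_context` the plan was optimized in.
#' @return numeric array of per-voxel dose (Gy) on the full grid.
#' @export
compute_plan_dose <- function(plan, ctx) {
  model <- ctx$model
  full_idx <- seq_len(prod(model$grid$shape))
  dose <- numeric(prod(model$grid$shape))
  off <- 0L
  for (i in seq_len(n_beams(plan$beam_set))) {
    b <- beam_at(plan$beam_set, i)
    k <- plan$beamlets_per_beam[i]
    f <- plan$fluence[(off + 1):(off + k)]
    off <- off + k
    if (all(f == 0)) next
    bg <- build_beamlet_grid(model, b, ctx$beamlet_size_mm, ctx$margin_mm)
    infl <- compute_influence(model, bg, ctx$kernel, voxel_idx = full_idx)
    dose <- dose + as.numeric(infl$matrix %*% f)
  }
  array(dose, model$grid$shape)
}
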