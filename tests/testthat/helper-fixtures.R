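# Shared fixtures: tiny grids and phantoms sized for fast solves. All tests
# are deterministic (fixed seeds).

tiny_grid <- function() rt_grid(c(20L, 14L, 18L), 16)

# ~300 cc mediastinal target, no lobes; 16 mm voxels
tiny_patient <- function(seed = 7) {
  generate_patient(anatomy_spec(300, 70, -70), seed, tiny_grid())
}

tiny_kernel <- function() {
  kernel_params(sigma_penumbra_mm = 12, output_factor = 1, trunc_rel = 1e-3)
}

# influence list over a modest voxel sample for a few coplanar beams
tiny_influences <- function(model, gantries = c(0, 70, 140, -150, -70),
                            stride = 3) {
  vi <- which(model$masks$patient)
  vi <- sort(unique(c(vi[seq(1, length(vi), by = stride)],
                      which(model$masks$PTV),
                      which(model$masks$heart))))
  infl <- lapply(gantries, function(gd)
    compute_influence(model, build_beamlet_grid(model, beam_direction(gd), 25, 15),
                      tiny_kernel(), voxel_idx = vi))
  infl
}

# two-priority wish-list with a nontrivial optimum (patient cap below the
# coverage threshold forces positive underdose)
tight_wishlist <- function() {
  wishlist(
    hard_constraints = list(hard_constraint("patient", "max_dose", 30),
                            hard_constraint("heart", "mean_dose", 1.0)),
    objectives = list(
      objective_entry(1, "PTV", "mean_underdose_below", goal = 0,
                      threshold = 28.5),
      objective_entry(2, "lungs", "mean_dose", goal = 2)))
}

# tiny planning context for BAO tests
tiny_context <- function(model) {
  planning_context(model, tiny_kernel(), beamlet_size_mm = 25, margin_mm = 15,
                   downsample = 2,
                   sample_caps = c(PTV = Inf, heart = 60, lungs = 80,
                                   breast_L = 30, breast_R = 30,
                                   patient = 150))
}

expect_lex_leq <- function(a, b, tol = 1e-3) {
  expect_lte(lexicographic_compare(a, b, tol), 0)
}
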