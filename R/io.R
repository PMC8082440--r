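## YAML serialization of protocol objects and HDF5 persistence of plans and
## influence matrices.

#' Write a wish-list as YAML
#' @param wl a [wishlist()]; @param path output file.
#' @export
write_wishlist_yaml <- function(wl, path) {
  yaml::write_yaml(list(
    prescription_dose = wl$prescription_dose,
    slack_delta = wl$slack_delta,
    hard_constraints = lapply(wl$hard_constraints, function(h)
      list(structure = h$structure, type = h$type, bound = h$bound)),
    objectives = lapply(wl$objectives, function(o) {
      e <- list(priority = o$priority, structure = o$structure, type = o$type,
                goal = o$goal)
      if (!is.na(o$threshold)) e$threshold <- o$threshold
      if (!is.na(o$a)) e$a <- o$a
      e
    })), path)
  invisible(path)
}

#' Read a wish-list from YAML
#' @param path YAML file written by [write_wishlist_yaml()].
#' @export
read_wishlist_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  wishlist(
    hard_constraints = lapply(y$hard_constraints, function(h)
      hard_constraint(h$structure, h$type, h$bound)),
    objectives = lapply(y$objectives, function(o)
      objective_entry(o$priority, o$structure, o$type, o$goal,
                      threshold = o$threshold, a = o$a)),
    slack_delta = y$slack_delta,
    prescription_dose = y$prescription_dose)
}

#' Write a cohort spec as YAML
#' @param cohort a [cohort_spec()]; @param path output file.
#' @export
write_cohort_yaml <- function(cohort, path) {
  yaml::write_yaml(unclass(cohort), path)
  invisible(path)
}

#' Read a cohort spec from YAML
#' @param path YAML file.
#' @export
read_cohort_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  cohort_spec(y$n_patients, y$seed, y$volume_median_cc, y$volume_sigma_log,
              unlist(y$volume_range_cc), y$flag_probabilities)
}

#' Persist a plan to HDF5 (+ dose as NIfTI if provided)
#'
#' @param plan an `rt_plan`.
#' @param path output `.h5` file.
#' @param dose optional full-grid dose array; written next to the plan as
#'   `<path>.dose.nii`.
#' @param voxel_mm voxel size for the dose NIfTI.
#' @export
write_plan_h5 <- function(plan, path, dose = NULL, voxel_mm = NULL) {
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(plan$fluence, path, "fluence")
  rhdf5::h5write(plan$beamlets_per_beam, path, "beamlets_per_beam")
  rhdf5::h5write(cbind(plan$beam_set$gantry_deg, plan$beam_set$couch_deg),
                 path, "beams")
  rhdf5::h5write(plan$objective_values, path, "objective_values")
  rhdf5::h5write(plan$achieved_stage, path, "achieved_stage")
  rhdf5::h5write(plan$bounds, path, "bounds")
  rhdf5::h5write(plan$voxel_idx, path, "voxel_idx")
  rhdf5::h5closeAll()
  if (!is.null(dose)) {
    stopifnot(!is.null(voxel_mm))
    write_nifti(dose, paste0(path, ".dose.nii"), voxel_mm)
  }
  invisible(path)
}

#' Read the persisted parts of a plan from HDF5
#' @param path `.h5` file written by [write_plan_h5()].
#' @return list with fluence, beam set, objective values, bounds, voxel_idx.
#' @export
read_plan_h5 <- function(path) {
  b <- rhdf5::h5read(path, "beams")
  out <- list(fluence = as.numeric(rhdf5::h5read(path, "fluence")),
              beamlets_per_beam = as.integer(rhdf5::h5read(path, "beamlets_per_beam")),
              beam_set = beam_set(b[, 1], b[, 2]),
              objective_values = as.numeric(rhdf5::h5read(path, "objective_values")),
              achieved_stage = as.numeric(rhdf5::h5read(path, "achieved_stage")),
              bounds = as.numeric(rhdf5::h5read(path, "bounds")),
              voxel_idx = as.integer(rhdf5::h5read(path, "voxel_idx")))
  rhdf5::h5closeAll()
  out
}

#' Persist a sparse influence matrix to HDF5 (triplets + shape + beam)
#' @param infl a `dose_influence`; @param path output `.h5` file.
#' @export
write_influence_h5 <- function(infl, path) {
  if (file.exists(path)) file.remove(path)
  M <- methods::as(infl$matrix, "TsparseMatrix")
  rhdf5::h5createFile(path)
  rhdf5::h5write(M@i + 1L, path, "i")
  rhdf5::h5write(M@j + 1L, path, "j")
  rhdf5::h5write(M@x, path, "x")
  rhdf5::h5write(dim(infl$matrix), path, "shape")
  rhdf5::h5write(infl$voxel_idx, path, "voxel_idx")
  rhdf5::h5write(c(infl$beam$gantry_deg, infl$beam$couch_deg), path, "beam")
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read an influence matrix from HDF5
#' @param path `.h5` file written by [write_influence_h5()].
#' @export
read_influence_h5 <- function(path) {
  shape <- as.integer(rhdf5::h5read(path, "shape"))
  M <- Matrix::sparseMatrix(i = as.integer(rhdf5::h5read(path, "i")),
                            j = as.integer(rhdf5::h5read(path, "j")),
                            x = as.numeric(rhdf5::h5read(path, "x")),
                            dims = shape)
  bm <- as.numeric(rhdf5::h5read(path, "beam"))
  out <- structure(list(matrix = M,
                        voxel_idx = as.integer(rhdf5::h5read(path, "voxel_idx")),
                        beam = beam_direction(bm[1], bm[2]), bgrid = NULL),
                   class = "dose_influence")
  rhdf5::h5closeAll()
  out
}

#' Write comparison-table rows and summary as CSV
#' @param tab a `comparison_table`; @param dir output directory.
#' @export
write_comparison_csv <- function(tab, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(tab$rows, file.path(dir, "rows.csv"), row.names = FALSE)
  utils::write.csv(tab$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(excluded = tab$excluded,
                            evaluable = tab$evaluable,
                            patient_order = attr(tab$summary, "patient_order")),
                       file.path(dir, "meta.json"), auto_unbox = FALSE)
  invisible(dir)
}
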