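## Study protocol: for every patient of a synthetic cohort, generate the 24
## beam-configuration plans (CP_5..CP_15, NCP_5..NCP_15, VMAT, B-VMAT),
## evaluate all clinical metrics on the full grid, apply the coverage
## exclusion rule, and aggregate population statistics, Wilcoxon tests and
## beam-direction histograms.

#' Reduced-resolution study profile
#'
#' The full protocol (24 configurations, greedy BAO, full-grid evaluation)
#' at desk-scale settings: 14 mm grid, 20 mm beamlets with a 10 mm
#' penumbra sigma, candidate sets at 20-degree separation (the coplanar
#' ring is a subset of the non-coplanar candidates), capped voxel sampling
#' and bounded solver iterations. Counts and protocol structure are
#' resolution-independent; only dosimetric resolution is reduced.
#'
#' @param n_patients cohort size.
#' @param seed master seed.
#' @param verbose print progress.
#' @export
study_profile_reduced <- function(n_patients = 25L, seed = 1L,
                                  verbose = FALSE) {
  study_config(
    cohort = cohort_spec(n_patients = n_patients, seed = seed),
    grid = rt_grid(c(23L, 16L, 20L), 14),
    kernel = kernel_params(sigma_penumbra_mm = 10, output_factor = 1,
                           trunc_rel = 1e-3),
    beamlet_size_mm = 20, margin_mm = 15,
    downsample = 2,
    # coverage is the one hard requirement: every PTV voxel is sampled
    sample_caps = c(PTV = Inf, heart = 50, lungs = 80, breast_L = 30,
                    breast_R = 30, patient = 200),
    cp_spacing = 20, ncp_min_sep = 20,
    bao = bao_config(
      score_control = solver_control(max_iter = 120L, check_every = 60L,
                                     min_iter = 60L, obj_tol = 1e-3,
                                     feas_tol_rel = 1e-2,
                                     eps_margin_rel = 3e-2,
                                     on_fail = "silent"),
      resolve_control = solver_control(max_iter = 1000L, check_every = 100L,
                                       min_iter = 150L, obj_tol = 1e-4,
                                       feas_tol_rel = 2e-3,
                                       eps_margin_rel = 5e-3,
                                       on_fail = "silent",
                                       stage1_max_iter = 4000L),
      score_depth = 2),
    verbose = verbose)
}

#' The 24 study configuration labels
#' @export
study_labels <- function() {
  c(sprintf("CP_%d", 5:15), sprintf("NCP_%d", 5:15), "VMAT", "BVMAT")
}

#' Study configuration
#'
#' @param cohort a [cohort_spec()].
#' @param grid the phantom grid.
#' @param wl the wish-list driving all plans.
#' @param kernel dose-kernel parameters.
#' @param beamlet_size_mm,margin_mm,downsample,sample_caps planning-context
#'   settings (see [planning_context()]).
#' @param cp_spacing gantry spacing of the coplanar candidate set (degrees).
#' @param ncp_min_sep minimum separation of the non-coplanar candidates.
#' @param collision collision mask for the non-coplanar candidates.
#' @param bao a [bao_config()].
#' @param normalize rescale each plan's fluence so full-grid PTV coverage
#'   reaches the prescription isodose where the 110% ceiling allows
#'   (prescription renormalization, standard planning practice).
#' @param compute_pvalues run pairwise Wilcoxon tests per metric.
#' @param verbose print per-patient progress.
#' @export
study_config <- function(cohort = cohort_spec(), grid = rt_grid(),
                         wl = default_wishlist(),
                         kernel = kernel_params(),
                         beamlet_size_mm = 10, margin_mm = 10,
                         downsample = 2,
                         sample_caps = c(PTV = 250, heart = 120, lungs = 180,
                                         breast_L = 80, breast_R = 80,
                                         patient = 300),
                         cp_spacing = 10, ncp_min_sep = 10,
                         collision = default_collision_mask(),
                         bao = bao_config(),
                         normalize = TRUE,
                         compute_pvalues = TRUE,
                         verbose = FALSE) {
  cfg <- structure(list(cohort = cohort, grid = grid, wl = wl, kernel = kernel,
                        beamlet_size_mm = beamlet_size_mm,
                        margin_mm = margin_mm, downsample = downsample,
                        sample_caps = sample_caps, cp_spacing = cp_spacing,
                        ncp_min_sep = ncp_min_sep, collision = collision,
                        bao = bao, normalize = normalize,
                        compute_pvalues = compute_pvalues, verbose = verbose,
                        configurations = study_labels(), x_range = 5:15),
                   class = "study_config")
  stopifnot(length(cfg$configurations) == 24)
  cfg
}

# prescription renormalization: scale fluence so that (nearly) 95% of the
# PTV reaches 95% of the prescription, within the 110% ceiling
.normalize_fluence_scale <- function(dose, model, prescription = 30) {
  dp <- dose[model$masks$PTV]
  q <- stats::quantile(dp, 0.04, names = FALSE)
  if (q <= 0) return(1)
  s <- 0.95 * prescription / q
  mx <- max(dose[model$masks$patient])
  if (mx > 0) s <- min(s, 1.105 * prescription / mx)
  max(1, s)
}

# all 24 plans for one patient; returns rows, selections and plan summaries
.study_patient <- function(model, cfg, cp_cand, ncp_cand, patient_id) {
  ctx <- planning_context(model, cfg$kernel, cfg$beamlet_size_mm,
                          cfg$margin_mm, cfg$downsample, cfg$sample_caps)
  x_max <- max(cfg$x_range)
  res <- list(rows = NULL, selections = list(), p1 = list())

  eval_plan <- function(plan, label) {
    dose <- compute_plan_dose(plan, ctx)
    if (cfg$normalize) {
      s <- .normalize_fluence_scale(dose, model, cfg$wl$prescription_dose)
      dose <- dose * s
    }
    met <- compute_metrics(dose, model, cfg$wl$prescription_dose)
    rep <- check_goals(met)
    cbind(data.frame(patient_id = patient_id, configuration = label,
                     coverage_ok = coverage_ok(rep), solver_failed = FALSE),
          met)
  }
  failed_row <- function(label) {
    met <- as.data.frame(as.list(stats::setNames(rep(NA_real_,
                                                     length(metric_names())),
                                                 metric_names())))
    cbind(data.frame(patient_id = patient_id, configuration = label,
                     coverage_ok = FALSE, solver_failed = TRUE), met)
  }

  rows <- list()
  for (kind in c("CP", "NCP")) {
    cand <- if (kind == "CP") cp_cand else ncp_cand
    bao_res <- tryCatch(
      greedy_select(model, cand, x_max, cfg$wl, cfg$bao, ctx),
      error = function(e) e)
    if (inherits(bao_res, "error")) {
      for (x in cfg$x_range) rows[[paste0(kind, "_", x)]] <-
          failed_row(paste0(kind, "_", x))
      next
    }
    res$selections[[kind]] <- bao_res$selected
    res$p1[[kind]] <- bao_res$obj_after[, 1]
    for (x in cfg$x_range) {
      label <- paste0(kind, "_", x)
      plan_x <- bao_res$iterates[[x]]
      rows[[label]] <- tryCatch(eval_plan(plan_x, label),
                                error = function(e) failed_row(label))
    }
  }
  for (cls in c("VMAT", "BVMAT")) {
    beams <- if (cls == "VMAT") build_vmat_surrogate() else build_bvmat()
    rows[[cls]] <- tryCatch(
      eval_plan(plan_beams(ctx, beams, cfg$wl, cfg$bao$resolve_control), cls),
      error = function(e) failed_row(cls))
  }
  res$rows <- do.call(rbind, rows)
  rownames(res$rows) <- NULL
  res
}

#' Run the full comparison study on a synthetic cohort
#'
#' For every patient: CP_x and NCP_x (x = 5..15) by greedy beam-angle
#' selection (one nested greedy run per candidate set), plus the VMAT and
#' B-VMAT class solutions; all plans evaluated on the full grid. Patients
#' with any plan failing the coverage requirement (PTV V95% >= 95%) are
#' excluded from population analyses.
#'
#' @param cfg a [study_config()].
#' @return a `comparison_table`: `rows` (one per patient x configuration),
#'   `excluded` patient ids, `summary` (per-configuration mean and range per
#'   metric), `pvalues` (config x config x metric array, if requested),
#'   `selections` and `candidates` (for beam-direction histograms), `p1`
#'   (per-iteration priority-1 values per patient), and the `config` echo.
#' @export
run_study <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  cp_cand <- enumerate_coplanar_candidates(cfg$cp_spacing)
  ncp_cand <- enumerate_noncoplanar_candidates(cfg$ncp_min_sep, cfg$collision)
  rows <- list(); selections <- list(); p1 <- list()
  for (i in seq_len(cfg$cohort$n_patients)) {
    t0 <- Sys.time()
    model <- generate_patient(draw_anatomy_spec(cfg$cohort, i, cfg$grid),
                              seed = cfg$cohort$seed + i, grid = cfg$grid)
    pr <- .study_patient(model, cfg, cp_cand, ncp_cand, i)
    rows[[i]] <- pr$rows
    selections[[i]] <- pr$selections
    p1[[i]] <- pr$p1
    if (cfg$verbose) {
      message(sprintf("patient %d/%d: PTV %.0f cc, %d plans, %.1fs",
                      i, cfg$cohort$n_patients, model$ptv_cc, nrow(pr$rows),
                      as.numeric(Sys.time() - t0, units = "secs")))
    }
  }
  rows <- do.call(rbind, rows)
  bad <- unique(rows$patient_id[!rows$coverage_ok])
  evaluable <- setdiff(unique(rows$patient_id), bad)
  tab <- structure(list(rows = rows, excluded = bad, evaluable = evaluable,
                        selections = selections, p1 = p1,
                        candidates = list(CP = cp_cand, NCP = ncp_cand),
                        config = cfg),
                   class = "comparison_table")
  tab$summary <- population_summary(tab)
  if (cfg$compute_pvalues && length(evaluable) >= 2) {
    tab$pvalues <- .pairwise_wilcoxon(tab)
  }
  tab
}

#' @exportS3Method base::print
print.comparison_table <- function(x, ...) {
  cat(sprintf("<comparison_table: %d rows, %d evaluable / %d patients, %d excluded>\n",
              nrow(x$rows), length(x$evaluable),
              length(unique(x$rows$patient_id)), length(x$excluded)))
  invisible(x)
}

#' Population mean and range per metric per configuration
#'
#' Computed over evaluable patients only. Also emits the patient ordering by
#' descending heart mean dose in the NCP_15 plans (the convention used for
#' per-patient comparison figures).
#'
#' @param tab a `comparison_table`.
#' @return data frame (configuration, metric, mean, min, max) with attribute
#'   `patient_order`.
#' @export
population_summary <- function(tab) {
  rows <- tab$rows[tab$rows$patient_id %in% tab$evaluable &
                     !tab$rows$solver_failed, , drop = FALSE]
  if (!nrow(rows)) stop("no evaluable patients")
  mets <- metric_names()
  out <- do.call(rbind, lapply(split(rows, rows$configuration), function(d) {
    do.call(rbind, lapply(mets, function(mn) {
      v <- d[[mn]]
      data.frame(configuration = d$configuration[1], metric = mn,
                 mean = mean(v), min = min(v), max = max(v))
    }))
  }))
  rownames(out) <- NULL
  ncp15 <- rows[rows$configuration == "NCP_15", ]
  attr(out, "patient_order") <-
    ncp15$patient_id[order(ncp15$heart_dmean_gy, decreasing = TRUE)]
  out
}

# two-sided Wilcoxon signed-rank p-values for every configuration pair and
# metric, paired over evaluable patients
.pairwise_wilcoxon <- function(tab) {
  rows <- tab$rows[tab$rows$patient_id %in% tab$evaluable, , drop = FALSE]
  cfgs <- study_labels()
  mets <- metric_names()
  arr <- array(NA_real_, dim = c(length(cfgs), length(cfgs), length(mets)),
               dimnames = list(cfgs, cfgs, mets))
  wide <- lapply(cfgs, function(cg) {
    d <- rows[rows$configuration == cg, ]
    d[order(d$patient_id), ]
  })
  names(wide) <- cfgs
  for (a in seq_along(cfgs)) for (b in seq_along(cfgs)) {
    if (a >= b) next
    for (mi in seq_along(mets)) {
      va <- wide[[a]][[mets[mi]]]; vb <- wide[[b]][[mets[mi]]]
      if (anyNA(va) || anyNA(vb)) next
      p <- wilcoxon_signed_rank(va, vb)$p_value
      arr[a, b, mi] <- p; arr[b, a, mi] <- p
    }
  }
  arr
}

#' Histogram of selected beam directions on the candidate lattice
#'
#' @param tab a `comparison_table`.
#' @param configuration a `CP_x` or `NCP_x` label (class solutions have
#'   fixed geometry and no selection — error).
#' @return data frame (gantry_deg, couch_deg, count) over the full candidate
#'   set; attribute `total` is the summed count (evaluable patients times x)
#'   and attribute `bvmat` carries the B-VMAT beam set for overlay.
#' @export
beam_direction_histogram <- function(tab, configuration) {
  mt <- regmatches(configuration,
                   regexec("^(CP|NCP)_([0-9]+)$", configuration))[[1]]
  if (!length(mt)) {
    stop("beam histograms are defined for CP_x/NCP_x only, not ",
         configuration)
  }
  kind <- mt[2]; x <- as.integer(mt[3])
  cand <- tab$candidates[[kind]]
  counts <- integer(n_beams(cand))
  for (pid in tab$evaluable) {
    sel <- tab$selections[[pid]][[kind]]
    if (is.null(sel)) next
    sel_x <- sel[seq_len(min(x, length(sel)))]
    for (s in sel_x) counts[s] <- counts[s] + 1L
  }
  out <- data.frame(gantry_deg = cand$gantry_deg,
                    couch_deg = cand$couch_deg, count = counts)
  attr(out, "total") <- sum(counts)
  attr(out, "bvmat") <- build_bvmat()
  out
}
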