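## Exact DVH and clinical plan-parameter computation. Vx metrics use the
## ">= threshold" convention; cc values are voxel count times voxel volume
## (no sub-voxel interpolation); percentage metrics are relative to their own
## structure volume. V95%/V107%/V110% thresholds are percentages of the
## prescription dose (30 Gy), per the clinical protocol phrasing.

#' Cumulative dose-volume histogram
#'
#' @param dose per-voxel dose (array or vector over the grid).
#' @param mask logical structure mask.
#' @param bin_width_gy dose bin width (Gy).
#' @return data frame (`dose_gy`, `volume_pct`), monotone non-increasing
#'   from 100% at 0 Gy; `volume_pct` at `t` is the percentage of structure
#'   voxels with dose >= t.
#' @export
compute_dvh <- function(dose, mask, bin_width_gy = 0.1) {
  if (!any(mask)) stop("empty structure mask")
  stopifnot(bin_width_gy > 0)
  d <- sort(as.numeric(dose[mask]))
  m <- length(d)
  tmax <- max(d, 0)
  t <- seq(0, tmax + bin_width_gy, by = bin_width_gy)
  n_lt <- findInterval(t, d, left.open = TRUE) # voxels strictly below t
  structure(data.frame(dose_gy = t, volume_pct = 100 * (m - n_lt) / m),
            class = c("dvh", "data.frame"))
}

# % of structure with dose >= t
.v_pct <- function(dose, mask, t) 100 * sum(dose[mask] >= t) / sum(mask)
# cc of structure with dose >= t (or < t)
.v_cc <- function(dose, mask, t, grid, below = FALSE) {
  n <- if (below) sum(dose[mask] < t) else sum(dose[mask] >= t)
  n * voxel_cc(grid)
}

#' Clinical plan metrics
#'
#' Computes the study's plan parameters: PTV V95%/V<90%(cc)/V107%/V110%,
#' conformity index CI = (cc of patient >= 95% of prescription) / (cc of
#' PTV), per-OAR mean doses, breast V4Gy (%), lungs V5Gy/V20Gy (%) and
#' patient V5Gy/V20Gy (cc). `lungs` is the union of both lungs.
#'
#' @param dose per-voxel dose over the full grid (array or vector).
#' @param model a `patient_model`.
#' @param prescription prescription dose in Gy.
#' @return a one-row data frame of class `plan_metrics`.
#' @export
compute_metrics <- function(dose, model, prescription = 30) {
  need <- c("PTV", "lung_L", "lung_R", "heart", "breast_L", "breast_R", "patient")
  for (nm in need) {
    if (is.null(model$masks[[nm]])) stop("missing mask: ", nm)
  }
  if (length(dose) != prod(model$grid$shape)) {
    stop("dose length does not match the grid")
  }
  g <- model$grid
  msk <- model$masks
  lungs <- msk$lung_L | msk$lung_R
  t95 <- 0.95 * prescription
  t90 <- 0.90 * prescription
  t107 <- 1.07 * prescription
  t110 <- 1.10 * prescription
  out <- data.frame(
    ptv_v95_pct = .v_pct(dose, msk$PTV, t95),
    ptv_vunder90_cc = .v_cc(dose, msk$PTV, t90, g, below = TRUE),
    ptv_v107_pct = .v_pct(dose, msk$PTV, t107),
    ptv_v110_pct = .v_pct(dose, msk$PTV, t110),
    ci = .v_cc(dose, msk$patient, t95, g) / mask_cc(msk$PTV, g),
    heart_dmean_gy = mean(dose[msk$heart]),
    lungs_dmean_gy = mean(dose[lungs]),
    breast_l_dmean_gy = mean(dose[msk$breast_L]),
    breast_r_dmean_gy = mean(dose[msk$breast_R]),
    breast_l_v4_pct = .v_pct(dose, msk$breast_L, 4),
    breast_r_v4_pct = .v_pct(dose, msk$breast_R, 4),
    lungs_v5_pct = .v_pct(dose, lungs, 5),
    lungs_v20_pct = .v_pct(dose, lungs, 20),
    patient_v5_cc = .v_cc(dose, msk$patient, 5, g),
    patient_v20_cc = .v_cc(dose, msk$patient, 20, g))
  class(out) <- c("plan_metrics", "data.frame")
  out
}

#' Metric column names of a `plan_metrics` row
#' @export
metric_names <- function() {
  c("ptv_v95_pct", "ptv_vunder90_cc", "ptv_v107_pct", "ptv_v110_pct", "ci",
    "heart_dmean_gy", "lungs_dmean_gy", "breast_l_dmean_gy",
    "breast_r_dmean_gy", "breast_l_v4_pct", "breast_r_v4_pct",
    "lungs_v5_pct", "lungs_v20_pct", "patient_v5_cc", "patient_v20_cc")
}

#' Check clinical planning goals
#'
#' Evaluates the printed protocol goals: PTV V95% >= 95% (coverage), V110%
#' < 1%, V<90% < 5 cc (preferably < 2 cc), breast Dmean < 5 Gy (< 2 Gy),
#' heart Dmean < 26 Gy (< 10 Gy), lungs Dmean < 15 Gy (< 13.5 Gy), lungs
#' V5Gy < 55% (< 50%) and lungs V20Gy < 30%.
#'
#' @param metrics a `plan_metrics` row.
#' @return a `goal_report`: data frame (name, threshold, preferred,
#'   achieved, pass, preferred_pass) plus attribute `coverage_ok`.
#' @export
check_goals <- function(metrics) {
  gl <- list(
    # name, achieved, direction, required, preferred (NA = none)
    list("ptv_v95_pct", metrics$ptv_v95_pct, ">=", 95, NA),
    list("ptv_v110_pct", metrics$ptv_v110_pct, "<", 1, NA),
    list("ptv_vunder90_cc", metrics$ptv_vunder90_cc, "<", 5, 2),
    list("breast_l_dmean_gy", metrics$breast_l_dmean_gy, "<", 5, 2),
    list("breast_r_dmean_gy", metrics$breast_r_dmean_gy, "<", 5, 2),
    list("heart_dmean_gy", metrics$heart_dmean_gy, "<", 26, 10),
    list("lungs_dmean_gy", metrics$lungs_dmean_gy, "<", 15, 13.5),
    list("lungs_v5_pct", metrics$lungs_v5_pct, "<", 55, 50),
    list("lungs_v20_pct", metrics$lungs_v20_pct, "<", 30, NA))
  rows <- lapply(gl, function(e) {
    ach <- e[[2]]
    pass <- if (e[[3]] == ">=") ach >= e[[4]] else ach < e[[4]]
    ppass <- if (is.na(e[[5]])) NA else {
      if (e[[3]] == ">=") ach >= e[[5]] else ach < e[[5]]
    }
    data.frame(name = e[[1]], threshold = e[[4]], preferred = e[[5]],
               achieved = ach, pass = pass, preferred_pass = ppass)
  })
  out <- do.call(rbind, rows)
  attr(out, "coverage_ok") <- metrics$ptv_v95_pct >= 95
  class(out) <- c("goal_report", "data.frame")
  out
}

#' Coverage flag of a goal report
#' @param report a `goal_report`.
#' @export
coverage_ok <- function(report) isTRUE(attr(report, "coverage_ok"))
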