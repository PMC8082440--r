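## Wish-list protocol types: ordered hard constraints plus prioritized
## convex objectives with goal values, driving the staged epsilon-constraint
## optimization.

.obj_types <- c("mean_dose", "mean_underdose_below", "mean_overdose_above", "gEUD")
.con_types <- c("max_dose", "mean_dose")

#' A hard constraint entry
#' @param structure structure name (see [get_structure_mask()]).
#' @param type `max_dose` or `mean_dose`.
#' @param bound bound in Gy.
#' @export
hard_constraint <- function(structure, type = c("max_dose", "mean_dose"), bound) {
  type <- match.arg(type)
  stopifnot(is.numeric(bound), length(bound) == 1)
  list(structure = structure, type = type, bound = as.numeric(bound))
}

#' A prioritized objective entry
#' @param priority unique priority rank (1 = most important).
#' @param structure structure name.
#' @param type objective type: `mean_dose`, `mean_underdose_below`,
#'   `mean_overdose_above` or `gEUD`.
#' @param goal goal value in Gy (or Gy-equivalent).
#' @param threshold threshold in Gy for the under/overdose types.
#' @param a gEUD exponent (only for `gEUD`).
#' @export
objective_entry <- function(priority, structure, type, goal,
                            threshold = NULL, a = NULL) {
  type <- match.arg(type, .obj_types)
  if (type %in% c("mean_underdose_below", "mean_overdose_above")) {
    stopifnot(!is.null(threshold), threshold >= 0)
  }
  if (type == "gEUD") stopifnot(!is.null(a), a > 0)
  stopifnot(goal >= 0)
  list(priority = as.integer(priority), structure = structure, type = type,
       goal = as.numeric(goal),
       threshold = if (is.null(threshold)) NA_real_ else as.numeric(threshold),
       a = if (is.null(a)) NA_real_ else as.numeric(a))
}

#' Construct a wish-list
#'
#' @param hard_constraints list of [hard_constraint()]s.
#' @param objectives list of [objective_entry()]s; priorities must be unique
#'   and consecutive starting at 1.
#' @param slack_delta relative relaxation applied to an unattained goal when
#'   descending priorities.
#' @param prescription_dose prescription in Gy.
#' @export
wishlist <- function(hard_constraints, objectives, slack_delta = 0.03,
                     prescription_dose = 30) {
  stopifnot(slack_delta >= 0, prescription_dose > 0)
  pri <- vapply(objectives, `[[`, integer(1), "priority")
  if (!identical(sort(pri), seq_along(pri))) {
    stop("objective priorities must be unique and consecutive from 1")
  }
  objectives <- objectives[order(pri)]
  for (h in hard_constraints) {
    if (!h$type %in% .con_types) stop("bad hard constraint type: ", h$type)
    if (h$bound < 0) stop("negative hard bound")
  }
  structure(list(hard_constraints = hard_constraints, objectives = objectives,
                 slack_delta = slack_delta,
                 prescription_dose = prescription_dose),
            class = "wishlist")
}

#' @exportS3Method base::print
print.wishlist <- function(x, ...) {
  cat(sprintf("<wishlist: %d hard constraints, %d priorities, slack %.3g, Rx %g Gy>\n",
              length(x$hard_constraints), length(x$objectives), x$slack_delta,
              x$prescription_dose))
  for (h in x$hard_constraints)
    cat(sprintf("  hard  %-9s %s <= %g Gy\n", h$structure, h$type, h$bound))
  for (o in x$objectives)
    cat(sprintf("  %2d    %-9s %s%s, goal %g\n", o$priority, o$structure, o$type,
                if (!is.na(o$threshold)) sprintf("(%g Gy)", o$threshold) else "",
                o$goal))
  invisible(x)
}

#' Default wish-list reconstructed from the printed clinical protocol
#'
#' Prescription 30 Gy in 15 fractions. Hard maximum of 110% of prescription
#' on PTV and patient; priorities: PTV coverage (mean underdose below 95% of
#' prescription), then heart, lungs and per-breast mean dose with the
#' protocol's preferred thresholds as goals (heart 10, lungs 13.5, breast
#' 2 Gy), a lungs low-dose surrogate (mean overdose above 5 Gy; convex
#' surrogate for lungs V5Gy), and finally patient mean dose (conformality).
#' The clinical wish-list itself is not published; this is a reconstruction
#' from the printed protocol values and is documented as such.
#' @export
default_wishlist <- function() {
  rx <- 30
  wishlist(
    hard_constraints = list(
      hard_constraint("PTV", "max_dose", 1.1 * rx),
      hard_constraint("patient", "max_dose", 1.1 * rx)),
    objectives = list(
      objective_entry(1, "PTV", "mean_underdose_below", goal = 0,
                      threshold = 0.95 * rx),
      objective_entry(2, "heart", "mean_dose", goal = 10),
      objective_entry(3, "lungs", "mean_dose", goal = 13.5),
      objective_entry(4, "breast_L", "mean_dose", goal = 2),
      objective_entry(5, "breast_R", "mean_dose", goal = 2),
      objective_entry(6, "lungs", "mean_overdose_above", goal = 1.5,
                      threshold = 5),
      objective_entry(7, "patient", "mean_dose", goal = 0)),
    slack_delta = 0.03,
    prescription_dose = rx)
}

#' Resolve a structure name to a mask
#'
#' Knows the model's native masks plus the unions `lungs` (both lungs) and
#' `breasts` (both breasts).
#' @param model a `patient_model`.
#' @param name structure name.
#' @export
get_structure_mask <- function(model, name) {
  m <- model$masks
  switch(name,
         lungs = m$lung_L | m$lung_R,
         breasts = m$breast_L | m$breast_R,
         {
           if (is.null(m[[name]])) stop("unknown structure: ", name)
           m[[name]]
         })
}

#' Evaluate a convex objective on a dose distribution
#'
#' `mean_dose` is the mean over the mask; `mean_underdose_below(t)` the mean
#' of `max(t - d, 0)`; `mean_overdose_above(t)` the mean of `max(d - t, 0)`;
#' `gEUD(a)` the generalized equivalent uniform dose `mean(d^a)^(1/a)`.
#'
#' @param dose numeric vector/array of per-voxel dose (Gy).
#' @param mask logical vector/array, same length.
#' @param type objective type.
#' @param threshold threshold in Gy (under/overdose types).
#' @param a gEUD exponent.
#' @return value in Gy.
#' @export
evaluate_objective <- function(dose, mask, type, threshold = NULL, a = NULL) {
  type <- match.arg(type, .obj_types)
  if (!any(mask)) stop("empty structure mask")
  d <- dose[mask]
  switch(type,
         mean_dose = mean(d),
         mean_underdose_below = {
           stopifnot(!is.null(threshold)); mean(pmax(threshold - d, 0))
         },
         mean_overdose_above = {
           stopifnot(!is.null(threshold)); mean(pmax(d - threshold, 0))
         },
         gEUD = {
           stopifnot(!is.null(a), a > 0); mean(d^a)^(1 / a)
         })
}
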