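## Integrated beam-angle optimization: greedy add-one selection of x
## directions from a candidate set, wrapped around the wish-list optimizer.
## Selection is nested: the first k selections do not depend on the target
## count x, so one greedy run to x_max yields all CP_x / NCP_x plans as
## prefixes.

#' Compare two prioritized objective vectors lexicographically
#'
#' @param a,b numeric vectors of equal length (priority order).
#' @param tol absolute tolerance below which two entries are considered
#'   equal.
#' @return -1 if `a` is better (smaller at the first differing priority),
#'   0 if equal, 1 if `b` is better.
#' @export
lexicographic_compare <- function(a, b, tol = 1e-6) {
  if (length(a) != length(b)) stop("objective vectors differ in length")
  for (i in seq_along(a)) {
    if (abs(a[i] - b[i]) > tol) return(if (a[i] < b[i]) -1L else 1L)
  }
  0L
}

#' Beam-angle optimization configuration
#'
#' @param scoring_mode `incremental` (fix the incumbent dose, optimize only
#'   the candidate's beamlets; the default) or `full` (wish-list re-solve of
#'   incumbent plus candidate for every candidate).
#' @param score_control solver control for candidate scoring.
#' @param resolve_control solver control for the per-iteration full
#'   re-optimization of the incumbent.
#' @param keep_iterates keep each iteration's re-optimized plan (needed to
#'   read CP_x plans off one greedy run).
#' @export
#' @param score_depth number of leading priorities used during candidate
#'   scoring (the full wish-list is always used for the re-optimization);
#'   `Inf` scores with all priorities.
#' @param score_control_coverage solver control used for scoring while the
#'   incumbent's priority-1 (coverage) objective is still positive; beam
#'   choice matters most there, so more iterations are spent.
bao_config <- function(scoring_mode = c("incremental", "full"),
                       score_control = control_score(),
                       resolve_control = control_fast(),
                       keep_iterates = TRUE,
                       score_depth = 3,
                       score_control_coverage = NULL,
                       resolve_control_coverage = NULL) {
  if (is.null(score_control_coverage)) {
    score_control_coverage <- score_control
    score_control_coverage$max_iter <- 4L * score_control$max_iter
  }
  if (is.null(resolve_control_coverage)) {
    resolve_control_coverage <- resolve_control
    resolve_control_coverage$max_iter <- 4L * resolve_control$max_iter
    if (!is.null(resolve_control$stage1_max_iter)) {
      resolve_control_coverage$stage1_max_iter <-
        3L * resolve_control$stage1_max_iter
    }
  }
  structure(list(scoring_mode = match.arg(scoring_mode),
                 score_control = score_control,
                 resolve_control = resolve_control,
                 keep_iterates = keep_iterates,
                 score_depth = score_depth,
                 score_control_coverage = score_control_coverage,
                 resolve_control_coverage = resolve_control_coverage),
            class = "bao_config")
}

# restrict a wish-list to its first `depth` priorities (scoring shortcut)
.truncate_wishlist <- function(wl, depth) {
  np <- length(wl$objectives)
  if (!is.finite(depth) || depth >= np) return(wl)
  wishlist(wl$hard_constraints, wl$objectives[seq_len(depth)],
           wl$slack_delta, wl$prescription_dose)
}

# objective vector of the zero-fluence state (the "before" of iteration 1)
.zero_objective <- function(wl, model, voxel_idx) {
  vapply(wl$objectives, function(o) {
    mask <- get_structure_mask(model, o$structure)
    d <- numeric(sum(mask[voxel_idx]))
    switch(.solver_obj_type(o),
           mean_dose = 0,
           mean_underdose_below = o$threshold,
           mean_overdose_above = 0)
  }, numeric(1))
}

#' Greedy beam-angle selection
#'
#' Starting from an empty incumbent, each of `x` iterations scores every
#' unselected candidate by the objective vector of incumbent + candidate
#' (per `scoring_mode`), selects the lexicographically best (ties broken by
#' lowest couch, then lowest gantry — the candidate ordering), then fully
#' re-optimizes the fluence of the enlarged incumbent.
#'
#' @param model a `patient_model`.
#' @param candidates a candidate `beam_set` (ordered by couch, then gantry).
#' @param x number of beams to select (1 <= x <= number of candidates).
#' @param wl a [wishlist()].
#' @param config a [bao_config()].
#' @param ctx optional [planning_context()]; built with defaults if omitted.
#' @return a `bao_result`: `plan` (final re-optimized plan), `selected`
#'   (candidate indices in selection order), `trace` (per-iteration data
#'   frame), `obj_before`/`obj_after` matrices, and (if kept) the
#'   per-iteration plans in `iterates`.
#' @export
greedy_select <- function(model, candidates, x, wl = default_wishlist(),
                          config = bao_config(), ctx = NULL) {
  nc <- n_beams(candidates)
  if (x < 1 || x > nc) stop("x must be in 1..", nc)
  if (is.null(ctx)) ctx <- planning_context(model)
  infl_cand <- vector("list", nc)
  get_infl <- function(i) {
    if (is.null(infl_cand[[i]])) {
      infl_cand[[i]] <<- ctx_influence(ctx, beam_at(candidates, i))
    }
    infl_cand[[i]]
  }
  np <- length(wl$objectives)
  m <- length(ctx$voxel_idx)
  incumbent <- integer(0)
  d_inc <- numeric(m)
  plan_prev <- NULL
  obj_before <- matrix(NA_real_, x, np)
  obj_after <- matrix(NA_real_, x, np)
  iterates <- if (config$keep_iterates) vector("list", x) else NULL
  cur_obj <- .zero_objective(wl, model, ctx$voxel_idx)

  wl_score <- .truncate_wishlist(wl, config$score_depth)
  score_warm <- vector("list", nc) # per-candidate warm-start fluence

  for (it in seq_len(x)) {
    remaining <- setdiff(seq_len(nc), incumbent)
    best_i <- NA_integer_; best_score <- NULL
    coverage_phase <- cur_obj[1] > 1e-3
    sctl <- if (coverage_phase) config$score_control_coverage
            else config$score_control
    for (ci in remaining) {
      sc <- if (config$scoring_mode == "incremental") {
        sp <- solve_wishlist(wl_score, list(get_infl(ci)), model,
                             control = sctl, dose_offset = d_inc,
                             x0 = score_warm[[ci]])
        score_warm[[ci]] <- sp$fluence
        sp$objective_values
      } else {
        solve_wishlist(wl_score, lapply(c(incumbent, ci), get_infl), model,
                       control = sctl)$objective_values
      }
      if (is.null(best_score) || lexicographic_compare(sc, best_score) < 0L) {
        best_score <- sc; best_i <- ci
      }
    }
    obj_before[it, ] <- cur_obj
    incumbent <- c(incumbent, best_i)
    x0 <- if (!is.null(plan_prev)) {
      c(plan_prev$fluence, numeric(ncol(get_infl(best_i)$matrix)))
    } else NULL
    rctl <- if (coverage_phase) config$resolve_control_coverage
            else config$resolve_control
    plan_prev <- solve_wishlist(wl, lapply(incumbent, get_infl), model,
                                control = rctl, x0 = x0)
    d_inc <- plan_prev$dose_sample
    cur_obj <- plan_prev$objective_values
    obj_after[it, ] <- cur_obj
    if (config$keep_iterates) iterates[[it]] <- plan_prev
  }

  trace <- data.frame(iteration = seq_len(x),
                      gantry_deg = candidates$gantry_deg[incumbent],
                      couch_deg = candidates$couch_deg[incumbent])
  structure(list(plan = plan_prev, selected = incumbent, trace = trace,
                 obj_before = obj_before, obj_after = obj_after,
                 iterates = iterates, candidates = candidates),
            class = "bao_result")
}
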