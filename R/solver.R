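## Staged (lexicographic / epsilon-constraint) fluence optimization.
##
## Each priority is one convex stage: minimize that objective subject to the
## hard constraints and to bounds on all higher-priority objectives. Bounds
## follow the 2-phase convention: an attained goal is constrained at the
## goal; an unattained one at achieved * (1 + slack_delta). Stages are
## solved with a diagonally preconditioned primal-dual first-order method
## (see src/pdhg.cpp); epsilon-constraints are posed with a small internal
## feasibility margin so that the recorded bounds hold for the returned
## fluence to well below 1e-6.

#' Solver control settings
#'
#' @param max_iter iteration cap per stage.
#' @param check_every convergence-check interval.
#' @param min_iter minimum iterations before stopping.
#' @param obj_tol relative objective-change stopping tolerance.
#' @param feas_tol_rel feasibility tolerance, relative to `1 + |bound|`.
#' @param eps_margin_rel internal tightening of epsilon-constraint bounds,
#'   relative to `1 + |bound|`; must exceed `feas_tol_rel`.
#' @param balance primal/dual step balance factor.
#' @param on_fail behavior when a stage fails to converge: `error`, `warn`
#'   or `silent`.
#' @export
solver_control <- function(max_iter = 20000L, check_every = 250L,
                           min_iter = 500L, obj_tol = 1e-6,
                           feas_tol_rel = 2e-4, eps_margin_rel = 5e-4,
                           balance = 4, on_fail = c("warn", "error", "silent"),
                           polish = FALSE, polish_max_dim = 2000L,
                           stage1_max_iter = NULL) {
  stopifnot(eps_margin_rel > feas_tol_rel)
  structure(list(max_iter = as.integer(max_iter),
                 check_every = as.integer(check_every),
                 min_iter = as.integer(min_iter),
                 obj_tol = obj_tol, feas_tol_rel = feas_tol_rel,
                 eps_margin_rel = eps_margin_rel, balance = balance,
                 on_fail = match.arg(on_fail), polish = polish,
                 polish_max_dim = as.integer(polish_max_dim),
                 stage1_max_iter = if (is.null(stage1_max_iter)) NULL
                                   else as.integer(stage1_max_iter)),
            class = "solver_control")
}

#' High-accuracy control (tiny problems, contract tests)
#'
#' First-order solve followed by an exact proximal-point LP polish
#' (quadprog); suitable for the small fixtures used in oracle and contract
#' tests, not for full study runs.
#' @export
control_accurate <- function() {
  solver_control(max_iter = 20000L, check_every = 500L, min_iter = 1000L,
                 obj_tol = 1e-6, feas_tol_rel = 2e-5, eps_margin_rel = 2e-4,
                 on_fail = "error", polish = TRUE)
}

#' Fast control for study runs and greedy re-solves
#' @export
control_fast <- function() {
  solver_control(max_iter = 1200L, check_every = 100L, min_iter = 150L,
                 obj_tol = 1e-4, feas_tol_rel = 2e-3, eps_margin_rel = 5e-3,
                 on_fail = "silent", stage1_max_iter = 5000L)
}

#' Very fast control for candidate scoring inside greedy selection
#' @export
control_score <- function() {
  solver_control(max_iter = 250L, check_every = 100L, min_iter = 100L,
                 obj_tol = 1e-3, feas_tol_rel = 1e-2, eps_margin_rel = 3e-2,
                 on_fail = "silent")
}

# R-side evaluation of a stage state: objective value and maximum
# feasibility violation relative to the per-block tolerances
.eval_stage_r <- function(A_full, map, d0, kind, r0, r1, wgt, thr, bnd, ftol, x) {
  z0 <- as.numeric(A_full %*% x)
  obj <- NA_real_; maxviol <- 0
  for (b in seq_along(kind)) {
    k <- kind[b]
    if (k == 7L) next
    rs <- r0[b]:r1[b]
    d <- z0[map[rs]] + d0[rs]
    w <- wgt[b]; t <- thr[b]; B <- bnd[b]
    val <- NA_real_
    if (k == 0L) obj <- w * sum(d)
    else if (k == 1L) obj <- w * sum(pmax(t - d, 0))
    else if (k == 2L) obj <- w * sum(pmax(d - t, 0))
    else if (k == 3L) val <- max(d) - B
    else if (k == 4L) val <- w * sum(d) - B
    else if (k == 5L) val <- w * sum(pmax(t - d, 0)) - B
    else if (k == 6L) val <- w * sum(pmax(d - t, 0)) - B
    else if (k == 8L) val <- max(t - d)
    else if (k == 9L) val <- max(d - t)
    if (!is.na(val)) maxviol <- max(maxviol, max(0, val) / max(ftol[b], 1e-300))
  }
  list(obj = obj, maxviol = maxviol)
}

# objective kind codes shared with src/pdhg.cpp
.kind_obj <- c(mean_dose = 0L, mean_underdose_below = 1L,
               mean_overdose_above = 2L)
.kind_con <- c(mean_dose = 4L, mean_underdose_below = 5L,
               mean_overdose_above = 6L)

# normalize gEUD(a=1) to mean_dose; error otherwise (solver scope)
.solver_obj_type <- function(o) {
  if (o$type == "gEUD") {
    if (isTRUE(all.equal(o$a, 1))) return("mean_dose")
    stop("solve_wishlist supports gEUD only with a = 1 (mean dose); ",
         "got a = ", o$a)
  }
  o$type
}

#' Solve a wish-list over a fixed beam set
#'
#' @param wl a [wishlist()].
#' @param influences list of `dose_influence` objects (one per beam) sharing
#'   a common `voxel_idx` (the optimization voxel sample).
#' @param model the `patient_model`.
#' @param control a [solver_control()].
#' @param dose_offset optional fixed per-voxel dose (Gy, over `voxel_idx`)
#'   added to the optimized dose; used for incremental candidate scoring.
#' @param x0 optional warm-start fluence.
#' @return an `rt_plan`: fluence, per-stage achieved values and bounds,
#'   final objective vector, solver status, and the sampled-voxel dose.
#'   Full-grid dose is computed separately (see [compute_plan_dose()]).
#' @export
solve_wishlist <- function(wl, influences, model, control = solver_control(),
                           dose_offset = NULL, x0 = NULL) {
  stopifnot(inherits(wl, "wishlist"))
  if (inherits(influences, "dose_influence")) influences <- list(influences)
  if (!length(influences)) stop("empty beam set")
  voxel_idx <- influences[[1]]$voxel_idx
  m <- length(voxel_idx)
  A_full <- do.call(cbind, lapply(influences, `[[`, "matrix"))
  n <- ncol(A_full)
  if (is.null(dose_offset)) dose_offset <- numeric(m)
  stopifnot(length(dose_offset) == m)

  # infeasibility pre-check: a nonpositive hard dose cap forces zero fluence,
  # which cannot satisfy a coverage (underdose) objective
  has_cov <- any(vapply(wl$objectives, function(o) {
    o$type == "mean_underdose_below" && o$threshold > 0
  }, logical(1)))
  for (h in wl$hard_constraints) {
    if (h$bound <= 0 && has_cov) {
      stop("infeasible wish-list at priority 1: hard ", h$type, "(",
           h$structure, ") <= ", h$bound,
           " admits only zero dose but a coverage objective is present")
    }
  }

  # row groups: stack one block per hard constraint and per objective
  add_group <- function(structure) {
    mask <- get_structure_mask(model, structure)
    rows <- which(mask[voxel_idx])
    rows
  }
  hard <- list(); objs <- list()
  for (h in wl$hard_constraints) {
    rows <- add_group(h$structure)
    if (!length(rows)) next
    hard[[length(hard) + 1]] <- c(h, list(rows = rows))
  }
  for (o in wl$objectives) {
    rows <- add_group(o$structure)
    if (!length(rows)) {
      stop("objective structure ", o$structure, " has no voxels in the sample")
    }
    o$solver_type <- .solver_obj_type(o)
    objs[[length(objs) + 1]] <- c(o, list(rows = rows))
  }

  all_rows <- c(lapply(hard, `[[`, "rows"), lapply(objs, `[[`, "rows"))
  block_len <- lengths(all_rows)
  stack_rows <- unlist(all_rows, use.names = FALSE)
  d0 <- dose_offset[stack_rows]
  r1 <- cumsum(block_len); r0 <- r1 - block_len + 1L
  nh <- length(hard); np <- length(objs)

  # static block descriptors
  kind0 <- integer(nh + np); wgt <- numeric(nh + np)
  thr <- numeric(nh + np); bndv <- numeric(nh + np); ftl <- rep(1, nh + np)
  for (k in seq_len(nh)) {
    h <- hard[[k]]
    kind0[k] <- if (h$type == "max_dose") 3L else 4L
    wgt[k] <- 1 / block_len[k]
    bndv[k] <- h$bound
    ftl[k] <- control$feas_tol_rel * (1 + abs(h$bound))
  }
  for (j in seq_len(np)) {
    o <- objs[[j]]
    wgt[nh + j] <- 1 / block_len[nh + j]
    thr[nh + j] <- if (!is.na(o$threshold)) o$threshold else 0
  }

  achieved <- numeric(np); bounds <- numeric(np)
  # per-priority epsilon-constraint posing, decided after each stage:
  # ckind/cbound/cthr/cftol describe how priority j is enforced downstream
  ckind <- integer(np); cbound <- numeric(np); cthr <- numeric(np)
  cftol <- numeric(np)
  status <- vector("list", np)
  x <- if (is.null(x0)) numeric(n) else {
    stopifnot(length(x0) == n); pmax(x0, 0)
  }
  y0 <- numeric(sum(block_len))
  emr <- control$eps_margin_rel

  for (i in seq_len(np)) {
    kind <- kind0
    for (j in seq_len(np)) {
      bj <- nh + j
      if (j < i) {
        kind[bj] <- ckind[j]
        bndv[bj] <- cbound[j]
        thr[bj] <- cthr[j]
        ftl[bj] <- cftol[j]
      } else if (j == i) {
        kind[bj] <- .kind_obj[[objs[[j]]$solver_type]]
        thr[bj] <- if (!is.na(objs[[j]]$threshold)) objs[[j]]$threshold else 0
      } else {
        kind[bj] <- 7L
      }
    }
    mi <- if (i == 1L && !is.null(control$stage1_max_iter))
      control$stage1_max_iter else control$max_iter
    res <- cpp_pdhg_stage(A_full, stack_rows - 1L, d0, kind, r0 - 1L, r1 - 1L,
                          wgt, thr, bndv, ftl,
                          x, y0, mi, control$check_every,
                          control$min_iter, control$obj_tol, control$balance)
    if (control$polish) {
      xp <- .polish_stage(A_full, stack_rows, d0, kind, r0, r1, wgt, thr, bndv,
                          as.numeric(res$x), max_dim = control$polish_max_dim)
      if (!is.null(xp)) {
        st <- .eval_stage_r(A_full, stack_rows, d0, kind, r0, r1, wgt, thr,
                            bndv, ftl, xp)
        # the polished point is the exact optimum of the (tightened) stage
        # LP; accept it whenever it is feasible — the first-order iterate it
        # replaces may be slightly infeasible with a lower objective
        if (st$maxviol <= 1) {
          res$x <- xp; res$objective <- st$obj; res$max_rel_viol <- st$maxviol
          res$converged <- TRUE; res$feasible <- TRUE
        }
      }
    }
    if (!res$converged || !res$feasible) {
      msg <- sprintf("stage %d (%s %s) did not converge: %d iters, max relative violation %.3g",
                     i, objs[[i]]$structure, objs[[i]]$type, res$iters,
                     res$max_rel_viol)
      if (control$on_fail == "error") stop(msg)
      if (control$on_fail == "warn") warning(msg)
    }
    x <- as.numeric(res$x)
    achieved[i] <- res$objective
    o <- objs[[i]]
    hinge <- o$solver_type %in% c("mean_underdose_below", "mean_overdose_above")
    tj <- if (!is.na(o$threshold)) o$threshold else 0
    if (hinge && o$goal < 1e-9 && achieved[i] <= 0.5 * emr * (1 + tj)) {
      # goal-0 hinge objective attained: enforce per-row at a slightly
      # tightened threshold so the recorded bound (0) holds exactly
      bounds[i] <- 0
      m_abs <- emr * (1 + tj)
      ckind[i] <- if (o$solver_type == "mean_underdose_below") 8L else 9L
      cthr[i] <- if (ckind[i] == 8L) tj + m_abs else tj - m_abs
      cbound[i] <- 0
      cftol[i] <- 0.4 * m_abs
    } else if (achieved[i] <= o$goal - emr * (1 + o$goal)) {
      # attained with margin: constrain at the goal, tightened internally
      m_abs <- emr * (1 + o$goal)
      bounds[i] <- o$goal
      ckind[i] <- .kind_con[[o$solver_type]]
      cthr[i] <- tj
      cbound[i] <- o$goal - m_abs
      cftol[i] <- 0.4 * m_abs
    } else {
      # not attained (or within margin of the goal): relax by slack_delta
      bounds[i] <- max(achieved[i], o$goal) * (1 + wl$slack_delta)
      m_abs <- emr * (1 + bounds[i])
      ckind[i] <- .kind_con[[o$solver_type]]
      cthr[i] <- tj
      cbound[i] <- max(bounds[i] - m_abs, achieved[i])
      cftol[i] <- 0.4 * m_abs
    }
    status[[i]] <- list(converged = res$converged, feasible = res$feasible,
                        iters = res$iters, max_rel_viol = res$max_rel_viol)
  }

  dose_sample <- dose_offset + as.numeric(A_full %*% x)
  objective_values <- vapply(seq_len(np), function(j) {
    o <- objs[[j]]
    d <- dose_sample[o$rows]
    switch(o$solver_type,
           mean_dose = mean(d),
           mean_underdose_below = mean(pmax(o$threshold - d, 0)),
           mean_overdose_above = mean(pmax(d - o$threshold, 0)))
  }, numeric(1))

  beams <- beam_set(vapply(influences, function(d) d$beam$gantry_deg, numeric(1)),
                    vapply(influences, function(d) d$beam$couch_deg, numeric(1)))
  nb <- vapply(influences, function(d) ncol(d$matrix), integer(1))
  structure(list(beam_set = beams,
                 fluence = x,
                 beamlets_per_beam = nb,
                 objective_values = objective_values,
                 achieved_stage = achieved,
                 bounds = bounds,
                 bounds_internal = cbound,
                 solver_status = status,
                 voxel_idx = voxel_idx,
                 dose_sample = dose_sample,
                 wishlist = wl),
            class = "rt_plan")
}

#' @exportS3Method base::print
print.rt_plan <- function(x, ...) {
  cat(sprintf("<rt_plan: %d beams, %d beamlets; objective values: %s>\n",
              n_beams(x$beam_set), length(x$fluence),
              paste(signif(x$objective_values, 4), collapse = ", ")))
  invisible(x)
}
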