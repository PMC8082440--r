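# wishlist_optimizer: objective evaluation, protocol defaults, staged solve
# contracts, independent LP oracle

test_that("evaluate_objective closed forms", {
  mask <- c(rep(TRUE, 50), rep(FALSE, 30))
  expect_equal(evaluate_objective(rep(30, 80), mask, "mean_dose"), 30)
  d <- c(rep(29, 50), rep(0, 30))
  expect_equal(evaluate_objective(d, mask, "mean_underdose_below",
                                  threshold = 28.5), 0)
  set.seed(5)
  for (k in 1:10) {
    dd <- runif(80, 0, 40)
    expect_equal(evaluate_objective(dd, mask, "gEUD", a = 1),
                 evaluate_objective(dd, mask, "mean_dose"), tolerance = 1e-12)
    t <- runif(1, 5, 35)
    expect_equal(evaluate_objective(dd, mask, "mean_underdose_below",
                                    threshold = t),
                 mean(pmax(t - dd[mask], 0)))
    expect_equal(evaluate_objective(dd, mask, "mean_overdose_above",
                                    threshold = t),
                 mean(pmax(dd[mask] - t, 0)))
    a <- runif(1, 1, 8)
    expect_equal(evaluate_objective(dd, mask, "gEUD", a = a),
                 mean(dd[mask]^a)^(1 / a))
  }
  expect_error(evaluate_objective(d, rep(FALSE, 80), "mean_dose"), "empty")
})

test_that("default wish-list encodes the printed protocol", {
  wl <- default_wishlist()
  expect_s3_class(wl, "wishlist")
  o1 <- wl$objectives[[1]]
  expect_equal(o1$structure, "PTV")             # coverage is priority 1
  expect_equal(o1$type, "mean_underdose_below")
  expect_equal(o1$threshold, 28.5)              # 95% of 30 Gy
  goals <- vapply(wl$objectives, `[[`, numeric(1), "goal")
  structs <- vapply(wl$objectives, `[[`, character(1), "structure")
  expect_equal(goals[structs == "heart"], 10)    # heart Dmean preferred
  expect_equal(goals[structs == "lungs"][1], 13.5) # lungs Dmean preferred
  expect_equal(goals[structs == "breast_L"], 2)  # breast Dmean preferred
  expect_equal(goals[structs == "breast_R"], 2)
  hb <- vapply(wl$hard_constraints, `[[`, numeric(1), "bound")
  expect_true(all(hb == 33))                     # 110% of prescription
  # invariants: unique consecutive priorities
  pri <- vapply(wl$objectives, `[[`, integer(1), "priority")
  expect_identical(sort(pri), seq_along(pri))
})

test_that("wishlist constructor validates its invariants", {
  hc <- list(hard_constraint("PTV", "max_dose", 33))
  o <- function(p) objective_entry(p, "heart", "mean_dose", goal = 10)
  expect_error(wishlist(hc, list(o(1), o(1))), "unique and consecutive")
  expect_error(wishlist(hc, list(o(2))), "unique and consecutive")
  expect_error(objective_entry(1, "PTV", "mean_underdose_below", goal = -1,
                               threshold = 28.5))
  expect_error(objective_entry(1, "PTV", "gEUD", goal = 1, a = -2))
})

test_that("single-priority solve matches an independent scipy LP oracle", {
  # the stage problem is an LP; scipy.optimize.linprog (HiGHS) through the
  # system python is the independent oracle on this tiny fixture
  m <- tiny_patient()
  infl <- tiny_influences(m)
  wl1 <- wishlist(tight_wishlist()$hard_constraints,
                  tight_wishlist()$objectives[1])
  plan <- solve_wishlist(wl1, infl, m, control = control_accurate())

  vi <- infl[[1]]$voxel_idx
  A <- as.matrix(do.call(cbind, lapply(infl, `[[`, "matrix")))
  td <- tempfile("lporacle"); dir.create(td)
  utils::write.csv(A, file.path(td, "A.csv"), row.names = FALSE)
  writeLines(as.character(which(m$masks$PTV[vi])), file.path(td, "ptv.txt"))
  writeLines(as.character(which(m$masks$patient[vi])), file.path(td, "pat.txt"))
  writeLines(as.character(which(m$masks$heart[vi])), file.path(td, "heart.txt"))
  py <- file.path(td, "oracle.py")
  writeLines(c(
    "import sys, numpy as np",
    "from scipy.optimize import linprog",
    "from scipy import sparse",
    "td = sys.argv[1]",
    "A = np.loadtxt(td + '/A.csv', delimiter=',', skiprows=1)",
    "ptv = np.loadtxt(td + '/ptv.txt', dtype=int) - 1",
    "pat = np.loadtxt(td + '/pat.txt', dtype=int) - 1",
    "heart = np.loadtxt(td + '/heart.txt', dtype=int) - 1",
    "m, n = A.shape; mp = len(ptv)",
    "c = np.concatenate([np.zeros(n), np.ones(mp) / mp])",
    "A1 = sparse.hstack([-sparse.csr_matrix(A[ptv]), -sparse.eye(mp)])",
    "A2 = sparse.hstack([sparse.csr_matrix(A[pat]), sparse.csr_matrix((len(pat), mp))])",
    "A3 = sparse.hstack([sparse.csr_matrix(A[heart].mean(axis=0)), sparse.csr_matrix((1, mp))])",
    "b = np.concatenate([-28.5 * np.ones(mp), 30 * np.ones(len(pat)), [1.0]])",
    "res = linprog(c, A_ub=sparse.vstack([A1, A2, A3]), b_ub=b,",
    "              bounds=(0, None), method='highs')",
    "print(repr(res.fun))"), py)
  out <- system2("python", c(py, td), stdout = TRUE)
  oracle <- as.numeric(out[length(out)])
  expect_false(is.na(oracle))
  expect_equal(plan$achieved_stage[1], oracle,
               tolerance = 1e-4 * max(1, abs(oracle)))
})

test_that("solve_wishlist respects the lexicographic bound contract", {
  m <- tiny_patient()
  infl <- tiny_influences(m)
  plan <- solve_wishlist(default_wishlist(), infl, m,
                         control = control_accurate())
  expect_true(all(plan$objective_values <= plan$bounds + 1e-6))
  expect_equal(length(plan$objective_values),
               length(default_wishlist()$objectives))
  # dose consistency: recorded sampled dose equals A x
  A <- do.call(cbind, lapply(infl, `[[`, "matrix"))
  expect_equal(plan$dose_sample, as.numeric(A %*% plan$fluence),
               tolerance = 1e-12)
})

test_that("infeasible hard constraints are rejected", {
  m <- tiny_patient()
  infl <- tiny_influences(m, gantries = c(0, 90))
  wl <- wishlist(
    hard_constraints = list(hard_constraint("patient", "max_dose", 0)),
    objectives = list(objective_entry(1, "PTV", "mean_underdose_below",
                                      goal = 0, threshold = 28.5)))
  expect_error(solve_wishlist(wl, infl, m), "infeasible")
})

test_that("gEUD objectives are evaluated exactly but solved only for a = 1", {
  m <- tiny_patient()
  infl <- tiny_influences(m, gantries = c(0, 90))
  wl_bad <- wishlist(
    hard_constraints = list(hard_constraint("patient", "max_dose", 33)),
    objectives = list(objective_entry(1, "heart", "gEUD", goal = 5, a = 2)))
  expect_error(solve_wishlist(wl_bad, infl, m), "gEUD")
  wl_ok <- wishlist(
    hard_constraints = list(hard_constraint("patient", "max_dose", 33)),
    objectives = list(objective_entry(1, "heart", "gEUD", goal = 5, a = 1)))
  plan <- solve_wishlist(wl_ok, infl, m, control = control_fast())
  expect_s3_class(plan, "rt_plan")
})

test_that("scale equivariance: doubling output_factor halves the fluence", {
  m <- tiny_patient()
  vi <- sort(unique(c(which(m$masks$PTV), which(m$masks$heart),
                      which(m$masks$patient)[seq(1, sum(m$masks$patient), 4)])))
  mk <- function(of) {
    kp <- kernel_params(sigma_penumbra_mm = 12, output_factor = of,
                        trunc_rel = 1e-3)
    lapply(c(0, 120, -120), function(gd)
      compute_influence(m, build_beamlet_grid(m, beam_direction(gd), 25, 15),
                        kp, voxel_idx = vi))
  }
  ctl <- control_accurate()
  p1 <- solve_wishlist(tight_wishlist(), mk(1), m, control = ctl)
  p2 <- solve_wishlist(tight_wishlist(), mk(2), m, control = ctl)
  expect_equal(p2$achieved_stage[1], p1$achieved_stage[1], tolerance = 1e-4)
  expect_equal(p2$dose_sample, p1$dose_sample, tolerance = 5e-3)
})

test_that("monotonicity in the beam set (extra beams never hurt priority 1)", {
  m <- tiny_patient()
  ctl <- control_accurate()
  inflA <- tiny_influences(m, gantries = c(0, 140))
  inflB <- tiny_influences(m, gantries = c(0, 140, -70))
  pA <- solve_wishlist(tight_wishlist(), inflA, m, control = ctl)
  pB <- solve_wishlist(tight_wishlist(), inflB, m, control = ctl)
  expect_lte(pB$achieved_stage[1],
             pA$achieved_stage[1] * (1 + 1e-4) + 1e-6)
})
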