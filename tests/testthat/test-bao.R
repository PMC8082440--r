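# bao_engine: lexicographic comparison, greedy selection, exhaustive oracle

test_that("lexicographic_compare: examples and antisymmetry property", {
  expect_equal(lexicographic_compare(c(0, 5), c(0, 5)), 0L)
  expect_equal(lexicographic_compare(c(0, 5), c(0.1, 1)), -1L) # p1 dominates
  expect_equal(lexicographic_compare(c(0.1, 1), c(0, 5)), 1L)
  expect_error(lexicographic_compare(c(1, 2), c(1, 2, 3)), "length")
  set.seed(17)
  for (k in 1:50) {
    a <- round(runif(4, 0, 3), 2); b <- round(runif(4, 0, 3), 2)
    expect_equal(lexicographic_compare(a, b), -lexicographic_compare(b, a))
  }
  # entries within tolerance are equal
  expect_equal(lexicographic_compare(c(1, 2), c(1 + 1e-8, 2)), 0L)
})

test_that("greedy selection is deterministic and respects trace invariants", {
  m <- tiny_patient()
  ctx <- tiny_context(m)
  cand <- enumerate_coplanar_candidates(45) # 8 candidates
  cfg <- bao_config(score_depth = Inf)
  r1 <- greedy_select(m, cand, 4, tight_wishlist(), cfg, ctx)
  r2 <- greedy_select(m, cand, 4, tight_wishlist(), cfg, ctx)
  expect_identical(r1$selected, r2$selected)
  expect_equal(nrow(r1$trace), 4)
  expect_equal(anyDuplicated(r1$selected), 0L)
  expect_true(all(r1$selected %in% seq_len(n_beams(cand))))
})

test_that("x equal to the candidate count selects every candidate", {
  m <- tiny_patient()
  ctx <- tiny_context(m)
  cand <- enumerate_coplanar_candidates(90) # 4 candidates
  r <- greedy_select(m, cand, 4, tight_wishlist(), bao_config(), ctx)
  expect_setequal(r$selected, 1:4)
  expect_error(greedy_select(m, cand, 5, tight_wishlist(), bao_config(), ctx),
               "x must be")
})

test_that("greedy with full scoring against the exhaustive C(4,2) oracle", {
  m <- tiny_patient()
  ctx <- tiny_context(m)
  cand <- enumerate_coplanar_candidates(90) # 4 candidates
  wl <- tight_wishlist()
  ctl <- control_accurate()
  cfg <- bao_config(scoring_mode = "full", score_control = ctl,
                    resolve_control = ctl, score_depth = Inf)
  r <- greedy_select(m, cand, 2, wl, cfg, ctx)
  greedy_obj <- r$plan$objective_values

  # oracle: all 6 subsets solved with solve_wishlist
  subsets <- utils::combn(4, 2)
  objs <- lapply(seq_len(ncol(subsets)), function(k) {
    infl <- lapply(subsets[, k], function(i)
      ctx_influence(ctx, beam_at(cand, i)))
    solve_wishlist(wl, infl, m, control = ctl)$objective_values
  })
  best <- objs[[1]]
  for (o in objs) if (lexicographic_compare(o, best) < 0) best <- o

  # greedy solves its own subset, so it can never beat the exhaustive best;
  # it either matches within 1e-3 relative per priority or the gap is
  # reported with the oracle as reference
  expect_lte(lexicographic_compare(best, greedy_obj, tol = 1e-6), 0)
  gap <- greedy_obj - best
  rel <- abs(gap) / pmax(1, abs(best))
  if (any(rel > 1e-3)) {
    message("greedy vs exhaustive gap (oracle reference): ",
            paste(signif(gap, 3), collapse = ", "))
  } else {
    expect_true(all(rel <= 1e-3))
  }
})

test_that("superset argmin oracle: non-coplanar subsets can only improve", {
  # best C(4,2) subset objective over a superset of candidates is <= the
  # best over the coplanar subset (argmin over a superset)
  m <- tiny_patient()
  ctx <- tiny_context(m)
  cp <- enumerate_coplanar_candidates(90)                      # 4 coplanar
  ncp <- beam_set(c(cp$gantry_deg, 20, -20), c(cp$couch_deg, 50, 50))
  wl <- tight_wishlist()
  ctl <- control_accurate()
  best_of <- function(cand) {
    n <- n_beams(cand)
    subsets <- utils::combn(n, 2)
    best <- NULL
    for (k in seq_len(ncol(subsets))) {
      infl <- lapply(subsets[, k], function(i)
        ctx_influence(ctx, beam_at(cand, i)))
      o <- solve_wishlist(wl, infl, m, control = ctl)$objective_values
      if (is.null(best) || lexicographic_compare(o, best) < 0) best <- o
    }
    best
  }
  b_cp <- best_of(cp)
  b_ncp <- best_of(ncp)
  expect_lte(lexicographic_compare(b_ncp, b_cp, tol = 1e-3), 0)
})

test_that("priority-1 value is weakly monotone in x after re-optimization", {
  m <- tiny_patient()
  ctx <- tiny_context(m)
  cand <- enumerate_coplanar_candidates(45)
  # uniform solver budget across iterations: with heterogeneous budgets the
  # comparison would mix different convergence levels
  cfg <- bao_config(resolve_control = control_fast(),
                    resolve_control_coverage = control_fast())
  r <- greedy_select(m, cand, 6, tight_wishlist(), cfg, ctx)
  p1 <- r$obj_after[, 1]
  expect_true(all(diff(p1) <= 1e-3 * pmax(1, p1[-length(p1)])))
})
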