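# plan_eval: DVH, clinical metrics, goal checking — all against brute-force
# voxel counting

test_that("DVH closed forms and the counting oracle", {
  m <- tiny_patient()
  mask <- m$masks$PTV
  dose <- array(0, m$grid$shape); dose[mask] <- 30
  dvh <- compute_dvh(dose, mask, bin_width_gy = 0.5)
  expect_equal(dvh$volume_pct[1], 100)               # V(0) = 100%
  expect_true(all(dvh$volume_pct[dvh$dose_gy <= 30] == 100))
  expect_true(all(dvh$volume_pct[dvh$dose_gy > 30] == 0))
  expect_true(all(diff(dvh$volume_pct) <= 0))        # monotone
  expect_error(compute_dvh(dose, array(FALSE, m$grid$shape)), "empty")

  # random doses: V(t) equals brute-force counting at 50 thresholds
  set.seed(23)
  for (rep in 1:3) {
    d <- array(runif(prod(m$grid$shape), 0, 35), m$grid$shape)
    dvh <- compute_dvh(d, mask, bin_width_gy = 0.7)
    ts <- dvh$dose_gy[seq(1, nrow(dvh), length.out = 50)]
    for (t in ts) {
      expect_equal(dvh$volume_pct[which.min(abs(dvh$dose_gy - t))],
                   100 * sum(d[mask] >= dvh$dose_gy[which.min(abs(dvh$dose_gy - t))]) / sum(mask))
    }
  }
})

test_that("compute_metrics: conformal limit and hand-counted examples", {
  # hand-built model with PTV disjoint from all OARs so the perfectly
  # conformal limit drives every OAR metric to zero
  g <- tiny_grid()
  zero <- function() array(FALSE, g$shape)
  m <- list(grid = g, masks = list(
    PTV = zero(), lung_L = zero(), lung_R = zero(), heart = zero(),
    breast_L = zero(), breast_R = zero(), patient = array(TRUE, g$shape)))
  m$masks$PTV[8:12, 6:9, 8:12] <- TRUE
  m$masks$lung_L[16:18, 6:9, 8:12] <- TRUE
  m$masks$lung_R[2:4, 6:9, 8:12] <- TRUE
  m$masks$heart[8:10, 11:13, 3:5] <- TRUE
  m$masks$breast_L[14:16, 12:14, 3:5] <- TRUE
  m$masks$breast_R[3:5, 12:14, 3:5] <- TRUE
  class(m) <- "patient_model"
  dose <- array(0, g$shape)
  dose[m$masks$PTV] <- 30
  met <- compute_metrics(dose, m)
  expect_equal(met$ptv_v95_pct, 100)
  expect_equal(met$ci, 1.0)            # patient >= 28.5 exactly the PTV
  expect_equal(met$heart_dmean_gy, 0)
  expect_equal(met$lungs_v5_pct, 0)
  expect_equal(met$patient_v20_cc, sum(m$masks$PTV) * voxel_cc(g))

  # 3-voxel PTV at {27, 28.5, 30}: the >= convention counts 2 of 3
  m3 <- m
  m3$masks$PTV[] <- FALSE
  idx <- which(m$masks$patient)[1:3]
  m3$masks$PTV[idx] <- TRUE
  d3 <- array(0, g$shape); d3[idx] <- c(27, 28.5, 30)
  met3 <- compute_metrics(d3, m3)
  expect_equal(met3$ptv_v95_pct, 100 * 2 / 3, tolerance = 1e-9)
  expect_equal(met3$ptv_vunder90_cc, 0 * voxel_cc(g)) # none strictly < 27

  # ci = 2 when the high-dose region is twice the PTV volume
  idx6 <- which(m$masks$patient)[1:6]
  d6 <- array(0, g$shape); d6[idx6] <- 30
  met6 <- compute_metrics(d6, m3)
  expect_equal(met6$ci, 2.0)
})

test_that("V-metrics equal brute-force voxel counting on random doses", {
  m <- tiny_patient()
  g <- m$grid
  lungs <- m$masks$lung_L | m$masks$lung_R
  set.seed(41)
  for (k in 1:20) {
    d <- array(runif(prod(g$shape), 0, 36), g$shape)
    met <- compute_metrics(d, m)
    expect_equal(met$ptv_v95_pct,
                 100 * sum(d[m$masks$PTV] >= 28.5) / sum(m$masks$PTV))
    expect_equal(met$ptv_vunder90_cc,
                 sum(d[m$masks$PTV] < 27) * voxel_cc(g))
    expect_equal(met$lungs_v20_pct, 100 * sum(d[lungs] >= 20) / sum(lungs))
    expect_equal(met$patient_v5_cc,
                 sum(d[m$masks$patient] >= 5) * voxel_cc(g))
    expect_equal(met$ci, sum(d[m$masks$patient] >= 28.5) /
                   sum(m$masks$PTV))
    expect_equal(met$breast_l_v4_pct,
                 100 * sum(d[m$masks$breast_L] >= 4) / sum(m$masks$breast_L))
  }
  # purity: same inputs, identical output
  d <- array(runif(prod(g$shape), 0, 36), g$shape)
  expect_identical(compute_metrics(d, m), compute_metrics(d, m))
})

test_that("check_goals applies required and preferred thresholds", {
  m <- tiny_patient()
  d0 <- array(0, m$grid$shape); d0[m$masks$PTV] <- 30
  met <- compute_metrics(d0, m)
  rep <- check_goals(met)
  expect_true(all(rep$pass))
  expect_true(coverage_ok(rep))

  # heart Dmean 20.4: passes the required < 26 but fails the preferred < 10
  met$heart_dmean_gy <- 20.4
  rep2 <- check_goals(met)
  hrow <- rep2[rep2$name == "heart_dmean_gy", ]
  expect_true(hrow$pass)
  expect_false(hrow$preferred_pass)

  # strict coverage edge: 94.9 is not ok, 95 is
  met$ptv_v95_pct <- 94.9
  expect_false(coverage_ok(check_goals(met)))
  met$ptv_v95_pct <- 95
  expect_true(coverage_ok(check_goals(met)))
})

test_that("ci is stable under consistent resolution change", {
  # analytic spherical dose field evaluated on two grids: ci agrees to a few
  # percent (one voxel-volume quantum at these sizes)
  # same analytic geometry voxelized at two resolutions: an ellipsoidal PTV
  # inside an all-patient grid with a spherical dose field; only
  # quantization may differ
  mk <- function(vm, shp) {
    g <- rt_grid(shp, vm)
    ax <- wishplan:::grid_axes(g)
    ptv <- array(outer(outer((ax$x / 50)^2, (ax$y / 40)^2, "+"),
                       (ax$z / 60)^2, "+") <= 1, g$shape)
    m <- list(grid = g,
              masks = list(PTV = ptv, lung_L = ptv & FALSE,
                           lung_R = ptv & FALSE, heart = ptv & FALSE,
                           breast_L = ptv & FALSE, breast_R = ptv & FALSE,
                           patient = array(TRUE, g$shape)))
    class(m) <- "patient_model"
    r2 <- outer(outer(ax$x^2, ax$y^2, "+"), ax$z^2, "+")
    list(m = m, dose = array(30 * exp(-r2 / (2 * 120^2)), g$shape))
  }
  a <- mk(12, c(27L, 19L, 24L))
  b <- mk(10, c(32L, 22L, 28L))
  ci1 <- compute_metrics(a$dose, a$m)$ci
  ci2 <- compute_metrics(b$dose, b$m)$ci
  expect_equal(ci1, ci2, tolerance = 0.05)
})
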