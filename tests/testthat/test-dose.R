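# dose_engine: beamlet lattice, kernel physics, influence structure,
# linearity

test_that("beamlet lattice covers the PTV projection (projection oracle)", {
  m <- tiny_patient()
  b <- beam_direction(40, 10)
  for (margin in c(5, 15, 25)) {
    bg <- build_beamlet_grid(m, b, beamlet_size_mm = 20, margin_mm = margin)
    # oracle: project PTV voxel centers, count lattice nodes of the dilated
    # bounding box directly
    fr <- bg$frame
    P <- wishplan:::voxel_coords(m$grid, which(m$masks$PTV))
    bu <- P %*% fr$e1; bv <- P %*% fr$e2
    half <- m$grid$voxel_mm / 2
    nu_oracle <- floor((diff(range(bu)) + 2 * margin + 2 * half) / 20) + 1
    nv_oracle <- floor((diff(range(bv)) + 2 * margin + 2 * half) / 20) + 1
    expect_equal(bg$nu, nu_oracle)
    expect_equal(bg$nv, nv_oracle)
    expect_gte(n_beamlets(bg), 1)
  }
  # monotone in margin
  n1 <- n_beamlets(build_beamlet_grid(m, b, 20, 5))
  n2 <- n_beamlets(build_beamlet_grid(m, b, 20, 25))
  expect_gte(n2, n1)
  # empty PTV errors
  m2 <- m; m2$masks$PTV[] <- FALSE
  expect_error(build_beamlet_grid(m2, b), "empty PTV")
})

test_that("voxels outside the patient get identically zero rows", {
  m <- tiny_patient()
  bg <- build_beamlet_grid(m, beam_direction(0), 25, 10)
  infl <- compute_influence(m, bg, tiny_kernel())
  outside <- which(!m$masks$patient)
  expect_equal(sum(abs(infl$matrix[outside, ])), 0)
  expect_true(all(infl$matrix@x >= 0))
})

test_that("homogeneous-phantom depth attenuation matches the closed form", {
  # uniform-density block phantom, anterior beam: central-axis dose ratio
  # between two depths is exp(-mu * (d2 - d1))
  g <- rt_grid(c(15L, 15L, 15L), 10)
  m <- list(grid = g,
            masks = list(PTV = array(FALSE, g$shape),
                         patient = array(TRUE, g$shape)),
            density = array(1, g$shape))
  class(m) <- "patient_model"
  m$masks$PTV[8, 8, 8] <- TRUE
  kp <- kernel_params(mu = 0.005, sigma_penumbra_mm = 6, output_factor = 1,
                      trunc_rel = 1e-6)
  bg <- build_beamlet_grid(m, beam_direction(0), 10, 20)
  infl <- compute_influence(m, bg, kp, step_mm = 0.5)
  # central beamlet: the one whose center is nearest the PTV voxel's BEV
  # coordinate
  fr <- bg$frame
  p <- wishplan:::voxel_coords(g, which(m$masks$PTV))
  cu <- beamlet_centers(bg)
  j <- which.min((cu[, 1] - sum(p * fr$e1))^2 + (cu[, 2] - sum(p * fr$e2))^2)
  # two voxels on the central axis at different depths (y axis)
  idx_of <- function(ix, iy, iz) ix + (iy - 1) * 15 + (iz - 1) * 225
  d1 <- infl$matrix[idx_of(8, 10, 8), j] # shallower (closer to +y surface)
  d2 <- infl$matrix[idx_of(8, 4, 8), j]  # deeper
  expect_gt(d1, 0)
  expect_equal(d2 / d1, exp(-0.005 * 60), tolerance = 1e-3)
})

test_that("monotone attenuation along the central axis", {
  g <- rt_grid(c(15L, 15L, 15L), 10)
  m <- list(grid = g,
            masks = list(PTV = array(FALSE, g$shape),
                         patient = array(TRUE, g$shape)),
            density = array(1, g$shape))
  class(m) <- "patient_model"
  m$masks$PTV[8, 8, 8] <- TRUE
  kp <- kernel_params(mu = 0.007, sigma_penumbra_mm = 6, output_factor = 1,
                      trunc_rel = 1e-6)
  bg <- build_beamlet_grid(m, beam_direction(0), 10, 20)
  infl <- compute_influence(m, bg, kp, step_mm = 0.5)
  f <- rep(1, n_beamlets(bg))
  dose <- total_dose(list(infl), f)
  prof <- dose[8 + (seq(14, 2) - 1) * 15 + (8 - 1) * 225] # entry -> exit
  expect_true(all(diff(prof) < 0))
})

test_that("mirrored phantom and mirrored beam give the mirrored dose", {
  m <- tiny_patient(9)
  flip <- function(a) a[rev(seq_len(dim(a)[1])), , , drop = FALSE]
  m2 <- m
  m2$masks <- lapply(m$masks, flip)
  m2$density <- flip(m$density)
  kp <- tiny_kernel()
  for (ang in c(50, -20)) {
    b1 <- beam_direction(ang); b2 <- beam_direction(-ang)
    i1 <- compute_influence(m, build_beamlet_grid(m, b1, 25, 15), kp)
    i2 <- compute_influence(m2, build_beamlet_grid(m2, b2, 25, 15), kp)
    expect_equal(ncol(i1$matrix), ncol(i2$matrix))
    d1 <- total_dose(list(i1), rep(1, ncol(i1$matrix)))
    d2 <- total_dose(list(i2), rep(1, ncol(i2$matrix)))
    expect_equal(array(d2, m$grid$shape),
                 flip(array(d1, m$grid$shape)), tolerance = 1e-6)
  }
})

test_that("total_dose: linearity, additivity, input validation", {
  m <- tiny_patient()
  infl <- tiny_influences(m, gantries = c(0, 90, 180))
  nb <- vapply(infl, function(d) ncol(d$matrix), integer(1))
  f <- rep(0.5, sum(nb))
  expect_equal(total_dose(infl, numeric(sum(nb))), numeric(nrow(infl[[1]]$matrix)))
  d <- total_dose(infl, f)
  expect_equal(total_dose(infl, 2 * f), 2 * d, tolerance = 1e-12)
  # additivity against per-beam accumulation
  acc <- numeric(length(d))
  off <- 0
  for (k in seq_along(infl)) {
    acc <- acc + total_dose(infl[k], f[(off + 1):(off + nb[k])])
    off <- off + nb[k]
  }
  expect_equal(acc, d, tolerance = 1e-12)
  expect_error(total_dose(infl, f[-1]), "beamlet count")
  expect_error(total_dose(infl, -f), "negative")
})

test_that("lung density reduces radiological depth", {
  m <- tiny_patient()
  # a lateral beam passes through lung to reach the mediastinum; with lungs
  # at density 0.25 the attenuation must be weaker than through soft tissue
  dens_soft <- m$density
  dens_soft[m$masks$lung_L | m$masks$lung_R] <- 1
  P <- wishplan:::voxel_coords(m$grid, which(m$masks$PTV))
  u <- beam_direction(90)$unit_vector
  d_lung <- wishplan:::cpp_radiological_depth(m$density, m$grid$shape, m$grid$voxel_mm,
                                   P, as.numeric(u), 2)
  d_soft <- wishplan:::cpp_radiological_depth(dens_soft, m$grid$shape, m$grid$voxel_mm,
                                   P, as.numeric(u), 2)
  expect_true(all(d_lung <= d_soft + 1e-9))
  expect_gt(mean(d_soft - d_lung), 5)
})
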