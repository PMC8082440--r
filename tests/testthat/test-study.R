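# study_protocol: Wilcoxon statistics, per-patient protocol mechanics,
# aggregation oracles

test_that("wilcoxon: degenerate, symmetry, exact enumeration oracle at n=6", {
  a <- c(1, 2, 3, 4, 5, 6)
  r0 <- wilcoxon_signed_rank(a, a)
  expect_true(r0$degenerate)
  expect_equal(r0$p_value, 1)

  # enumeration oracle: all 2^6 sign assignments of differences {1..6}
  b <- a - (1:6)
  res <- wilcoxon_signed_rank(a, b) # differences +1..+6
  ranks <- 1:6
  grid2 <- expand.grid(rep(list(c(0, 1)), 6))
  W <- as.matrix(grid2) %*% ranks
  w_obs <- sum(ranks)
  p_oracle <- min(1, 2 * min(mean(W <= w_obs), mean(W >= w_obs)))
  expect_equal(res$method, "exact")
  expect_equal(res$p_value, p_oracle, tolerance = 1e-12)

  # swap symmetry
  set.seed(3)
  x <- rnorm(12); y <- rnorm(12)
  expect_equal(wilcoxon_signed_rank(x, y)$p_value,
               wilcoxon_signed_rank(y, x)$p_value)
})

test_that("wilcoxon exact p matches stats::wilcox.test without ties", {
  set.seed(8)
  for (k in 1:10) {
    x <- rnorm(10); y <- rnorm(10)
    ours <- wilcoxon_signed_rank(x, y)
    ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE,
                              correct = FALSE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("wilcoxon handles ties via midranks and large n via normal approx", {
  a <- c(3, 3, 5, 5, 1, 2, 8, 8, 8, 4)
  b <- rep(0, 10)
  res <- wilcoxon_signed_rank(a, b)
  expect_equal(res$method, "exact")
  expect_true(res$p_value > 0 && res$p_value <= 1)
  set.seed(12)
  x <- rnorm(40); y <- rnorm(40, 0.6)
  res_n <- wilcoxon_signed_rank(x, y)
  expect_equal(res_n$method, "normal")
  ref <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE)
  expect_equal(res_n$p_value, ref$p.value, tolerance = 0.02)
})

test_that("study labels and config invariants", {
  lb <- study_labels()
  expect_length(lb, 24)
  expect_setequal(lb, c(sprintf("CP_%d", 5:15), sprintf("NCP_%d", 5:15),
                        "VMAT", "BVMAT"))
  cfg <- study_profile_reduced(n_patients = 2, seed = 1)
  expect_s3_class(cfg, "study_config")
  expect_length(cfg$configurations, 24)
})

test_that("population_summary equals brute-force re-aggregation", {
  # synthetic comparison table (no solver): random metrics for 4 patients
  set.seed(99)
  lb <- study_labels()
  rows <- do.call(rbind, lapply(1:4, function(pid) {
    do.call(rbind, lapply(lb, function(cg) {
      met <- as.data.frame(as.list(stats::setNames(
        runif(length(metric_names()), 0, 30), metric_names())))
      cbind(data.frame(patient_id = pid, configuration = cg,
                       coverage_ok = TRUE, solver_failed = FALSE), met)
    }))
  }))
  tab <- structure(list(rows = rows, evaluable = 1:4, excluded = integer(0)),
                   class = "comparison_table")
  s <- population_summary(tab)
  for (k in sample(nrow(s), 25)) {
    sub <- rows[rows$configuration == s$configuration[k], s$metric[k]]
    expect_equal(s$mean[k], mean(sub))
    expect_equal(s$min[k], min(sub))
    expect_equal(s$max[k], max(sub))
  }
  # the ordering is a permutation of evaluable ids
  expect_setequal(attr(s, "patient_order"), 1:4)

  # the exclusion rule: a patient with one failing plan leaves every summary
  rows2 <- rows
  rows2$coverage_ok[rows2$patient_id == 2 & rows2$configuration == "CP_5"] <- FALSE
  bad <- unique(rows2$patient_id[!rows2$coverage_ok])
  tab2 <- structure(list(rows = rows2, evaluable = setdiff(1:4, bad),
                         excluded = bad), class = "comparison_table")
  s2 <- population_summary(tab2)
  expect_false(2 %in% attr(s2, "patient_order"))
  sub2 <- rows2[rows2$configuration == "NCP_15" & rows2$patient_id != 2, ]
  expect_equal(s2$mean[s2$configuration == "NCP_15" &
                         s2$metric == "heart_dmean_gy"],
               mean(sub2$heart_dmean_gy))
})

test_that("beam_direction_histogram counts re-aggregate the traces", {
  cp <- enumerate_coplanar_candidates(20)
  ncp <- enumerate_noncoplanar_candidates(20)
  set.seed(7)
  selections <- lapply(1:3, function(i)
    list(CP = sample(n_beams(cp), 15),
         NCP = sample(n_beams(ncp), 15)))
  tab <- structure(list(selections = selections, evaluable = 1:3,
                        candidates = list(CP = cp, NCP = ncp)),
                   class = "comparison_table")
  h <- beam_direction_histogram(tab, "NCP_15")
  expect_equal(attr(h, "total"), 3 * 15)
  expect_equal(sum(h$count), 45)
  # counts re-summed from the traces
  oracle <- integer(n_beams(ncp))
  for (s in selections) for (i in s$NCP[1:15]) oracle[i] <- oracle[i] + 1L
  expect_equal(h$count, oracle)
  # CP histograms live at couch 0
  hcp <- beam_direction_histogram(tab, "CP_10")
  expect_true(all(hcp$couch_deg[hcp$count > 0] == 0))
  expect_equal(attr(hcp, "total"), 30)
  expect_error(beam_direction_histogram(tab, "VMAT"), "CP_x/NCP_x")
  # B-VMAT overlay attached
  expect_equal(n_beams(attr(h, "bvmat")), 20)
})
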