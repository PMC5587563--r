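make_toy_cohort <- function(n_subj = 4, n = 8, seed = 1) {
  mats <- lapply(seq_len(n_subj), function(i)
    random_weight_matrix(n, 0.7, seed = seed + i))
  as_cohort(mats)
}

test_that("measure curves equal per-density recomputation", {
  coh <- make_toy_cohort(2, 10, seed = 5)
  kap <- c(0.2, 0.6, 1.0)
  cv <- measure_curve(coh, "whole", "efficiency", kappas = kap)
  summ <- median_summary(coh)
  for (i in 1:2) for (k in seq_along(kap)) {
    m <- density_threshold(summ, kap[k])
    expect_equal(cv$values[i, k],
                 global_efficiency(apply_mask(coh[[i]], m)),
                 tolerance = 1e-12)
  }
  # the kappa = 1 endpoint is the unthresholded measure
  expect_equal(cv$values[1, 3], global_efficiency(coh[[1]]),
               tolerance = 1e-12)

  # nodal strength curve is the row sum of masked weights
  sv <- measure_curve(coh, "whole", "strength", kappas = kap, node = 3)
  m <- density_threshold(summ, 0.2)
  expect_equal(sv$values[2, 1],
               sum(apply_mask(coh[[2]], m)$weights[3, ]),
               tolerance = 1e-12)

  expect_error(measure_curve(coh, "whole", "strength"), "node")
  expect_error(measure_curve(coh, "whole", "nope"), "unknown")
})

test_that("identical groups give a flat t-curve, zero area and p = 1", {
  V <- matrix(rnorm(5 * 7), 5, 7)
  V2 <- rbind(V, V)
  g <- factor(rep(c("control", "patient"), each = 5))
  res <- mtcp_test(V2, g, n_perm = 100, seed = 3,
                   kappas = seq(0.1, 0.7, 0.1))
  expect_equal(max(abs(res$t_obs)), 0, tolerance = 1e-12)
  expect_equal(res$A, 0)
  expect_equal(res$p, 1)
  expect_false(res$significant)
})

test_that("exhaustive MTCP p-values match enumeration over all splits", {
  set.seed(44)
  V <- matrix(rnorm(8 * 6), 8, 6)
  V[1:4, ] <- V[1:4, ] + 1
  g <- factor(rep(c("a", "b"), each = 4))
  res <- mtcp_test(V, g, exhaustive = TRUE, kappas = seq(0.1, 0.6, 0.1))
  want <- oracle_tmax_exhaustive(V, 4)
  expect_equal(res$t_obs, want$t_obs, tolerance = 1e-12)
  expect_equal(res$p, mean(want$maxs >= max(abs(want$t_obs)) - 1e-12),
               tolerance = 1e-12)
  expect_equal(res$n_perm, choose(8, 4))
})

test_that("a large persistent effect yields a full-grid supercritical cluster", {
  kap <- kappa_grid_global()
  set.seed(7)
  base <- matrix(rnorm(26 * 19, mean = 5), 26, 19)
  base[14:26, ] <- base[14:26, ] - 2      # patient deficit, g ~ 2
  g <- factor(rep(c("control", "patient"), each = 13))
  res <- mtcp_test(base, g, n_perm = 500, seed = 11, kappas = kap)
  expect_true(res$significant)
  expect_lte(res$p, 0.05)
  expect_equal(res$cluster_range, range(kap))
  expect_gt(res$t_mtcp, 0)                # positive t = deficit in patients
  expect_gt(res$A, 0)
  expect_gte(res$A_crit, 0)
  expect_gte(res$A_crit, res$A_crit_all * (res$A_crit_all > 0))
})

test_that("supercritical area is positive exactly when the peak is supercritical", {
  kap <- seq(0.1, 0.9, 0.1)
  g <- factor(rep(c("a", "b"), each = 6))
  for (seed in 1:20) {
    set.seed(seed)
    V <- matrix(rnorm(12 * 9), 12, 9)
    res <- mtcp_test(V, g, n_perm = 60, seed = seed, kappas = kap)
    expect_identical(res$A > 0, res$t_max > res$t_crit)
    expect_true(res$p > 0 && res$p <= 1)
  }
})

test_that("MTCP results are bit-reproducible under a fixed seed", {
  set.seed(10)
  V <- matrix(rnorm(12 * 9), 12, 9)
  g <- factor(rep(c("a", "b"), each = 6))
  r1 <- mtcp_test(V, g, n_perm = 80, seed = 5, kappas = seq(0.1, 0.9, 0.1))
  r2 <- mtcp_test(V, g, n_perm = 80, seed = 5, kappas = seq(0.1, 0.9, 0.1))
  expect_identical(r1[c("t_obs", "t_crit", "A", "A_crit", "p")],
                   r2[c("t_obs", "t_crit", "A", "A_crit", "p")])
})

test_that("degenerate densities are dropped with a warning", {
  set.seed(2)
  V <- cbind(matrix(rnorm(12 * 3), 12, 3), 1)  # constant last column
  g <- factor(rep(c("a", "b"), each = 6))
  expect_warning(res <- mtcp_test(V, g, n_perm = 50, seed = 1,
                                  kappas = c(0.1, 0.2, 0.3, 0.4)),
                 "zero variance")
  expect_equal(res$dropped_kappas, 0.4)
  expect_length(res$t_obs, 3)
})

test_that("nodal screen reports one calibrated row per usable region", {
  sim <- simulate_cohort(simulation_config(n_controls = 6, n_patients = 6,
                                           n_nodes_per_hemisphere = 8,
                                           delta = 0.5, seed = 21))
  g <- factor(sim$covariates$group)
  tab <- nodal_mtcp_screen(sim$cohort, "right", "strength", g,
                           kappas = seq(0.2, 0.8, 0.1), n_perm = 120,
                           seed = 9)
  expect_equal(nrow(tab), 8)
  expect_true(all(tab$significant == (abs(tab$t_max) > tab$t_crit)))
  expect_true(all((tab$A > 0) == tab$significant))
  expect_true(all(tab$p > 0 & tab$p <= 1))
  # a strong right-hemisphere deficit should flag most regions
  expect_gt(mean(tab$significant), 0.5)
  expect_true(all(tab$hedges_g[tab$significant] > 0))

  # an all-zero region is dropped with a warning
  mats <- lapply(1:8, function(i) {
    m <- random_weight_matrix(6, 0.8, seed = i)
    m[1, ] <- m[, 1] <- 0
    m
  })
  coh <- as_cohort(mats)
  g2 <- factor(rep(c("a", "b"), each = 4))
  expect_warning(tab2 <- nodal_mtcp_screen(coh, "left", "strength", g2,
                                           kappas = c(0.3, 0.6),
                                           n_perm = 40, seed = 2),
                 "degenerate")
  expect_false("r01" %in% tab2$region)
})
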