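test_that("strength quartiles use linear-interpolation quantiles per region-set", {
  # left block: 4 regions, 6 pairs, five nonzero weights 1..5
  w <- matrix(0, 8, 8)
  lp <- which(upper.tri(matrix(0, 4, 4)), arr.ind = TRUE)
  for (i in 1:5) w[lp[i, 1], lp[i, 2]] <- i
  w[5, 6] <- 2          # right block: single edge
  w[1, 5] <- 7          # one interhemispheric connection
  w <- pmax(w, t(w))
  c <- connectome(w, parc_n(8), "s1")
  q <- strength_quartiles(c)
  expect_equal(unlist(q[q$region_set == "left", c("q25", "q50", "q75")]),
               c(q25 = 2, q50 = 3, q75 = 4))
  expect_equal(unlist(q[q$region_set == "right", c("q25", "q50", "q75")]),
               c(q25 = 2, q50 = 2, q75 = 2))
  expect_equal(q[q$region_set == "interhemispheric", "q50"], 7)

  # constant weights: all quartiles equal
  wc <- matrix(0.4, 8, 8); diag(wc) <- 0
  qc <- strength_quartiles(connectome(wc, parc_n(8), "s2"))
  expect_true(all(qc$q25 == 0.4 & qc$q75 == 0.4))
})

test_that("tmax permutation p-values are family-wise monotone and honest", {
  # identical groups: every statistic has t = 0 and adjusted p = 1
  V <- matrix(rnorm(5 * 4), 5, 4)
  V2 <- rbind(V, V)
  g <- factor(rep(c("a", "b"), each = 5))
  res <- tmax_permutation_test(V2, g, n_perm = 50, seed = 1)
  expect_true(all(res$t_obs == 0))
  expect_true(all(res$p_adj == 1))

  set.seed(33)
  V <- matrix(rnorm(12 * 5), 12, 5)
  V[1:6, 1] <- V[1:6, 1] + 3
  g <- factor(rep(c("a", "b"), each = 6))
  res <- tmax_permutation_test(V, g, n_perm = 400, seed = 2)
  expect_true(all(res$p_adj >= res$p_raw - 1e-12))
  # adjusted p decreases with |t| within one family
  ord <- order(abs(res$t_obs))
  expect_true(all(diff(res$p_adj[ord]) <= 1e-12))
  # identity relabeling is counted: p >= 1/n_perm
  expect_true(all(res$p_adj >= 1 / 400))
})

test_that("exhaustive tmax relabelings reproduce the enumeration oracle", {
  set.seed(91)
  V <- matrix(rnorm(6 * 3), 6, 3)
  g <- factor(rep(c("a", "b"), each = 3))
  res <- tmax_permutation_test(V, g, exhaustive = TRUE)
  want <- oracle_tmax_exhaustive(V, 3)
  expect_equal(res$t_obs, want$t_obs, tolerance = 1e-12)
  expect_equal(res$p_adj, want$p_adj, tolerance = 1e-12)
})

test_that("KS wrapper matches an ECDF scan", {
  x <- c(1, 2); y <- c(3, 4)
  expect_equal(ks_two_sample(x, y)$D, 1)
  expect_equal(ks_two_sample(x, x)$D, 0)
  set.seed(5)
  for (i in 1:5) {
    a <- rnorm(20); b <- rnorm(25, 0.5)
    expect_equal(ks_two_sample(a, b)$D, oracle_ks_D(a, b),
                 tolerance = 1e-12)
  }
  expect_error(ks_two_sample(numeric(0), y), "nonempty")
})

test_that("group-averaged strengths are edge-wise means within group", {
  m1 <- matrix(0, 4, 4); m1[1, 2] <- m1[2, 1] <- 2
  m2 <- m1 * 3; m3 <- m1 * 5
  coh <- as_cohort(list(m1, m2, m3))
  g <- factor(c("a", "a", "b"))
  av <- group_average_strengths(coh, g, "left")
  expect_equal(av$a[1], 4)   # mean of 2 and 6 on the only left edge
  expect_equal(av$b[1], 10)
})

test_that("mixed ANOVA matches the definitional sums of squares", {
  d <- expand.grid(subject_id = paste0("s", 1:6),
                   region = c("L", "I", "R"))
  d$group <- ifelse(d$subject_id %in% paste0("s", 1:3), "g1", "g2")
  set.seed(12)
  d$value <- rnorm(nrow(d)) + 2 * (d$group == "g2") +
    1.5 * (d$region == "R") + (d$group == "g2") * (d$region == "R")
  res <- rm_anova_2xk(d)

  # definitional decomposition (balanced, equal group sizes)
  k <- 3; ng <- 3
  grand <- mean(d$value)
  subj_mean <- tapply(d$value, d$subject_id, mean)
  grp_of <- tapply(d$group, d$subject_id, function(x) x[1])
  grp_mean <- tapply(d$value, d$group, mean)
  lev_mean <- tapply(d$value, d$region, mean)
  cell <- tapply(d$value, list(d$group, d$region), mean)
  ss_bs <- k * sum((subj_mean - grand)^2)
  ss_group <- k * ng * sum((grp_mean - grand)^2)
  ss_serr <- ss_bs - ss_group
  ss_wtot <- sum((d$value - subj_mean[as.character(d$subject_id)])^2)
  ss_region <- 2 * ng * sum((lev_mean - grand)^2)
  ss_int <- ng * sum((sweep(sweep(cell, 1, grp_mean), 2, lev_mean) +
                        grand)^2)
  ss_werr <- ss_wtot - ss_region - ss_int

  expect_equal(res$sum_sq, c(ss_group, ss_region, ss_int),
               tolerance = 1e-8)
  expect_equal(res$sum_sq_error, c(ss_serr, ss_werr, ss_werr),
               tolerance = 1e-8)
  expect_equal(res$F,
               c((ss_group / 1) / (ss_serr / 4),
                 (ss_region / 2) / (ss_werr / 8),
                 (ss_int / 2) / (ss_werr / 8)),
               tolerance = 1e-8)
  expect_true(all(res$partial_eta_sq >= 0 & res$partial_eta_sq <= 1))

  # the strata partition the total sum of squares
  expect_equal(sum(res$sum_sq) + ss_serr + ss_werr,
               sum((d$value - grand)^2), tolerance = 1e-8)

  expect_error(rm_anova_2xk(d[-1, ]), "balanced")
})

test_that("simple effects report group t-tests with Hedges g per level", {
  d <- expand.grid(subject_id = paste0("s", 1:8), region = c("L", "R"))
  d$group <- ifelse(d$subject_id %in% paste0("s", 1:4), "g1", "g2")
  set.seed(2)
  d$value <- rnorm(nrow(d)) + 3 * (d$group == "g1") * (d$region == "R")
  se <- simple_effects_group(d)
  expect_equal(nrow(se), 2)
  tt <- t.test(d$value[d$region == "R" & d$group == "g1"],
               d$value[d$region == "R" & d$group == "g2"],
               var.equal = TRUE)
  expect_equal(se$t[se$level == "R"], unname(tt$statistic),
               tolerance = 1e-12)
})

test_that("Hedges g applies the small-sample correction", {
  # means exactly 1 and 0, pooled SD exactly 1, n = 13 + 13
  v <- as.numeric(scale(1:13))
  x <- 1 + v; y <- v
  expect_equal(hedges_g(x, y), 1 - 3 / 95, tolerance = 1e-12)
  expect_equal(hedges_g(y, x), -(1 - 3 / 95), tolerance = 1e-12)
  expect_equal(hedges_g(c(1, 2, 3), c(3, 2, 1)), 0)
  expect_error(hedges_g(c(1, 1), c(1, 1)), "variance")
  expect_error(hedges_g(1, c(1, 2)), "observations")
})
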