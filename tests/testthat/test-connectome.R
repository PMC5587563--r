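test_that("build_connectome normalises by volume product and symmetrises", {
  p <- parcellation(c("a", "b"), c("left", "right"), c(2, 2))
  raw <- matrix(c(0, 10, 30, 0), 2, 2, byrow = TRUE)
  c <- build_connectome(raw, p)
  expect_equal(c$weights[1, 2], 5.0)  # (10/4 + 30/4)/2
  expect_equal(c$weights[2, 1], 5.0)

  # all-zero counts give an all-zero connectome
  c0 <- build_connectome(matrix(0, 2, 2), p)
  expect_true(all(c0$weights == 0))

  # unit volumes + already-symmetric raw: identity up to the diagonal
  p1 <- parc_n(4)
  raw <- random_weight_matrix(4, 1, seed = 2)
  diag(raw) <- 9
  c1 <- build_connectome(raw, p1)
  expect_equal(unname(c1$weights[upper.tri(raw)]), raw[upper.tri(raw)])
  expect_true(all(diag(c1$weights) == 0))

  expect_error(build_connectome(matrix(0, 3, 3), p), "dimension")
  expect_error(build_connectome(matrix(-1, 2, 2), p), "nonnegative")
  expect_error(parcellation("a", "left", 0), "positive")
})

test_that("hemisphere extraction partitions intra-hemispheric edges", {
  sim <- simulate_cohort(simulation_config(n_controls = 2, n_patients = 2,
                                           seed = 3))
  c <- sim$cohort[[1]]
  l <- extract_hemisphere(c, "left")
  r <- extract_hemisphere(c, "right")
  x <- extract_hemisphere(c, "interhemispheric")
  expect_equal(nrow(l$weights), 36)
  expect_equal(nrow(r$weights), 36)
  expect_equal(dim(x), c(36, 36))
  nz <- function(m) sum(m[upper.tri(m)] > 0)
  expect_equal(nz(l$weights) + nz(r$weights) + sum(x > 0),
               nz(c$weights))
  expect_error(extract_hemisphere(c, "middle"))

  # block-diagonal network has an empty interhemispheric block
  bd <- matrix(0, 4, 4)
  bd[1, 2] <- bd[2, 1] <- bd[3, 4] <- bd[4, 3] <- 1
  cbd <- connectome(bd, parc_n(4))
  expect_true(all(extract_hemisphere(cbd, "interhemispheric") == 0))
})

test_that("median summary is the elementwise median over all subjects", {
  m1 <- matrix(0, 4, 4); m1[1, 2] <- m1[2, 1] <- 1
  m2 <- m1 * 2
  m3 <- m1 * 9
  coh <- as_cohort(list(m1, m2, m3))
  expect_equal(median_summary(coh)[1, 2], 2)
  expect_equal(unname(median_summary(coh[1])), m1)

  # 26 simulated subjects against a per-edge sort oracle
  mats <- lapply(1:26, function(i) random_weight_matrix(10, 0.5, seed = i))
  coh <- as_cohort(mats)
  ms <- median_summary(coh)
  arr <- simplify2array(mats)
  for (pair in list(c(1, 2), c(3, 7), c(9, 10))) {
    v <- sort(arr[pair[1], pair[2], ])
    expect_equal(ms[pair[1], pair[2]], (v[13] + v[14]) / 2)
  }
  expect_identical(ms, t(ms))
  expect_error(median_summary(list()), "at least one")
})

test_that("density thresholding retains round-half-up counts and nests", {
  s72 <- random_weight_matrix(72, 0.6, seed = 5)
  expect_equal(density_threshold(s72, 0.05)$edge_count, 128L)
  expect_equal(density_threshold(s72, 0.95)$edge_count, 2428L)
  s36 <- random_weight_matrix(36, 0.6, seed = 5)
  expect_equal(density_threshold(s36, 0.05)$edge_count, 32L)
  expect_equal(density_threshold(s36, 0.95)$edge_count, 599L)

  # kappa = 1 keeps every pair
  full <- density_threshold(s36, 1)
  expect_equal(full$edge_count, 36L * 35L / 2L)
  expect_true(all(full$mask[upper.tri(full$mask)]))
  expect_false(any(diag(full$mask)))

  # masks are monotone in kappa and deterministic
  masks <- lapply(kappa_grid_global(), density_threshold, summary = s36)
  for (i in seq_len(length(masks) - 1))
    expect_true(all(masks[[i + 1]]$mask[masks[[i]]$mask]))
  expect_identical(density_threshold(s36, 0.4)$mask,
                   density_threshold(s36, 0.4)$mask)

  # structural zeros are ranked so sparse summaries still reach the count
  sparse <- matrix(0, 36, 36)
  sparse[1, 2] <- sparse[2, 1] <- 1
  expect_equal(density_threshold(sparse, 0.95)$edge_count, 599L)

  expect_error(density_threshold(s36, 0), "kappa")
  expect_error(density_threshold(s36, 1.2), "kappa")
})

test_that("apply_mask zeroes outside the mask and never increases weights", {
  w <- random_weight_matrix(20, 0.7, seed = 11)
  c <- connectome(w, parc_n(20))
  m <- density_threshold(w, 0.3)
  cm <- apply_mask(c, m)
  expect_valid_connectome(cm)
  expect_true(all(cm$weights <= c$weights))
  expect_true(all(cm$weights[!m$mask] == 0))
  expect_identical(cm$weights[m$mask], c$weights[m$mask])
  expect_lte(sum(cm$weights[upper.tri(w)] > 0), m$edge_count)

  # complete mask is the identity transform
  cfull <- apply_mask(c, density_threshold(w, 1))
  expect_equal(cfull$weights, c$weights)

  # total strength shrinks as kappa shrinks
  strengths <- vapply(c(0.2, 0.5, 0.8),
                      function(k) sum(apply_mask(c, density_threshold(w, k))$weights),
                      numeric(1))
  expect_true(all(diff(strengths) >= 0))
})

test_that("matrix, region and cohort tables round-trip through disk", {
  dir <- withr::local_tempdir()
  w <- random_weight_matrix(6, 0.8, seed = 1)
  f <- file.path(dir, "w.csv")
  write_matrix(w, f)
  expect_equal(read_matrix(f), w)

  p <- parc_n(6, volumes = c(10, 20, 30, 40, 50, 60))
  pf <- file.path(dir, "regions.csv")
  write_region_table(p, pf)
  p2 <- read_region_table(pf)
  expect_equal(p2$label, p$label)
  expect_equal(p2$volume, p$volume)

  sim <- simulate_cohort(simulation_config(n_controls = 2, n_patients = 2,
                                           n_nodes_per_hemisphere = 4,
                                           seed = 8))
  write_cohort(sim, dir)
  cov <- read_cohort_table(file.path(dir, "cohort.csv"))
  expect_equal(cov$subject_id, sim$covariates$subject_id)
  paths <- file.path(dir, paste0(cov$subject_id, ".csv"))
  names(paths) <- cov$subject_id
  coh <- read_cohort_matrices(paths, sim$cohort[[1]]$parcellation)
  expect_equal(coh[[3]]$weights, sim$cohort[[3]]$weights,
               tolerance = 1e-12)
})
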