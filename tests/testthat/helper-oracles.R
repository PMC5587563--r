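# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (igraph shortest paths, matrix-power clustering,
# vectorised permutation t-statistics) so that agreement is informative.

# All-pairs shortest paths by Floyd-Warshall on lengths 1/w.
oracle_distances <- function(w) {
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  d[w > 0] <- 1 / w[w > 0]
  diag(d) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

oracle_efficiency <- function(w) {
  n <- nrow(w)
  d <- oracle_distances(w)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

# Triple enumeration of the geometric-mean clustering formula.
oracle_clustering <- function(w, denominator = "degree") {
  mx <- max(w)
  if (mx > 0) w <- w / mx
  n <- nrow(w)
  cv <- numeric(n)
  for (v in seq_len(n)) {
    num <- 0
    for (x in seq_len(n)) for (y in seq_len(n)) {
      if (x == v || y == v || x == y) next
      num <- num + (w[v, x] * w[v, y] * w[x, y])^(1 / 3)
    }
    k <- if (denominator == "degree") sum(w[v, ] > 0) else sum(w[v, ])
    den <- k * (k - 1)
    cv[v] <- if (den > 0) num / den else 0
  }
  list(global = mean(cv), local = cv)
}

oracle_local_efficiency <- function(w, include_self = TRUE) {
  n <- nrow(w)
  out <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(w[v, ] > 0)
    if (length(nb) < 2) next
    keep <- if (include_self) c(v, nb) else nb
    out[v] <- oracle_efficiency(w[keep, keep, drop = FALSE])
  }
  out
}

# Weighted modularity of an explicit partition.
oracle_modularity_value <- function(w, membership) {
  s <- rowSums(w)
  m2 <- sum(w)
  if (m2 == 0) return(NA_real_)
  same <- outer(membership, membership, "==")
  sum((w - outer(s, s) / m2)[same]) / m2
}

# All set partitions of n elements as restricted growth strings.
oracle_all_partitions <- function(n) {
  out <- list()
  rec <- function(assign, k) {
    i <- length(assign) + 1
    if (i > n) {
      out[[length(out) + 1]] <<- assign
      return()
    }
    for (c in seq_len(k + 1)) rec(c(assign, c), max(k, c))
  }
  rec(integer(0), 0)
  out
}

# Exhaustive-partition optimum of weighted modularity (n <= 8).
oracle_modularity_best <- function(w) {
  parts <- oracle_all_partitions(nrow(w))
  max(vapply(parts, function(p) oracle_modularity_value(w, p), numeric(1)))
}

# Pooled-variance two-sample t (first group minus second).
oracle_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
}

# Exhaustive max-statistic adjusted p-values over all assignments of n1
# subjects to the first group.
oracle_tmax_exhaustive <- function(values, n1) {
  n <- nrow(values)
  sets <- utils::combn(n, n1)
  tmat <- apply(sets, 2, function(g1) {
    vapply(seq_len(ncol(values)), function(k)
      oracle_t(values[g1, k], values[-g1, k]), numeric(1))
  })                                   # statistics x splits
  tmat <- matrix(tmat, ncol = ncol(sets))
  maxs <- apply(abs(tmat), 2, max)
  t_obs <- tmat[, 1]                   # identity split is column 1 when
                                       # subjects 1..n1 are group one
  list(t_obs = t_obs,
       p_adj = vapply(abs(t_obs), function(t0) mean(maxs >= t0 - 1e-12),
                      numeric(1)),
       maxs = maxs)
}

# Empirical-CDF scan for the two-sample KS statistic.
oracle_ks_D <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  max(abs(ecdf(x)(grid) - ecdf(y)(grid)))
}

# -- fixture builders -------------------------------------------------

# Parcellation with n regions, first half left.
parc_n <- function(n, volumes = rep(1, n)) {
  parcellation(sprintf("r%02d", seq_len(n)),
               rep(c("left", "right"), each = n / 2), volumes)
}

as_cohort <- function(mats, parc = NULL) {
  if (is.null(parc)) parc <- parc_n(nrow(mats[[1]]))
  lapply(seq_along(mats), function(i)
    connectome(mats[[i]], parc, sprintf("s%02d", i)))
}

expect_valid_connectome <- function(c) {
  w <- c$weights
  expect_true(all(w >= 0))
  expect_identical(w, t(w))
  expect_true(all(diag(w) == 0))
  expect_equal(nrow(w), nrow(c$parcellation))
}
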