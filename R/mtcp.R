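# Multi-threshold cluster permutation (MTCP) inference: group statistics
# evaluated over a grid of edge densities, calibrated by the permutation
# distribution of the maximal |t| across the grid, with the supercritical
# area-under-the-curve as an effect-size measure that combines strength
# and persistence of an effect across thresholds.

#' Default threshold grids
#'
#' The global grid spans densities 0.05 to 0.95 in steps of 0.05
#' (19 points); the nodal grid spans 0.10 to 0.90 in steps of 0.02
#' (41 points). Lower densities risk fragmenting the network, higher
#' densities admit spurious connections.
#'
#' @name kappa_grids
#' @return Numeric vector of densities.
NULL

#' @rdname kappa_grids
#' @export
kappa_grid_global <- function() seq(0.05, 0.95, by = 0.05)

#' @rdname kappa_grids
#' @export
kappa_grid_nodal <- function() seq(0.10, 0.90, by = 0.02)

# Cohort restricted to a scope; masks computed once per kappa from the
# pooled (both groups) median summary of that scope.
scope_cohort <- function(cohort, scope = c("whole", "left", "right")) {
  scope <- match.arg(scope)
  if (scope == "whole") cohort
  else lapply(cohort, extract_hemisphere, side = scope)
}

masks_for <- function(cohort, kappas) {
  summ <- median_summary(cohort)
  lapply(kappas, function(k) density_threshold(summ, k))
}

eval_global_measure <- function(w, measure, denominator = "degree",
                                mod_repeats = 10, mod_seed = 1L) {
  switch(measure,
    efficiency = global_efficiency(w),
    clustering = weighted_clustering(w, denominator)$global,
    modularity = modularity_q(w, repeats = mod_repeats, seed = mod_seed)$Q,
    median_strength = {
      v <- w[upper.tri(w)]
      v <- v[v > 0]
      if (length(v) == 0) NA_real_ else stats::median(v)
    },
    stop("unknown global measure: ", measure, call. = FALSE))
}

#' Per-subject measure curve over the density grid
#'
#' Evaluates a global or nodal graph measure for every subject at every
#' edge density of a grid. Masks come from the pooled median summary of
#' the scoped cohort, so the same mask is applied to both groups at each
#' density. Global efficiency and clustering may be normalised per
#' subject and density by the mean of a degree- and strength-preserving
#' null ensemble.
#'
#' @param cohort list of [connectome]s (identical parcellations).
#' @param scope `"whole"`, `"left"` or `"right"`.
#' @param measure one of `"efficiency"`, `"clustering"`, `"modularity"`,
#'   `"median_strength"` (global), or `"strength"`,
#'   `"local_efficiency"`, `"local_clustering"` (nodal; needs `node`).
#' @param kappas density grid (defaults to the global grid for global
#'   measures, the nodal grid for nodal ones).
#' @param normalize null-normalise efficiency/clustering
#'   (default `FALSE`).
#' @param node region label or index for nodal measures.
#' @param denominator clustering denominator, see [weighted_clustering].
#' @param ensemble_size,rewires_per_edge null-ensemble settings when
#'   `normalize = TRUE`.
#' @param seed master seed; per-subject, per-density ensemble and
#'   modularity seeds are derived from it by a counter.
#' @return An object of class `measure_curve`: list with `kappas`,
#'   `values` (subjects x densities matrix), `measure`, `scope`,
#'   `normalized`, `node`, `subject_ids`.
#' @export
measure_curve <- function(cohort, scope = "whole", measure = "efficiency",
                          kappas = NULL, normalize = FALSE, node = NULL,
                          denominator = "degree", ensemble_size = 150,
                          rewires_per_edge = 10, seed = 1L) {
  nodal <- measure %in% c("strength", "local_efficiency",
                          "local_clustering")
  if (is.null(kappas))
    kappas <- if (nodal) kappa_grid_nodal() else kappa_grid_global()
  if (nodal && is.null(node))
    stop("nodal measures need `node`", call. = FALSE)
  if (normalize && !measure %in% c("efficiency", "clustering"))
    stop("only efficiency and clustering are null-normalised",
         call. = FALSE)
  sc <- scope_cohort(cohort, scope)
  if (nodal) {
    arr <- nodal_curve_array(sc, measure, kappas, denominator)
    idx <- if (is.character(node))
      match(node, sc[[1]]$parcellation$label) else node
    if (is.na(idx) || idx < 1 || idx > dim(arr)[3])
      stop("unknown node: ", node, call. = FALSE)
    vals <- arr[, , idx]
  } else {
    masks <- masks_for(sc, kappas)
    vals <- matrix(NA_real_, length(sc), length(kappas))
    ctr <- 0L
    for (i in seq_along(sc)) {
      for (k in seq_along(kappas)) {
        ctr <- ctr + 1L
        wm <- sc[[i]]$weights
        wm[!masks[[k]]$mask] <- 0
        if (normalize) {
          nm <- normalize_measure(wm, measure, ensemble_size,
                                  rewires_per_edge,
                                  derive_seed(seed, ctr), denominator)
          vals[i, k] <- nm$normalized
        } else {
          vals[i, k] <- eval_global_measure(wm, measure, denominator,
                                            mod_seed = derive_seed(seed,
                                                                   ctr))
        }
      }
    }
  }
  structure(list(kappas = kappas, values = vals, measure = measure,
                 scope = scope, normalized = normalize,
                 node = if (nodal) node else NULL,
                 subject_ids = vapply(sc, function(x) x$subject_id, "")),
            class = "measure_curve")
}

# subjects x kappas x nodes array of a nodal measure over nested masks.
nodal_curve_array <- function(sc, measure, kappas,
                              denominator = "degree") {
  masks <- masks_for(sc, kappas)
  n <- nrow(sc[[1]]$weights)
  arr <- array(NA_real_, c(length(sc), length(kappas), n),
               dimnames = list(NULL, NULL, sc[[1]]$parcellation$label))
  for (i in seq_along(sc)) {
    for (k in seq_along(kappas)) {
      wm <- sc[[i]]$weights
      wm[!masks[[k]]$mask] <- 0
      arr[i, k, ] <- switch(measure,
        strength = rowSums(wm),
        local_efficiency = local_efficiency(wm),
        local_clustering = weighted_clustering(wm, denominator)$local,
        stop("unknown nodal measure: ", measure, call. = FALSE))
    }
  }
  arr
}

# Supercritical area of a piecewise-linear |t| curve above t_crit:
# trapezoidal integration over the maximal contiguous supercritical run
# containing the peak, extended to the interpolated crossings of t_crit
# at the run boundaries (so a single supercritical point still carries
# positive area). Returns 0 when the peak does not exceed t_crit.
sc_area <- function(abs_t, t_crit, kappas) {
  k_star <- which.max(abs_t)
  if (!(abs_t[k_star] > t_crit)) return(0)
  n <- length(abs_t)
  a <- k_star
  while (a > 1 && abs_t[a - 1] > t_crit) a <- a - 1
  b <- k_star
  while (b < n && abs_t[b + 1] > t_crit) b <- b + 1
  xs <- kappas[a:b]
  ys <- abs_t[a:b] - t_crit
  # linear interpolation to the zero-crossings just outside the run
  if (a > 1) {
    y0 <- abs_t[a - 1] - t_crit
    x0 <- kappas[a - 1] + (kappas[a] - kappas[a - 1]) * (-y0) /
      (ys[1] - y0)
    xs <- c(x0, xs); ys <- c(0, ys)
  }
  if (b < n) {
    y1 <- abs_t[b + 1] - t_crit
    xn <- kappas[b] + (kappas[b + 1] - kappas[b]) * ys[length(ys)] /
      (ys[length(ys)] - y1)
    xs <- c(xs, xn); ys <- c(ys, 0)
  }
  if (length(xs) < 2) return(0)
  sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
}

#' Multi-threshold cluster permutation test on a measure curve
#'
#' For each density of the grid, computes an independent-samples pooled
#' t-statistic between the two groups (first factor level minus second,
#' so that with controls first, positive t means a deficit in patients).
#' The same set of group relabelings (identity included) is evaluated at
#' every density; the 95th percentile of the per-relabeling maximal |t|
#' across densities is the critical value `t_crit`. A significant effect
#' is declared when the observed maximal |t| exceeds `t_crit`; its
#' supercritical cluster is the maximal contiguous density run around
#' the peak where |t| stays above `t_crit`, and the supercritical
#' area-under-the-curve `A` is the trapezoidal area of |t| - t_crit over
#' that run (boundaries interpolated to the crossings). `A_crit` is the
#' average supercritical area of the relabelings, averaged over those
#' with a nonzero area (`A_crit_all` averages over all relabelings).
#' The family-wise p-value is the proportion of relabelings whose
#' maximal |t| reaches the observed one.
#'
#' @param curve a [measure_curve] (or a plain subjects x densities
#'   matrix plus `kappas`).
#' @param groups factor of length n-subjects with two levels.
#' @param n_perm number of relabelings (default 1000).
#' @param alpha significance level for `t_crit` (default 0.05).
#' @param seed integer seed.
#' @param exhaustive enumerate all distinct group assignments.
#' @param kappas density grid when `curve` is a plain matrix.
#' @return An object of class `mtcp_result`: `kappas`, `t_obs`,
#'   `t_crit`, `t_max`, `kappa_mtcp`, `t_mtcp` (signed t at the peak),
#'   `cluster_range`, `A`, `A_crit`, `A_crit_all`, `p`, `significant`,
#'   `n_perm`, `dropped_kappas`.
#' @export
mtcp_test <- function(curve, groups, n_perm = 1000, alpha = 0.05,
                      seed = NULL, exhaustive = FALSE, kappas = NULL) {
  if (inherits(curve, "measure_curve")) {
    V <- curve$values
    kappas <- curve$kappas
  } else {
    V <- as.matrix(curve)
    if (is.null(kappas)) stop("kappas required for a plain matrix",
                              call. = FALSE)
  }
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2) stop("need exactly two groups", call. = FALSE)
  if (min(table(groups)) < 2)
    stop("need at least 2 subjects per group", call. = FALSE)
  ok <- apply(V, 2, function(col) all(is.finite(col)) &&
                stats::var(col) > 0)
  dropped <- kappas[!ok]
  if (length(dropped) > 0)
    warning(sprintf("dropping %d densities with missing values or zero variance",
                    length(dropped)))
  V <- V[, ok, drop = FALSE]
  kap <- kappas[ok]
  if (ncol(V) == 0) stop("no usable densities left", call. = FALSE)
  G <- relabelings(groups, n_perm, seed, exhaustive)
  Tm <- perm_t_matrix(V, G)
  t_obs <- Tm[1, ]
  abs_obs <- abs(t_obs)
  perm_max <- apply(abs(Tm), 1, max)
  t_crit <- unname(stats::quantile(perm_max, 1 - alpha, type = 7))
  k_star <- which.max(abs_obs)
  t_max <- abs_obs[k_star]
  A <- sc_area(abs_obs, t_crit, kap)
  perm_A <- apply(abs(Tm[-1, , drop = FALSE]), 1, sc_area, t_crit = t_crit,
                  kappas = kap)
  pos <- perm_A[perm_A > 0]
  structure(list(
    kappas = kap, t_obs = t_obs, t_crit = t_crit, t_max = t_max,
    kappa_mtcp = kap[k_star], t_mtcp = t_obs[k_star],
    cluster_range = if (A > 0) range(kap[abs_obs > t_crit]) else NULL,
    A = A,
    A_crit = if (length(pos) > 0) mean(pos) else 0,
    A_crit_all = if (length(perm_A) > 0) mean(perm_A) else 0,
    p = mean(perm_max >= t_max - 1e-12),
    significant = t_max > t_crit,
    n_perm = nrow(G), dropped_kappas = dropped),
    class = "mtcp_result")
}

#' @export
print.mtcp_result <- function(x, ...) {
  cat(sprintf(
    "MTCP: t_max = %.3f vs t_crit = %.3f (p = %.4g, %d relabelings)\n",
    x$t_max, x$t_crit, x$p, x$n_perm))
  if (x$significant)
    cat(sprintf(
      "  peak at kappa = %.2f (t = %.3f), cluster [%.2f, %.2f], A = %.3f (A_crit = %.3f)\n",
      x$kappa_mtcp, x$t_mtcp, x$cluster_range[1], x$cluster_range[2],
      x$A, x$A_crit))
  else cat("  no supercritical cluster\n")
  invisible(x)
}

#' Nodal MTCP screen across all regions
#'
#' Runs the MTCP machinery on the per-node curves of a nodal measure for
#' every region of the scoped network, sharing one set of group
#' relabelings across regions and densities. Each region gets its own
#' critical value (the 95th percentile of its relabeling maximal-|t|
#' distribution). Regions whose curves are degenerate (all-zero or
#' missing at every density) are dropped with a warning.
#'
#' @inheritParams mtcp_test
#' @param cohort list of [connectome]s.
#' @param scope `"whole"`, `"left"` or `"right"`.
#' @param measure `"strength"`, `"local_efficiency"` or
#'   `"local_clustering"`.
#' @param kappas density grid (default the nodal grid).
#' @param denominator clustering denominator.
#' @return A data frame, one row per region: `measure`, `region`,
#'   `kappa_mtcp`, `control_value`, `patient_value` (group means of the
#'   measure at the peak density; first and second group level),
#'   `hedges_g`, `t_max` (signed t at the peak), `t_crit`, `A`,
#'   `A_crit`, `A_crit_all`, `p`, `significant` (t_max ratio > 1),
#'   `persistent` (A ratio > 1).
#' @export
nodal_mtcp_screen <- function(cohort, scope = "right",
                              measure = "strength", groups,
                              kappas = kappa_grid_nodal(), n_perm = 1000,
                              alpha = 0.05, seed = NULL,
                              denominator = "degree") {
  groups <- droplevels(as.factor(groups))
  sc <- scope_cohort(cohort, scope)
  arr <- nodal_curve_array(sc, measure, kappas, denominator)
  G <- relabelings(groups, n_perm, seed)
  regions <- dimnames(arr)[[3]]
  lv <- levels(groups)
  rows <- list()
  for (j in seq_along(regions)) {
    V <- arr[, , j]
    ok <- apply(V, 2, function(col) all(is.finite(col)) &&
                  stats::var(col) > 0)
    if (!any(ok)) {
      warning("dropping degenerate region: ", regions[j])
      next
    }
    Vok <- V[, ok, drop = FALSE]
    kap <- kappas[ok]
    Tm <- perm_t_matrix(Vok, G)
    t_obs <- Tm[1, ]
    abs_obs <- abs(t_obs)
    perm_max <- apply(abs(Tm), 1, max)
    t_crit <- unname(stats::quantile(perm_max, 1 - alpha, type = 7))
    k_star <- which.max(abs_obs)
    A <- sc_area(abs_obs, t_crit, kap)
    perm_A <- apply(abs(Tm[-1, , drop = FALSE]), 1, sc_area,
                    t_crit = t_crit, kappas = kap)
    pos <- perm_A[perm_A > 0]
    x <- Vok[groups == lv[1], k_star]
    y <- Vok[groups == lv[2], k_star]
    rows[[length(rows) + 1]] <- data.frame(
      measure = measure, region = regions[j], kappa_mtcp = kap[k_star],
      control_value = mean(x), patient_value = mean(y),
      hedges_g = tryCatch(hedges_g(x, y), error = function(e) NA_real_),
      t_max = t_obs[k_star], t_crit = t_crit, A = A,
      A_crit = if (length(pos) > 0) mean(pos) else 0,
      A_crit_all = mean(perm_A),
      p = mean(perm_max >= abs_obs[k_star] - 1e-12),
      significant = abs_obs[k_star] > t_crit,
      persistent = A > (if (length(pos) > 0) mean(pos) else 0) && A > 0,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
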