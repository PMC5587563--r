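# Connectivity-strength group comparisons: quartile summaries,
# max-statistic permutation inference, distribution tests, mixed ANOVA
# and effect sizes.

#' Quartiles of within-subject connectivity strength distributions
#'
#' For each region-set (left hemisphere, right hemisphere,
#' interhemispheric) computes the 25/50/75 percent quantiles (linear
#' interpolation) of the subject's nonzero connection weights.
#'
#' @param c a [connectome] whose parcellation carries hemisphere tags.
#' @return A data frame with columns `subject_id`, `region_set`, `q25`,
#'   `q50`, `q75`; quantiles are `NA` when a region-set has no nonzero
#'   weights.
#' @export
strength_quartiles <- function(c) {
  sets <- list(
    left = {
      w <- extract_hemisphere(c, "left")$weights
      w[upper.tri(w)]
    },
    right = {
      w <- extract_hemisphere(c, "right")$weights
      w[upper.tri(w)]
    },
    interhemispheric = as.vector(extract_hemisphere(c, "interhemispheric")))
  rows <- lapply(names(sets), function(nm) {
    v <- sets[[nm]]
    v <- v[v > 0]
    q <- if (length(v) == 0) rep(NA_real_, 3)
         else stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    data.frame(subject_id = c$subject_id, region_set = nm,
               q25 = q[1], q50 = q[2], q75 = q[3],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Two-sample pooled-variance t-statistics for many statistics and many
# relabelings at once. V: subjects x statistics. G: relabelings x subjects
# 0/1 indicator of membership in the first group. Sign convention: first
# group mean minus second group mean. Returns relabelings x statistics.
perm_t_matrix <- function(V, G) {
  n <- nrow(V)
  n1 <- rowSums(G)[1]
  n2 <- n - n1
  sum1 <- G %*% V
  ss1 <- G %*% (V^2)
  sumT <- matrix(colSums(V), nrow(G), ncol(V), byrow = TRUE)
  ssT <- matrix(colSums(V^2), nrow(G), ncol(V), byrow = TRUE)
  sum2 <- sumT - sum1
  ss2 <- ssT - ss1
  sp2 <- (pmax(ss1 - sum1^2 / n1, 0) + pmax(ss2 - sum2^2 / n2, 0)) /
    (n - 2)
  num <- sum1 / n1 - sum2 / n2
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- num / se
  t[se == 0 & num == 0] <- 0
  t[se == 0 & num != 0] <- Inf * sign(num[se == 0 & num != 0])
  t
}

# Relabeling indicator matrix: first row is the identity labeling; the
# rest are uniform random permutations of the group labels (exhaustive =
# all distinct assignments of n1 subjects to the first group).
relabelings <- function(groups, n_perm, seed = NULL, exhaustive = FALSE) {
  g1 <- as.integer(groups == levels(groups)[1])
  n <- length(g1)
  n1 <- sum(g1)
  if (exhaustive) {
    sets <- utils::combn(n, n1)
    G <- matrix(0, ncol(sets), n)
    G[cbind(rep(seq_len(ncol(sets)), each = n1), as.vector(sets))] <- 1
    # put the identity assignment first
    obs <- which(apply(G, 1, function(r) all(r == g1)))
    G <- G[c(obs, setdiff(seq_len(nrow(G)), obs)), , drop = FALSE]
    return(G)
  }
  G <- matrix(0, n_perm, n)
  G[1, ] <- g1
  with_seed(seed, {
    for (i in seq_len(n_perm)[-1]) G[i, sample.int(n, n1)] <- 1
  })
  G
}

#' Max-statistic permutation test over a family of comparisons
#'
#' Computes a two-sample t-statistic for every column of `values`, then
#' calibrates family-wise adjusted p-values by the permutation
#' distribution of the maximal absolute t across the family: for each
#' relabeling of the group assignment (the identity labeling included),
#' the maximum |t| over all statistics is recorded, and the adjusted
#' p-value of a statistic is the proportion of relabelings whose maximum
#' reaches its observed |t|. This controls the family-wise error rate
#' without assuming independence between the statistics.
#'
#' @param values numeric matrix, subjects x statistics (e.g. 3 quartiles
#'   x 3 region-sets = 9 columns).
#' @param groups factor of length `nrow(values)` with two levels; the t
#'   sign convention is first level minus second.
#' @param n_perm number of relabelings (default 10000).
#' @param seed integer seed.
#' @param exhaustive enumerate all distinct group assignments instead of
#'   sampling (feasible for small cohorts; `n_perm` is then ignored).
#' @return A data frame with one row per statistic: `statistic`, `t_obs`,
#'   `p_raw` (per-statistic permutation p), `p_adj` (max-statistic
#'   adjusted p).
#' @export
tmax_permutation_test <- function(values, groups, n_perm = 10000,
                                  seed = NULL, exhaustive = FALSE) {
  values <- as.matrix(values)
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2) stop("need exactly two groups", call. = FALSE)
  if (!exhaustive && n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  G <- relabelings(groups, n_perm, seed, exhaustive)
  Tm <- abs(perm_t_matrix(values, G))
  t_obs <- perm_t_matrix(values, G[1, , drop = FALSE])[1, ]
  maxs <- apply(Tm, 1, max)
  p_adj <- vapply(abs(t_obs), function(t0) mean(maxs >= t0 - 1e-12),
                  numeric(1))
  p_raw <- vapply(seq_along(t_obs),
                  function(k) mean(Tm[, k] >= abs(t_obs[k]) - 1e-12),
                  numeric(1))
  nm <- colnames(values)
  if (is.null(nm)) nm <- paste0("stat", seq_along(t_obs))
  data.frame(statistic = nm, t_obs = unname(t_obs), p_raw = p_raw,
             p_adj = p_adj, stringsAsFactors = FALSE)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Thin wrapper around [stats::ks.test] returning the supremum ECDF
#' distance and its asymptotic p-value. Used to compare group-averaged
#' within-subject connectivity strength distributions (edge-wise mean
#' across the subjects of each group, then one value per edge).
#'
#' @param x,y nonempty numeric samples.
#' @return A list with `D` and `p`.
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) == 0 || length(y) == 0)
    stop("samples must be nonempty", call. = FALSE)
  kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  list(D = unname(kt$statistic), p = kt$p.value)
}

#' Group-averaged edge weight vectors
#'
#' Edge-wise mean of the upper-triangle weights across the subjects of
#' each group, for one region-set; the two resulting vectors (one value
#' per connection) are what [ks_two_sample] compares.
#'
#' @param cohort list of [connectome]s.
#' @param groups factor with two levels, aligned with `cohort`.
#' @param region_set `"left"`, `"right"` or `"interhemispheric"`.
#' @return A list of two numeric vectors named by group level.
#' @export
group_average_strengths <- function(cohort, groups,
                                    region_set = c("left", "right",
                                                   "interhemispheric")) {
  region_set <- match.arg(region_set)
  groups <- droplevels(as.factor(groups))
  vec <- function(c) {
    if (region_set == "interhemispheric")
      as.vector(extract_hemisphere(c, "interhemispheric"))
    else {
      w <- extract_hemisphere(c, region_set)$weights
      w[upper.tri(w)]
    }
  }
  M <- matrix(vapply(cohort, vec, numeric(length(vec(cohort[[1]])))),
              ncol = length(cohort))
  out <- lapply(levels(groups), function(l) {
    rowMeans(M[, groups == l, drop = FALSE])
  })
  names(out) <- levels(groups)
  out
}

#' Mixed two-way repeated-measures ANOVA with partial eta squared
#'
#' Fits a balanced mixed ANOVA with one between-subject factor (group,
#' two levels) and one within-subject factor (e.g. region with levels
#' left / interhemispheric / right), via [stats::aov] with an error
#' stratum per subject. Partial eta squared of each effect is
#' `SS_effect / (SS_effect + SS_error)` using the error term of the
#' effect's own stratum.
#'
#' @param data data frame in long format.
#' @param value,subject,group,within column names (strings) of the
#'   response, subject identifier, between-factor and within-factor.
#' @return A data frame with one row per effect (`group`, `within`,
#'   `group:within`): `df`, `df_error`, `sum_sq`, `sum_sq_error`, `F`,
#'   `p`, `partial_eta_sq`.
#' @export
rm_anova_2xk <- function(data, value = "value", subject = "subject_id",
                         group = "group", within = "region") {
  d <- data.frame(value = data[[value]],
                  subject = factor(data[[subject]]),
                  group = factor(data[[group]]),
                  within = factor(data[[within]]))
  if (nlevels(d$group) != 2)
    stop("between-subject factor must have two levels", call. = FALSE)
  tab <- table(d$subject, d$within)
  if (any(tab != 1))
    stop("design must be balanced: one value per subject per level",
         call. = FALSE)
  fit <- stats::aov(value ~ group * within + Error(subject / within),
                    data = d)
  s <- summary(fit)
  btw <- as.data.frame(s[["Error: subject"]][[1]])
  wth <- as.data.frame(s[["Error: subject:within"]][[1]])
  pick <- function(tabl, term) {
    i <- grep(paste0("^", term, "\\s*$"), rownames(tabl))
    tabl[i, , drop = FALSE]
  }
  res_b <- pick(btw, "Residuals")
  res_w <- pick(wth, "Residuals")
  one <- function(tabl, res, term, label) {
    r <- pick(tabl, term)
    data.frame(effect = label, df = r$Df, df_error = res$Df,
               sum_sq = r$`Sum Sq`, sum_sq_error = res$`Sum Sq`,
               F = r$`F value`, p = r$`Pr(>F)`,
               partial_eta_sq = r$`Sum Sq` / (r$`Sum Sq` + res$`Sum Sq`),
               stringsAsFactors = FALSE)
  }
  out <- rbind(one(btw, res_b, "group", "group"),
               one(wth, res_w, "within", "within"),
               one(wth, res_w, "group:within", "group:within"))
  rownames(out) <- NULL
  out
}

#' Simple effects of group at each within-factor level
#'
#' Independent-samples t-test (pooled variance) comparing the two groups
#' at each level of the within-subject factor, with Hedges' g.
#'
#' @inheritParams rm_anova_2xk
#' @return A data frame with columns `level`, `t`, `df`, `p`,
#'   `hedges_g` (first group minus second).
#' @export
simple_effects_group <- function(data, value = "value",
                                 subject = "subject_id", group = "group",
                                 within = "region") {
  d <- data.frame(value = data[[value]], group = factor(data[[group]]),
                  within = factor(data[[within]]))
  lv <- levels(d$group)
  rows <- lapply(levels(d$within), function(l) {
    x <- d$value[d$within == l & d$group == lv[1]]
    y <- d$value[d$within == l & d$group == lv[2]]
    tt <- stats::t.test(x, y, var.equal = TRUE)
    data.frame(level = l, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               hedges_g = hedges_g(x, y), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Hedges' g standardized mean difference
#'
#' Bias-corrected standardized mean difference
#' `g = J * (mean(x) - mean(y)) / s_pooled` with small-sample correction
#' `J = 1 - 3 / (4 (n_x + n_y - 2) - 1)`; less biased than Cohen's d in
#' small samples.
#'
#' @param x,y numeric samples with at least 2 observations each.
#' @return Scalar effect size.
#' @export
hedges_g <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop("need >= 2 observations per sample",
                             call. = FALSE)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
    (nx + ny - 2)
  if (sp2 == 0) stop("zero pooled variance", call. = FALSE)
  J <- 1 - 3 / (4 * (nx + ny - 2) - 1)
  J * (mean(x) - mean(y)) / sqrt(sp2)
}
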