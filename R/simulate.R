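# Synthetic cohorts of weighted connectomes with known ground truth.
#
# The generator emulates the statistical structure the analysis assumes:
# symmetric nonnegative 72 x 72 matrices with zero diagonal, lognormal
# right-skewed weights, stronger intra- than inter-hemispheric
# connectivity, an optional multiplicative right-hemisphere deficit in
# the patient group, and clinical scores coupled to right-hemisphere
# global efficiency.

#' Simulation configuration
#'
#' @param n_nodes_per_hemisphere regions per hemisphere (default 36, the
#'   standard scheme).
#' @param n_controls,n_patients group sizes (default 13 each, >= 2).
#' @param base_logw_mean,base_logw_sd mean and SD of log weights of the
#'   intra-hemispheric blocks of the population template.
#' @param intra_inter_ratio ratio of intra- to inter-hemispheric mean
#'   weight (> 1; interhemispheric connections are weaker).
#' @param delta multiplicative right-hemisphere weight deficit in
#'   patients, in \[0, 1); 0 is the null.
#' @param subject_noise_sd SD of the per-subject, per-edge multiplicative
#'   lognormal noise (log scale).
#' @param volume_meanlog,volume_sdlog lognormal parameters of ROI
#'   volumes (mm^3).
#' @param age_mean,age_sd normal parameters of subject age (years).
#' @param score_link `"none"`, `"linear"` or `"exponential"` coupling of
#'   the clinical score to patients' right-hemisphere global efficiency.
#'   The link operates on the deviation `d = eff - eff_ref` of a
#'   subject's efficiency from the patient-group mean efficiency, so
#'   severity reflects a patient's relative standing and the score scale
#'   is stable across template draws.
#' @param score_a,score_b link coefficients: linear
#'   `score = a + b * d`, exponential `score = a * exp(b * d)`. Both
#'   links stay within the model families fitted by
#'   [fit_and_compare] (an exponential in `d` is an exponential in
#'   `eff`).
#' @param score_noise_sd SD of additive score noise; defaults to 8 for
#'   the linear link and 5 for the exponential one (keeping the
#'   curvature of the exponential link identifiable at small cohort
#'   sizes).
#' @param seed master seed.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_nodes_per_hemisphere = 36,
                              n_controls = 13, n_patients = 13,
                              base_logw_mean = log(0.3),
                              base_logw_sd = 0.8,
                              intra_inter_ratio = 3,
                              delta = 0,
                              subject_noise_sd = 0.3,
                              volume_meanlog = log(5000),
                              volume_sdlog = 0.3,
                              age_mean = 34.5, age_sd = 9,
                              score_link = c("none", "linear",
                                             "exponential"),
                              score_a = NULL, score_b = NULL,
                              score_noise_sd = NULL,
                              seed = 1L) {
  score_link <- match.arg(score_link)
  if (delta < 0 || delta >= 1) stop("delta must be in [0, 1)",
                                    call. = FALSE)
  if (n_controls < 2 || n_patients < 2)
    stop("group sizes must be >= 2", call. = FALSE)
  if (intra_inter_ratio <= 1)
    stop("intra_inter_ratio must exceed 1", call. = FALSE)
  if (base_logw_sd < 0 || subject_noise_sd < 0 ||
      (!is.null(score_noise_sd) && score_noise_sd < 0))
    stop("SDs must be nonnegative", call. = FALSE)
  # Default link coefficients map typical efficiency deviations (about
  # +/- 0.04 around the cohort mean) onto a YGTSS-like band, with the
  # exponential slope set so that the curvature signal (quadratic
  # departure from the best line) is about twice the score noise at the
  # default deviation spread.
  if (is.null(score_a))
    score_a <- if (score_link == "exponential") 20 else 35
  if (is.null(score_b))
    score_b <- if (score_link == "exponential") 50 else 400
  if (is.null(score_noise_sd))
    score_noise_sd <- if (score_link == "exponential") 5 else 8
  structure(list(n_nodes_per_hemisphere = n_nodes_per_hemisphere,
                 n_controls = n_controls, n_patients = n_patients,
                 base_logw_mean = base_logw_mean,
                 base_logw_sd = base_logw_sd,
                 intra_inter_ratio = intra_inter_ratio, delta = delta,
                 subject_noise_sd = subject_noise_sd,
                 volume_meanlog = volume_meanlog,
                 volume_sdlog = volume_sdlog,
                 age_mean = age_mean, age_sd = age_sd,
                 score_link = score_link, score_a = score_a,
                 score_b = score_b, score_noise_sd = score_noise_sd,
                 seed = seed),
            class = "simulation_config")
}

#' Simulate a cohort of connectomes with covariates
#'
#' Draws a symmetric lognormal population template with block structure
#' (intra-left, intra-right, interhemispheric; the interhemispheric
#' block mean is divided by `intra_inter_ratio`), multiplies it per
#' subject by elementwise lognormal noise, scales the intra-right block
#' of patients by `1 - delta`, converts weights to raw "streamline
#' counts" through drawn ROI volumes (so that [build_connectome]
#' round-trips exactly), and generates clinical scores for patients from
#' their right-hemisphere global efficiency via the configured link.
#'
#' @param cfg a [simulation_config].
#' @return A list with `cohort` (list of [connectome]s, controls first),
#'   `covariates` (data frame `subject_id`, `group`, `age`, `score`) and
#'   `ground_truth` (template matrix, volumes, delta, link parameters,
#'   per-patient right-hemisphere efficiency).
#' @export
simulate_cohort <- function(cfg = simulation_config()) {
  if (!inherits(cfg, "simulation_config"))
    stop("cfg must be a simulation_config", call. = FALSE)
  nh <- cfg$n_nodes_per_hemisphere
  n <- 2L * nh
  with_seed(cfg$seed, {
    left <- seq_len(nh)
    right <- nh + seq_len(nh)
    # population template, upper triangle lognormal by block
    tmpl <- matrix(0, n, n)
    ut <- upper.tri(tmpl)
    mlog <- matrix(cfg$base_logw_mean - log(cfg$intra_inter_ratio), n, n)
    mlog[left, left] <- cfg$base_logw_mean
    mlog[right, right] <- cfg$base_logw_mean
    tmpl[ut] <- stats::rlnorm(sum(ut), mlog[ut], cfg$base_logw_sd)
    tmpl <- tmpl + t(tmpl)

    volumes <- stats::rlnorm(n, cfg$volume_meanlog, cfg$volume_sdlog)
    if (nh == 36) {
      parc <- default_parcellation(volumes)
    } else {
      parc <- parcellation(
        c(sprintf("lh_r%02d", seq_len(nh)), sprintf("rh_r%02d", seq_len(nh))),
        rep(c("left", "right"), each = nh), volumes)
    }

    n_tot <- cfg$n_controls + cfg$n_patients
    ids <- c(sprintf("ctrl%02d", seq_len(cfg$n_controls)),
             sprintf("pat%02d", seq_len(cfg$n_patients)))
    grp <- rep(c("control", "patient"),
               c(cfg$n_controls, cfg$n_patients))
    vv <- outer(volumes, volumes)
    cohort <- vector("list", n_tot)
    eff_right <- rep(NA_real_, n_tot)
    for (i in seq_len(n_tot)) {
      noise <- matrix(0, n, n)
      noise[ut] <- stats::rnorm(sum(ut), 0, cfg$subject_noise_sd)
      noise <- noise + t(noise)
      w <- tmpl * exp(noise)
      if (grp[i] == "patient" && cfg$delta > 0)
        w[right, right] <- w[right, right] * (1 - cfg$delta)
      raw <- w * vv            # volume-normalisation round-trip
      cohort[[i]] <- build_connectome(raw, parc, ids[i])
      if (cfg$score_link != "none" && grp[i] == "patient")
        eff_right[i] <- global_efficiency(
          extract_hemisphere(cohort[[i]], "right"))
    }

    ages <- stats::rnorm(n_tot, cfg$age_mean, cfg$age_sd)
    score <- rep(NA_real_, n_tot)
    eff_ref <- NA_real_
    if (cfg$score_link != "none") {
      pat <- grp == "patient"
      eff_ref <- mean(eff_right[pat])
      dev <- eff_right[pat] - eff_ref
      mu <- switch(cfg$score_link,
                   linear = cfg$score_a + cfg$score_b * dev,
                   exponential = cfg$score_a * exp(cfg$score_b * dev))
      # severity scores live on a bounded positive scale (YGTSS-like)
      score[pat] <- pmin(pmax(mu + stats::rnorm(sum(pat), 0,
                                                cfg$score_noise_sd), 1),
                         100)
    }

    list(cohort = cohort,
         covariates = data.frame(subject_id = ids, group = grp,
                                 age = ages, score = score,
                                 stringsAsFactors = FALSE),
         ground_truth = list(template = tmpl, volumes = volumes,
                             delta = cfg$delta,
                             score_link = cfg$score_link,
                             score_a = cfg$score_a,
                             score_b = cfg$score_b,
                             score_noise_sd = cfg$score_noise_sd,
                             eff_ref = eff_ref,
                             eff_right = eff_right))
  })
}

#' Seeded random weight matrix
#'
#' Symmetric zero-diagonal matrix with a given edge density and uniform
#' weights; the deterministic building block of the oracle test graphs.
#'
#' @param n node count.
#' @param density fraction of node pairs connected.
#' @param seed integer seed.
#' @param wmin,wmax weight range.
#' @return An n x n numeric matrix.
#' @export
random_weight_matrix <- function(n, density = 0.5, seed = 1L,
                                 wmin = 0.2, wmax = 1) {
  with_seed(seed, {
    m <- matrix(0, n, n)
    ut <- which(upper.tri(m))
    on <- stats::runif(length(ut)) < density
    m[ut[on]] <- stats::runif(sum(on), wmin, wmax)
    m + t(m)
  })
}

#' Deterministic library of small test graphs
#'
#' Named weight matrices used throughout the oracle tests: `triangle`
#' (3 unit edges), `path3`, `star4` (3 unit leaves), `complete4`,
#' `two_cliques` (two disjoint unit triangles; exhaustive-partition
#' modularity 0.5), `planted` (12-node two-block planted partition,
#' fixed seed) and `random10` (seeded 10-node random weighted graph).
#'
#' @return A named list of symmetric weight matrices.
#' @export
fixture_suite <- function() {
  tri <- matrix(0, 3, 3); tri[1, 2] <- tri[2, 3] <- tri[1, 3] <- 1
  tri <- pmax(tri, t(tri))
  path3 <- matrix(0, 3, 3); path3[1, 2] <- path3[2, 3] <- 1
  path3 <- pmax(path3, t(path3))
  star4 <- matrix(0, 4, 4); star4[1, 2:4] <- 1
  star4 <- pmax(star4, t(star4))
  complete4 <- matrix(1, 4, 4); diag(complete4) <- 0
  two_cliques <- matrix(0, 6, 6)
  two_cliques[1:3, 1:3] <- tri
  two_cliques[4:6, 4:6] <- tri
  planted <- with_seed(123L, {
    m <- matrix(0, 12, 12)
    for (i in 1:11) for (j in (i + 1):12) {
      same <- (i <= 6) == (j <= 6)
      if (stats::runif(1) < if (same) 0.9 else 0.15)
        m[i, j] <- stats::runif(1, if (same) 0.5 else 0.05,
                                if (same) 1 else 0.3)
    }
    m + t(m)
  })
  list(triangle = tri, path3 = path3, star4 = star4,
       complete4 = complete4, two_cliques = two_cliques,
       planted = planted,
       random10 = random_weight_matrix(10, 0.5, seed = 7L))
}

#' Write a simulated cohort to disk
#'
#' Writes per-subject matrix CSVs, the region table, the cohort
#' covariate table and a ground-truth JSON into a directory.
#'
#' @param sim result of [simulate_cohort].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (c in sim$cohort)
    write_matrix(c, file.path(dir, paste0(c$subject_id, ".csv")))
  write_region_table(sim$cohort[[1]]$parcellation,
                     file.path(dir, "regions.csv"))
  utils::write.csv(sim$covariates, file.path(dir, "cohort.csv"),
                   row.names = FALSE)
  gt <- sim$ground_truth
  gt$template <- NULL          # large; reproducible from the seed
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
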