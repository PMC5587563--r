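# Orchestration of the full group analysis: strength comparison ->
# global MTCP -> nodal MTCP -> clinical association, with reproducible
# seeding and plain CSV/JSON outputs.

#' Run configuration
#'
#' @param kappas_global density grid for global measures.
#' @param kappas_nodal density grid for nodal measures.
#' @param n_perm_strength relabelings for the max-statistic strength
#'   test.
#' @param n_perm_mtcp relabelings per MTCP test.
#' @param ensemble_size null-ensemble size for normalisation.
#' @param normalize null-normalise global efficiency and clustering.
#' @param denominator clustering denominator, see [weighted_clustering].
#' @param global_measures global measures to test.
#' @param nodal_measures nodal measures to screen.
#' @param nodal_scope scope of the nodal screen.
#' @param master_seed master seed; every stage derives its own seed.
#' @param output_dir directory for result tables.
#' @return A list of class `run_config`.
#' @export
run_config <- function(kappas_global = kappa_grid_global(),
                       kappas_nodal = kappa_grid_nodal(),
                       n_perm_strength = 10000,
                       n_perm_mtcp = 1000,
                       ensemble_size = 150,
                       normalize = TRUE,
                       denominator = "degree",
                       global_measures = c("efficiency", "clustering",
                                           "modularity"),
                       nodal_measures = c("strength", "local_efficiency",
                                          "local_clustering"),
                       nodal_scope = "right",
                       master_seed = 1L,
                       output_dir = NULL) {
  if (any(kappas_global <= 0 | kappas_global > 1) ||
      any(kappas_nodal <= 0 | kappas_nodal > 1))
    stop("density grids must lie in (0, 1]", call. = FALSE)
  if (n_perm_strength < 1 || n_perm_mtcp < 1 || ensemble_size < 1)
    stop("counts must be positive", call. = FALSE)
  structure(as.list(environment()), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Keys mirror the arguments of [run_config]; unknown keys are an error.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read YAML configs",
         call. = FALSE)
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0)
    stop("unknown config keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(run_config, vals)
}

stage_seed <- function(cfg, stage) derive_seed(cfg$master_seed, stage)

#' Run the full group analysis
#'
#' Executes, in order: (1) connectivity-strength comparison (per-subject
#' quartiles per region-set, max-statistic permutation test over the
#' 9-fold family, Kolmogorov-Smirnov tests on group-averaged edge
#' distributions, and a 2 x 3 mixed ANOVA of median strength with simple
#' effects); (2) MTCP tests of the global measures for whole-brain,
#' left- and right-hemisphere networks; (3) a nodal MTCP screen; (4)
#' association of non-normalised right-hemisphere global efficiency of
#' the unthresholded network with the clinical score (patients only),
#' including the linear-versus-exponential model comparison. Stage
#' outputs are written as CSV/JSON under `cfg$output_dir` (if set)
#' together with a manifest recording configuration, seeds and package
#' version.
#'
#' @param cohort list of [connectome]s.
#' @param covariates data frame with `subject_id`, `group`, `age`,
#'   `score`, aligned with `cohort` by `subject_id`.
#' @param cfg a [run_config].
#' @return A list with elements `strengths`, `strength_test`,
#'   `ks_tests`, `anova`, `simple_effects`, `global_mtcp`,
#'   `nodal_screen`, `association`, `model_comparison`, `manifest`.
#' @export
run_full_analysis <- function(cohort, covariates, cfg = run_config()) {
  ids <- vapply(cohort, function(x) x$subject_id, "")
  covariates <- covariates[match(ids, covariates$subject_id), ]
  if (any(is.na(covariates$subject_id)))
    stop("stage covariates: cohort subjects missing from covariate table",
         call. = FALSE)
  groups <- factor(covariates$group)
  res <- list()

  # -- stage 1: overall connectivity strength -------------------------
  sq <- do.call(rbind, lapply(cohort, strength_quartiles))
  res$strengths <- sq
  wide <- stats::reshape(sq, idvar = "subject_id", timevar = "region_set",
                         direction = "wide")
  vm <- as.matrix(wide[, -1])
  rownames(vm) <- wide$subject_id
  res$strength_test <- tmax_permutation_test(
    vm[ids, , drop = FALSE], groups, n_perm = cfg$n_perm_strength,
    seed = stage_seed(cfg, 1L))
  res$ks_tests <- do.call(rbind, lapply(
    c("left", "right", "interhemispheric"), function(rs) {
      av <- group_average_strengths(cohort, groups, rs)
      ks <- ks_two_sample(av[[1]], av[[2]])
      data.frame(region_set = rs, D = ks$D, p = ks$p,
                 stringsAsFactors = FALSE)
    }))
  long <- sq[, c("subject_id", "region_set", "q50")]
  long$group <- covariates$group[match(long$subject_id,
                                       covariates$subject_id)]
  res$anova <- rm_anova_2xk(long, value = "q50", within = "region_set")
  res$simple_effects <- simple_effects_group(long, value = "q50",
                                             within = "region_set")

  # -- stage 2: global graph parameters, MTCP -------------------------
  rows <- list()
  ctr <- 100L
  for (scope in c("whole", "left", "right")) {
    for (ms in cfg$global_measures) {
      ctr <- ctr + 1L
      norm <- cfg$normalize && ms %in% c("efficiency", "clustering")
      cv <- measure_curve(cohort, scope, ms, kappas = cfg$kappas_global,
                          normalize = norm,
                          denominator = cfg$denominator,
                          ensemble_size = cfg$ensemble_size,
                          seed = stage_seed(cfg, ctr))
      mt <- mtcp_test(cv, groups, n_perm = cfg$n_perm_mtcp,
                      seed = stage_seed(cfg, ctr + 1000L))
      rows[[length(rows) + 1]] <- data.frame(
        scope = scope, measure = ms, normalized = norm,
        kappa_mtcp = mt$kappa_mtcp, t_mtcp = mt$t_mtcp,
        t_max = mt$t_max, t_crit = mt$t_crit, A = mt$A,
        A_crit = mt$A_crit, p = mt$p, significant = mt$significant,
        stringsAsFactors = FALSE)
    }
  }
  res$global_mtcp <- do.call(rbind, rows)

  # -- stage 3: nodal MTCP screen -------------------------------------
  res$nodal_screen <- do.call(rbind, lapply(
    seq_along(cfg$nodal_measures), function(i) {
      nodal_mtcp_screen(cohort, cfg$nodal_scope, cfg$nodal_measures[i],
                        groups, kappas = cfg$kappas_nodal,
                        n_perm = cfg$n_perm_mtcp,
                        seed = stage_seed(cfg, 300L + i),
                        denominator = cfg$denominator)
    }))

  # -- stage 4: clinical association ----------------------------------
  pat <- covariates$group == levels(groups)[2]
  eff <- vapply(cohort, function(c)
    global_efficiency(extract_hemisphere(c, "right")), numeric(1))
  score <- covariates$score
  if (sum(pat & is.finite(score) & is.finite(eff)) >= 5) {
    res$association <- tryCatch(
      correlate_with_score(eff[pat], score[pat], covariates$age[pat]),
      error = function(e) e$message)
    res$model_comparison <- tryCatch(
      fit_and_compare(eff[pat], score[pat],
                      seed = stage_seed(cfg, 400L)),
      error = function(e) e$message)
  } else {
    res$association <- NULL
    res$model_comparison <- NULL
  }

  res$manifest <- list(
    package = "connectopy",
    version = as.character(utils::packageVersion("connectopy")),
    master_seed = cfg$master_seed,
    n_subjects = length(cohort),
    groups = as.list(table(groups)),
    config = cfg[!vapply(cfg, is.null, TRUE)])

  if (!is.null(cfg$output_dir)) write_analysis(res, cfg$output_dir)
  invisible(res)
}

write_analysis <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(d, f) utils::write.csv(d, file.path(dir, f),
                                        row.names = FALSE)
  wr(res$strengths, "strength_quartiles.csv")
  wr(res$strength_test, "strength_tmax_test.csv")
  wr(res$ks_tests, "ks_tests.csv")
  wr(res$anova, "anova.csv")
  wr(res$simple_effects, "simple_effects.csv")
  wr(res$global_mtcp, "global_mtcp.csv")
  wr(res$nodal_screen, "nodal_mtcp.csv")
  if (!is.null(res$association)) {
    wr(res$association, "association.csv")
    if (inherits(res$model_comparison, "model_comparison"))
      wr(res$model_comparison$models, "model_comparison.csv")
  }
  jsonlite::write_json(res$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
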