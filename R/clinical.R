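# Association of network measures with clinical severity scores:
# linear, rank and age-partial correlations, and comparison of a linear
# against a two-parameter exponential model by small-sample AIC.

#' Correlate a network measure with a clinical score
#'
#' Pearson correlation with a t-based p-value, its Spearman (rank)
#' analogue, and — when `age` is supplied — partial correlations given
#' age, obtained by residualising both variables on age and correlating
#' the residuals (p from a t-statistic on n - 3 degrees of freedom).
#'
#' @param measure per-subject network measure values.
#' @param score per-subject clinical scores (same length, >= 4 complete
#'   pairs).
#' @param age optional per-subject covariate.
#' @return A data frame with columns `type` (`pearson`, `spearman`,
#'   `pearson_partial`, `spearman_partial`), `R`, `p`, `n`.
#' @export
correlate_with_score <- function(measure, score, age = NULL) {
  keep <- is.finite(measure) & is.finite(score)
  if (!is.null(age)) keep <- keep & is.finite(age)
  x <- measure[keep]; y <- score[keep]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input vector", call. = FALSE)
  pear <- stats::cor.test(x, y)
  spear <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  out <- data.frame(
    type = c("pearson", "spearman"),
    R = c(unname(pear$estimate), unname(spear$estimate)),
    p = c(pear$p.value, spear$p.value),
    n = n, stringsAsFactors = FALSE)
  if (!is.null(age)) {
    z <- age[keep]
    partial <- function(u, v) {
      ru <- stats::residuals(stats::lm(u ~ z))
      rv <- stats::residuals(stats::lm(v ~ z))
      r <- stats::cor(ru, rv)
      tval <- r * sqrt((n - 3) / (1 - r^2))
      c(r, 2 * stats::pt(-abs(tval), df = n - 3))
    }
    pp <- partial(x, y)
    sp <- partial(rank(x), rank(y))
    out <- rbind(out, data.frame(
      type = c("pearson_partial", "spearman_partial"),
      R = c(pp[1], sp[1]), p = c(pp[2], sp[2]), n = n,
      stringsAsFactors = FALSE))
  }
  out
}

#' Relative likelihood from a pair of AICc values
#'
#' `exp((AICc_worse - AICc_better) / 2)`: how many times more probable
#' the better model is to minimise information loss. Depends only on the
#' AICc difference, so additive constants in the likelihood cancel.
#'
#' @param aicc_1,aicc_2 two AICc values.
#' @return Scalar >= 1.
#' @export
relative_likelihood <- function(aicc_1, aicc_2) {
  exp(abs(aicc_1 - aicc_2) / 2)
}

# Small-sample corrected AIC from a least-squares fit:
# n log(RSS/n) + 2k + 2k(k+1)/(n-k-1), with k counting the residual
# variance in addition to the regression coefficients.
aicc_ls <- function(rss, n, n_coef) {
  k <- n_coef + 1
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Compare linear and two-parameter exponential fits by AICc
#'
#' Fits `y ~ a + b x` by ordinary least squares and `y = a exp(b x)` by
#' nonlinear least squares (initialised from a log-linear regression of
#' `ln y` on `x`, with 5 jittered restarts, best residual sum of squares
#' kept) and compares them through the small-sample corrected Akaike
#' criterion. Reported per model: RSS, RMSE (`sqrt(RSS / (n - p))`),
#' adjusted R^2, F against the constant model with its p-value, and
#' AICc; plus the relative likelihood of the better model.
#'
#' @param x predictor (e.g. global efficiency values).
#' @param y response (clinical scores; must be positive for the
#'   exponential fit).
#' @param seed seed for the jittered restarts.
#' @return An object of class `model_comparison`: `models` (data frame
#'   with one row per model), `preferred` (model name with lower AICc),
#'   `relative_likelihood`, and `fits` (the lm / nls objects).
#' @export
fit_and_compare <- function(x, y, seed = 1L) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 5) stop("need at least 5 points", call. = FALSE)
  if (any(y <= 0))
    stop("response must be positive for the exponential model",
         call. = FALSE)
  tss <- sum((y - mean(y))^2)
  lin <- stats::lm(y ~ x)
  rss_lin <- sum(stats::residuals(lin)^2)

  loglin <- stats::lm(log(y) ~ x)
  a0 <- exp(stats::coef(loglin)[1]); b0 <- stats::coef(loglin)[2]
  best <- NULL
  with_seed(seed, {
    for (r in 0:5) {
      st <- if (r == 0) c(a = unname(a0), b = unname(b0))
            else c(a = unname(a0) * exp(stats::rnorm(1, 0, 0.3)),
                   b = unname(b0) * (1 + stats::rnorm(1, 0, 0.3)))
      fit <- tryCatch(
        stats::nls(y ~ a * exp(b * x), start = as.list(st),
                   control = stats::nls.control(maxiter = 200,
                                                warnOnly = TRUE)),
        error = function(e) NULL)
      if (!is.null(fit)) {
        rss <- sum(stats::residuals(fit)^2)
        if (is.null(best) || rss < best$rss)
          best <- list(fit = fit, rss = rss)
      }
    }
  })
  if (is.null(best))
    stop("exponential fit did not converge from any start", call. = FALSE)

  row_for <- function(name, rss, p_coef) {
    dfe <- n - p_coef
    f <- ((tss - rss) / (p_coef - 1)) / (rss / dfe)
    data.frame(model = name, rss = rss, rmse = sqrt(rss / dfe),
               r2_adj = 1 - (rss / dfe) / (tss / (n - 1)),
               F = f, df1 = p_coef - 1, df2 = dfe,
               p = stats::pf(f, p_coef - 1, dfe, lower.tail = FALSE),
               aicc = aicc_ls(rss, n, p_coef), stringsAsFactors = FALSE)
  }
  models <- rbind(row_for("linear", rss_lin, 2),
                  row_for("exponential", best$rss, 2))
  pref <- models$model[which.min(models$aicc)]
  structure(list(models = models, preferred = pref,
                 relative_likelihood = relative_likelihood(models$aicc[1],
                                                           models$aicc[2]),
                 fits = list(linear = lin, exponential = best$fit)),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  print(x$models, row.names = FALSE)
  cat(sprintf("preferred: %s (relative likelihood %.3f)\n",
              x$preferred, x$relative_likelihood))
  invisible(x)
}
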