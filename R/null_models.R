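# Randomised reference networks preserving size, degree sequence and
# weight distribution, used to normalise strength-sensitive global
# measures.

#' Degree- and strength-preserving network randomisation
#'
#' Randomises the topology of a weighted network by repeated
#' degree-preserving double-edge swaps (Maslov-Sneppen rewiring,
#' `rewires_per_edge` attempted swaps per edge), then re-assigns the
#' original weights to the rewired edges by rank-matching node strength:
#' the largest remaining weight is placed on the edge whose endpoints
#' have the largest remaining strength deficit relative to the source
#' network. The degree sequence and the weight multiset are preserved
#' exactly; per-node strengths are preserved approximately.
#'
#' @param c a [connectome] or symmetric nonnegative weight matrix with at
#'   least 2 edges.
#' @param rewires_per_edge attempted swaps per edge (default 10).
#' @param seed integer seed for bit-reproducible output.
#' @return A randomised weight matrix of the same dimension.
#' @export
randomize_network <- function(c, rewires_per_edge = 10, seed = NULL) {
  w <- as_weight_matrix(c)
  g <- weights_to_igraph(w)
  m <- igraph::ecount(g)
  if (m < 2)
    stop("need at least 2 edges to randomise", call. = FALSE)
  wts <- igraph::E(g)$weight
  g2 <- with_seed(seed, {
    igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                             niter = rewires_per_edge * m))
  })
  ends <- igraph::as_edgelist(g2, names = FALSE)
  target <- rowSums(w)          # strengths to approximate
  cur <- numeric(nrow(w))
  ord_w <- sort(wts, decreasing = TRUE)
  remaining <- seq_len(m)
  out <- matrix(0, nrow(w), ncol(w), dimnames = dimnames(w))
  for (k in seq_len(m)) {
    deficit <- (target - cur)[ends[remaining, 1]] +
      (target - cur)[ends[remaining, 2]]
    pick <- remaining[which.max(deficit)]
    i <- ends[pick, 1]; j <- ends[pick, 2]
    out[i, j] <- out[j, i] <- ord_w[k]
    cur[i] <- cur[i] + ord_w[k]
    cur[j] <- cur[j] + ord_w[k]
    remaining <- remaining[remaining != pick]
  }
  out
}

#' Ensemble of randomised reference networks
#'
#' Generates `count` independent realisations of [randomize_network] and
#' records the ensemble means of global efficiency and weighted
#' clustering, the denominators used for measure normalisation.
#'
#' @inheritParams randomize_network
#' @param count ensemble size (default 150).
#' @param denominator clustering denominator, see [weighted_clustering].
#' @param keep_realizations logical; keep the realisation matrices
#'   (default `FALSE`, means only).
#' @return A list with `count`, `measure_means` (named numeric:
#'   `efficiency`, `clustering`), `measure_sds`, and optionally
#'   `realizations`.
#' @export
null_ensemble <- function(c, count = 150, rewires_per_edge = 10,
                          seed = NULL, denominator = "degree",
                          keep_realizations = FALSE) {
  w <- as_weight_matrix(c)
  eff <- numeric(count)
  clu <- numeric(count)
  reals <- if (keep_realizations) vector("list", count) else NULL
  for (r in seq_len(count)) {
    wr <- randomize_network(w, rewires_per_edge, derive_seed(seed, r))
    eff[r] <- global_efficiency(wr)
    clu[r] <- weighted_clustering(wr, denominator)$global
    if (keep_realizations) reals[[r]] <- wr
  }
  out <- list(count = count,
              measure_means = c(efficiency = mean(eff),
                                clustering = mean(clu)),
              measure_sds = c(efficiency = stats::sd(eff),
                              clustering = stats::sd(clu)))
  if (keep_realizations) out$realizations <- reals
  out
}

#' Null-normalised global measure
#'
#' Divides a global measure by its average over an ensemble of degree-
#' and strength-preserving randomised reference networks, removing the
#' confounding effect of overall connectivity strength so that group
#' comparisons reflect topology. Modularity is not strength-confounded
#' and is deliberately not supported here.
#'
#' @inheritParams null_ensemble
#' @param measure `"efficiency"` or `"clustering"`.
#' @param ensemble_size number of realisations (default 150).
#' @return A list with `normalized`, `observed`, `null_mean`, `null_sd`.
#'   `normalized` is `NA` if the ensemble mean is zero.
#' @export
normalize_measure <- function(c, measure = c("efficiency", "clustering"),
                              ensemble_size = 150, rewires_per_edge = 10,
                              seed = NULL, denominator = "degree") {
  measure <- match.arg(measure)
  w <- as_weight_matrix(c)
  obs <- if (measure == "efficiency") global_efficiency(w)
         else weighted_clustering(w, denominator)$global
  ens <- null_ensemble(w, ensemble_size, rewires_per_edge, seed,
                       denominator)
  mu <- unname(ens$measure_means[measure])
  list(normalized = if (mu == 0) NA_real_ else obs / mu,
       observed = obs, null_mean = mu,
       null_sd = unname(ens$measure_sds[measure]))
}
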