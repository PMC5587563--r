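# Weighted graph measures on (thresholded) connectomes.
#
# Edge lengths for path-based measures are reciprocal weights,
# l_e = 1 / w_e, so stronger connections are shorter. Zero weights are
# absent edges.

as_weight_matrix <- function(x) {
  if (inherits(x, "connectome")) x$weights else x
}

weights_to_igraph <- function(w) {
  igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Shortest-path distance matrix
#'
#' All-pairs shortest-path distances with edge length equal to the inverse
#' connection weight. Disconnected pairs have distance `Inf`.
#'
#' @param c a [connectome] or a symmetric nonnegative weight matrix.
#' @return An n x n numeric matrix `d` with `d[s, s] = 0`.
#' @export
shortest_path_distances <- function(c) {
  w <- as_weight_matrix(c)
  g <- weights_to_igraph(w)
  if (igraph::ecount(g) == 0) {
    d <- matrix(Inf, nrow(w), ncol(w))
    diag(d) <- 0
    dimnames(d) <- dimnames(w)
    return(d)
  }
  igraph::distances(g, weights = 1 / igraph::E(g)$weight)
}

#' Global efficiency
#'
#' The average inverse shortest-path distance over all ordered pairs of
#' distinct nodes, `sum(1/d(s,t)) / (n(n-1))`, with disconnected pairs
#' contributing zero. A measure of network integration; equals 1 on a
#' complete unit-weight graph and 0 on an edgeless one.
#'
#' @param c a [connectome] or symmetric nonnegative weight matrix with at
#'   least 2 nodes.
#' @return Scalar efficiency value.
#' @export
global_efficiency <- function(c) {
  w <- as_weight_matrix(c)
  n <- nrow(w)
  if (n < 2) stop("global efficiency needs at least 2 nodes", call. = FALSE)
  d <- shortest_path_distances(w)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Weighted clustering coefficient
#'
#' Geometric-mean triangle closure around each node:
#' `C_v = sum_{x,y} (w_vx w_vy w_xy)^(1/3) / (k_v (k_v - 1))`, summing
#' over ordered pairs of other nodes, after rescaling all weights by the
#' global maximum so each geometric-mean term lies in \[0, 1\]. The global
#' coefficient is the mean of `C_v` over nodes.
#'
#' Two denominator conventions are provided for `k_v`: the node degree
#' (the standard convention of weighted-network toolboxes, guaranteeing
#' `C_v <= 1`; the default) or the node strength `sum_x w_vx` ("as
#' printed" in the defining formula). Nodes with `k_v (k_v - 1) <= 0` get
#' `C_v = 0`.
#'
#' @param c a [connectome] or symmetric nonnegative weight matrix.
#' @param denominator `"degree"` or `"strength_as_printed"`.
#' @return A list with `global` (mean over nodes) and `local` (per-node
#'   vector).
#' @export
weighted_clustering <- function(c, denominator = c("degree",
                                                   "strength_as_printed")) {
  denominator <- match.arg(denominator)
  w <- as_weight_matrix(c)
  n <- nrow(w)
  mx <- max(w)
  if (mx > 0) w <- w / mx
  w3 <- w^(1 / 3)
  # numerator_v = sum over ordered (x, y) of (w_vx w_vy w_xy)^(1/3)
  num <- diag(w3 %*% w3 %*% w3)
  k <- if (denominator == "degree") rowSums(w > 0) else rowSums(w)
  den <- k * (k - 1)
  cv <- ifelse(den > 0, num / den, 0)
  names(cv) <- rownames(w)
  list(global = mean(cv), local = cv)
}

#' Weighted modularity via seeded multilevel community detection
#'
#' Runs the greedy multilevel (Louvain) community-agglomeration optimiser
#' `repeats` times under seeded randomness and returns the best weighted
#' modularity found together with its partition. Modularity quantifies
#' how much more within-community weight the partition captures than
#' expected from the strength sequence; it is invariant to global weight
#' rescaling and is therefore never null-normalised.
#'
#' @param c a [connectome] or symmetric nonnegative weight matrix with at
#'   least one edge.
#' @param gamma resolution parameter (default 1).
#' @param repeats number of optimiser restarts (default 10).
#' @param seed integer seed; restarts use derived seeds.
#' @return A list with `Q` (best modularity) and `membership` (integer
#'   community labels of the best partition).
#' @export
modularity_q <- function(c, gamma = 1, repeats = 10, seed = 1L) {
  w <- as_weight_matrix(c)
  g <- weights_to_igraph(w)
  if (igraph::ecount(g) == 0)
    stop("modularity needs at least one edge", call. = FALSE)
  best <- NULL
  for (r in seq_len(repeats)) {
    cl <- with_seed(derive_seed(seed, r), {
      igraph::cluster_louvain(g, weights = igraph::E(g)$weight,
                              resolution = gamma)
    })
    q <- igraph::modularity(g, igraph::membership(cl),
                            weights = igraph::E(g)$weight)
    if (is.null(best) || q > best$Q)
      best <- list(Q = q, membership = as.integer(igraph::membership(cl)))
  }
  best
}

#' Local efficiency of every node
#'
#' The global efficiency of the weight submatrix induced by a node
#' together with its neighbours. By default the node itself is part of
#' the subgraph ("induced by the node and its neighbours");
#' `include_self = FALSE` gives the more common neighbour-only
#' convention. Nodes with fewer than 2 neighbours get 0.
#'
#' @param c a [connectome] or symmetric nonnegative weight matrix.
#' @param include_self logical, keep the centre node in the subgraph
#'   (default `TRUE`).
#' @return Numeric per-node vector.
#' @export
local_efficiency <- function(c, include_self = TRUE) {
  w <- as_weight_matrix(c)
  n <- nrow(w)
  out <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(w[v, ] > 0)
    if (length(nb) < 2) next
    keep <- if (include_self) c(v, nb) else nb
    out[v] <- global_efficiency(w[keep, keep, drop = FALSE])
  }
  names(out) <- rownames(w)
  out
}

#' Nodal measures: strength, local clustering, local efficiency
#'
#' @param c a [connectome] or symmetric nonnegative weight matrix.
#' @param denominator clustering denominator, see [weighted_clustering].
#' @param include_self local-efficiency subgraph convention, see
#'   [local_efficiency].
#' @return A data frame with columns `region`, `strength`,
#'   `local_clustering`, `local_efficiency`.
#' @export
nodal_measures <- function(c, denominator = "degree", include_self = TRUE) {
  w <- as_weight_matrix(c)
  labs <- rownames(w)
  if (is.null(labs)) labs <- as.character(seq_len(nrow(w)))
  data.frame(
    region = labs,
    strength = unname(rowSums(w)),
    local_clustering = unname(weighted_clustering(w, denominator)$local),
    local_efficiency = unname(local_efficiency(w, include_self)),
    stringsAsFactors = FALSE)
}

#' Global measures of a connectome
#'
#' Convenience wrapper returning global efficiency, global weighted
#' clustering and modularity in one list.
#'
#' @inheritParams nodal_measures
#' @param repeats,seed passed to [modularity_q].
#' @return A list with `efficiency`, `clustering`, `modularity`.
#' @export
global_measures <- function(c, denominator = "degree", repeats = 10,
                            seed = 1L) {
  w <- as_weight_matrix(c)
  list(efficiency = global_efficiency(w),
       clustering = weighted_clustering(w, denominator)$global,
       modularity = modularity_q(w, repeats = repeats, seed = seed)$Q)
}
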