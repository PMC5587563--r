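#' Weighted connectome objects
#'
#' A connectome is a symmetric, nonnegative, zero-diagonal weighted
#' adjacency matrix over the regions of a [parcellation], with weights
#' interpreted as volume-normalised streamline densities.
#'
#' @param weights n x n numeric matrix, symmetric, nonnegative, zero
#'   diagonal.
#' @param parcellation a [parcellation] with n rows.
#' @param subject_id identifier string.
#' @return An object of class `connectome` with elements `weights`,
#'   `parcellation`, `subject_id`.
#' @export
connectome <- function(weights, parcellation, subject_id = NA_character_) {
  stopifnot_square(weights, "weights")
  if (nrow(weights) != nrow(parcellation))
    stop("weights dimension does not match parcellation size", call. = FALSE)
  if (any(weights < 0)) stop("weights must be nonnegative", call. = FALSE)
  check_symmetric(weights, what = "weights")
  diag(weights) <- 0
  dimnames(weights) <- list(parcellation$label, parcellation$label)
  structure(list(weights = weights, parcellation = parcellation,
                 subject_id = subject_id),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  n <- nrow(x$weights)
  nz <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf("connectome '%s': %d regions, %d nonzero edges (density %.3f)\n",
              x$subject_id, n, nz, nz / (n * (n - 1) / 2)))
  invisible(x)
}

#' Build a connectome from raw streamline counts
#'
#' Normalises each directed count by the product of the seed and target
#' region volumes, then symmetrises by averaging the two directed
#' normalised entries and zeroes the diagonal.
#'
#' @param raw_counts n x n nonnegative matrix of streamline counts;
#'   `raw_counts[s, t]` counts streamlines seeded in region s that reach
#'   region t.
#' @param parcellation a [parcellation] with n rows supplying region
#'   volumes.
#' @param subject_id identifier carried on the result.
#' @return A [connectome] with
#'   `weights[s, t] = (raw[s, t] + raw[t, s]) / (2 * vol_s * vol_t)`.
#' @export
#' @examples
#' p <- parcellation(c("a", "b"), c("left", "right"), c(2, 2))
#' raw <- matrix(c(0, 10, 30, 0), 2, 2, byrow = TRUE)
#' build_connectome(raw, p)$weights[1, 2]  # (10/4 + 30/4)/2 = 5
build_connectome <- function(raw_counts, parcellation,
                             subject_id = NA_character_) {
  stopifnot_square(raw_counts, "raw_counts")
  if (nrow(raw_counts) != nrow(parcellation))
    stop("raw_counts dimension does not match parcellation size",
         call. = FALSE)
  if (any(raw_counts < 0))
    stop("streamline counts must be nonnegative", call. = FALSE)
  vol <- parcellation$volume
  norm <- raw_counts / outer(vol, vol)
  w <- (norm + t(norm)) / 2
  diag(w) <- 0
  connectome(w, parcellation, subject_id)
}

#' Extract a hemisphere subnetwork or the interhemispheric block
#'
#' For `side = "left"` or `"right"` returns the induced 36-region (in the
#' default scheme) connectome on that hemisphere. For
#' `side = "interhemispheric"` returns the left x right cross-block of
#' weights as a plain matrix; the cross-block is a bipartite weight table
#' meant for connectivity-strength summaries, not for graph measures.
#'
#' @param c a [connectome].
#' @param side `"left"`, `"right"` or `"interhemispheric"`.
#' @return A [connectome] (left/right) or a numeric matrix
#'   (interhemispheric).
#' @export
extract_hemisphere <- function(c, side = c("left", "right",
                                           "interhemispheric")) {
  side <- match.arg(side)
  hemi <- c$parcellation$hemisphere
  if (side == "interhemispheric") {
    return(c$weights[hemi == "left", hemi == "right", drop = FALSE])
  }
  keep <- hemi == side
  sub <- c$parcellation[keep, , drop = FALSE]
  class(sub) <- c("parcellation", "data.frame")
  connectome(c$weights[keep, keep, drop = FALSE], sub, c$subject_id)
}

#' Elementwise median summary matrix of a cohort
#'
#' Computes the matrix whose entries are the elementwise medians of the
#' subjects' connectivity weights, pooling all subjects (both groups).
#' This pooled summary defines the density-threshold masks applied
#' identically to both groups, so that thresholding itself cannot inflate
#' a group difference.
#'
#' @param cohort a list of [connectome]s over identical parcellations.
#' @return An n x n symmetric, zero-diagonal numeric matrix.
#' @export
median_summary <- function(cohort) {
  if (length(cohort) < 1) stop("need at least one connectome", call. = FALSE)
  labs <- cohort[[1]]$parcellation$label
  for (ci in cohort) {
    if (!identical(ci$parcellation$label, labs))
      stop("all connectomes must share one parcellation", call. = FALSE)
  }
  arr <- vapply(cohort, function(ci) ci$weights,
                matrix(0, length(labs), length(labs)))
  m <- apply(arr, c(1, 2), stats::median)
  dimnames(m) <- list(labs, labs)
  m
}

#' Density-threshold mask from a summary matrix
#'
#' Ranks all n(n-1)/2 distinct region pairs of a symmetric summary matrix
#' by descending weight (structural zeros included, ranked last; ties
#' broken by ascending row then column index so the mask is reproducible)
#' and retains the strongest `round_half_up(kappa * n(n-1)/2)` pairs. By
#' construction `kappa` is the edge density of the masked network. For the
#' 72-region scheme this gives 128 edges at kappa = 0.05 and 2428 at
#' kappa = 0.95; for a 36-region hemisphere, 32 and 599.
#'
#' @param summary n x n symmetric numeric matrix (typically from
#'   [median_summary]).
#' @param kappa edge density in (0, 1].
#' @return An object of class `threshold_mask` with elements `kappa`,
#'   `mask` (logical n x n, symmetric, FALSE diagonal) and `edge_count`.
#' @export
density_threshold <- function(summary, kappa) {
  stopifnot_square(summary, "summary")
  check_symmetric(summary, what = "summary")
  if (!is.numeric(kappa) || length(kappa) != 1 || kappa <= 0 || kappa > 1)
    stop("kappa must lie in (0, 1]", call. = FALSE)
  n <- nrow(summary)
  pairs <- upper_pairs(n)
  vals <- summary[pairs]
  keep_n <- round_half_up(kappa * n * (n - 1) / 2)
  ord <- order(-vals, pairs[, 1], pairs[, 2])
  sel <- ord[seq_len(keep_n)]
  mask <- matrix(FALSE, n, n)
  mask[pairs[sel, , drop = FALSE]] <- TRUE
  mask <- mask | t(mask)
  dimnames(mask) <- dimnames(summary)
  structure(list(kappa = kappa, mask = mask, edge_count = keep_n),
            class = "threshold_mask")
}

#' @export
print.threshold_mask <- function(x, ...) {
  cat(sprintf("threshold_mask: kappa = %.3f, %d edges over %d regions\n",
              x$kappa, x$edge_count, nrow(x$mask)))
  invisible(x)
}

#' Apply a threshold mask to a connectome
#'
#' Zeroes weights outside the mask; weights inside the mask are kept
#' unchanged (no binarisation).
#'
#' @param c a [connectome].
#' @param m a `threshold_mask` of matching dimension.
#' @return A [connectome] with masked weights.
#' @export
apply_mask <- function(c, m) {
  if (!inherits(m, "threshold_mask")) stop("m must be a threshold_mask",
                                           call. = FALSE)
  if (nrow(m$mask) != nrow(c$weights))
    stop("mask dimension does not match connectome", call. = FALSE)
  w <- c$weights
  w[!m$mask] <- 0
  connectome(w, c$parcellation, c$subject_id)
}

#' Read a connectivity matrix from delimited text
#'
#' Reads n header-less rows of n delimited floats.
#'
#' @param path file path.
#' @param sep field separator (default `","`).
#' @return A numeric matrix.
#' @export
read_matrix <- function(path, sep = ",") {
  m <- as.matrix(utils::read.table(path, sep = sep, header = FALSE))
  dimnames(m) <- NULL
  storage.mode(m) <- "double"
  m
}

#' Write a connectivity matrix as delimited text
#' @param m numeric matrix (or a [connectome], whose weights are written).
#' @param path file path.
#' @param sep field separator (default `","`).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, sep = ",") {
  if (inherits(m, "connectome")) m <- m$weights
  utils::write.table(m, path, sep = sep, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a cohort of connectivity matrices
#'
#' Accepts either one file per subject (a named character vector of paths)
#' or a single stacked file whose first column is a subject index followed
#' by n columns, n rows per subject.
#'
#' @param paths character vector of per-subject matrix files (names used
#'   as subject ids), or a single stacked file.
#' @param parcellation a [parcellation].
#' @param stacked logical; `TRUE` if `paths` is one stacked file.
#' @param sep field separator.
#' @return A list of [connectome]s.
#' @export
read_cohort_matrices <- function(paths, parcellation, stacked = FALSE,
                                 sep = ",") {
  n <- nrow(parcellation)
  if (stacked) {
    d <- utils::read.table(paths, sep = sep, header = FALSE)
    ids <- unique(d[[1]])
    return(lapply(ids, function(id) {
      w <- as.matrix(d[d[[1]] == id, -1, drop = FALSE])
      dimnames(w) <- NULL
      if (nrow(w) != n) stop("stacked block has wrong row count",
                             call. = FALSE)
      connectome(w, parcellation, as.character(id))
    }))
  }
  ids <- if (is.null(names(paths))) basename(paths) else names(paths)
  Map(function(p, id) connectome(read_matrix(p, sep), parcellation, id),
      paths, ids, USE.NAMES = FALSE)
}
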