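#' Construct a proximity graph
#'
#' A proximity graph is an undirected weighted graph on brain regions whose
#' edge weights are proximities in \[0, 1\] — here, non-negative Pearson
#' correlations of wavelet coefficients. A weight of exactly 0 means "edge
#' absent". The diagonal is ignored (self-proximity never enters any
#' computation) and is stored as 0.
#'
#' @param weights symmetric numeric matrix with entries in \[0, 1\].
#' @param node_ids character vector of region identifiers; defaults to the
#'   matrix dimnames, or `V1..Vn`.
#' @return an object of class `proximity_graph` with fields `weights`
#'   (symmetric n x n matrix, zero diagonal), `node_ids` and `n_nodes`.
#' @seealso [proximity_to_distance()], [metric_closure()]
#' @export
#' @examples
#' w <- matrix(c(0, .8, .2, .8, 0, .8, .2, .8, 0), 3, 3)
#' proximity_graph(w, node_ids = c("A", "B", "C"))
proximity_graph <- function(weights, node_ids = NULL) {
  weights <- as.matrix(weights)
  node_ids <- resolve_node_ids(weights, node_ids)
  check_square_symmetric(weights, node_ids, what = "proximity")
  bad <- which((weights < 0 | weights > 1) & !diag_mask(nrow(weights)),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- min(bad[1, ]); j <- max(bad[1, ])
    stop(sprintf(
      "proximity w[%s, %s] = %g is outside [0, 1]",
      node_ids[i], node_ids[j], weights[i, j]), call. = FALSE)
  }
  diag(weights) <- 0
  dimnames(weights) <- list(node_ids, node_ids)
  structure(
    list(weights = weights, node_ids = node_ids, n_nodes = nrow(weights)),
    class = "proximity_graph")
}

#' Construct a distance graph
#'
#' The distance-space counterpart of a [proximity_graph()]. Distances are
#' non-negative; an absent edge is represented by the explicit sentinel
#' `Inf`, never a large finite value, so no spurious shortest path can run
#' through a "very large" stand-in.
#'
#' @param distances symmetric numeric matrix, entries `>= 0` or `Inf`.
#' @param node_ids character vector of region identifiers.
#' @return an object of class `distance_graph`.
#' @export
distance_graph <- function(distances, node_ids = NULL) {
  distances <- as.matrix(distances)
  node_ids <- resolve_node_ids(distances, node_ids)
  check_square_symmetric(distances, node_ids, what = "distance")
  bad <- which((distances < 0 | is.na(distances)) & !diag_mask(nrow(distances)),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- min(bad[1, ]); j <- max(bad[1, ])
    stop(sprintf("distance d[%s, %s] = %g is negative or missing",
                 node_ids[i], node_ids[j], distances[i, j]), call. = FALSE)
  }
  diag(distances) <- 0
  dimnames(distances) <- list(node_ids, node_ids)
  structure(
    list(distances = distances, node_ids = node_ids,
         n_nodes = nrow(distances)),
    class = "distance_graph")
}

#' Map proximities to distances
#'
#' Applies the isomorphism `d_ij = 1/w_ij - 1` edgewise: full proximity
#' (w = 1) maps to zero distance, and an absent edge (w = 0) maps to
#' infinite distance, so excluded (e.g. negative-correlation) pairs can
#' never participate in a shortest path.
#'
#' @param p a [proximity_graph()].
#' @return a [distance_graph()] on the same nodes.
#' @export
#' @examples
#' p <- proximity_graph(matrix(c(0, .5, .5, 0), 2, 2))
#' proximity_to_distance(p)$distances[1, 2]  # 1/0.5 - 1 = 1
proximity_to_distance <- function(p) {
  stopifnot(inherits(p, "proximity_graph"))
  w <- p$weights
  d <- ifelse(w > 0, 1 / w - 1, Inf)
  diag(d) <- 0
  distance_graph(d, node_ids = p$node_ids)
}

#' Map distances back to proximities
#'
#' Inverse of [proximity_to_distance()]: `w_ij = 1/(d_ij + 1)`, with
#' infinite distance mapping to proximity 0. The round trip through both
#' maps is the identity to within numerical tolerance.
#'
#' @param d a [distance_graph()].
#' @return a [proximity_graph()] on the same nodes.
#' @export
distance_to_proximity <- function(d) {
  stopifnot(inherits(d, "distance_graph"))
  dd <- d$distances
  w <- ifelse(is.infinite(dd), 0, 1 / (dd + 1))
  diag(w) <- 0
  proximity_graph(w, node_ids = d$node_ids)
}

#' @export
print.proximity_graph <- function(x, ...) {
  ut <- upper_tri_values(x$weights)
  cat(sprintf("proximity_graph: %d nodes, %d present edges (of %d pairs)\n",
              x$n_nodes, sum(ut > 0), length(ut)))
  invisible(x)
}

#' @export
print.distance_graph <- function(x, ...) {
  ut <- upper_tri_values(x$distances)
  cat(sprintf("distance_graph: %d nodes, %d finite edges (of %d pairs)\n",
              x$n_nodes, sum(is.finite(ut)), length(ut)))
  invisible(x)
}

# ---- internal helpers -------------------------------------------------------

resolve_node_ids <- function(m, node_ids) {
  if (is.null(node_ids)) {
    node_ids <- rownames(m)
    if (is.null(node_ids)) node_ids <- paste0("V", seq_len(nrow(m)))
  }
  node_ids <- as.character(node_ids)
  if (length(node_ids) != nrow(m))
    stop("node_ids length does not match matrix dimension", call. = FALSE)
  if (anyDuplicated(node_ids))
    stop("node_ids must be unique", call. = FALSE)
  node_ids
}

check_square_symmetric <- function(m, node_ids, what, tol = 1e-8) {
  if (nrow(m) != ncol(m))
    stop(sprintf("%s matrix must be square", what), call. = FALSE)
  if (!is.numeric(m))
    stop(sprintf("%s matrix must be numeric", what), call. = FALSE)
  fin <- is.finite(m) & is.finite(t(m))
  asym <- abs(m - t(m))
  asym[!fin] <- ifelse(is.infinite(m[!fin]) & is.infinite(t(m)[!fin]), 0, Inf)
  worst <- max(asym, 0)
  if (worst > tol)
    stop(sprintf("%s matrix is asymmetric (max |m - t(m)| = %g)", what, worst),
         call. = FALSE)
}

diag_mask <- function(n) diag(TRUE, n)

upper_tri_values <- function(m) m[upper.tri(m)]

# unordered upper-triangle index pairs (i < j) for an n-node graph
all_pairs <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  colnames(idx) <- c("i", "j")
  idx
}
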