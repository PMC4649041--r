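#' Metric closure of a distance graph
#'
#' Replaces every pairwise distance by the shortest-path distance over the
#' whole graph (all-pairs shortest paths, Johnson's algorithm), then labels
#' each node pair:
#' \describe{
#'   \item{metric}{the direct edge already equals its shortest-path
#'     distance (within tolerance);}
#'   \item{semi-metric}{some indirect path is strictly shorter than the
#'     direct edge — a triangle-inequality (transitivity) violation;}
#'   \item{absent}{no direct edge (proximity 0, infinite distance).}
#' }
#' For each finite direct edge the *distortion* `s_ij = d_ij / D_ij`
#' (direct over closed distance) is recorded; it is exactly 1 for metric
#' edges and `> 1` for semi-metric edges.
#'
#' @param d a [distance_graph()] (or a [proximity_graph()], converted
#'   internally).
#' @param tol relative tie tolerance: an edge is semi-metric iff
#'   `D_ij < d_ij * (1 - tol)`. Default `1e-9`.
#' @return an object of class `closure_result` with fields
#'   `closed_distances` (n x n shortest-path distances; `Inf` between
#'   mutually unreachable nodes), `direct_distances`, `edge_labels`
#'   (character matrix, `NA` diagonal), `distortion` (numeric matrix, `NA`
#'   where absent), `node_ids`, `n_nodes`, `tol`.
#' @references Johnson, D. B. (1977). Efficient algorithms for shortest
#'   paths in sparse networks. Journal of the ACM 24(1), 1-13.
#' @export
#' @examples
#' w <- matrix(0, 3, 3); w[1, 2] <- w[2, 1] <- w[2, 3] <- w[3, 2] <- 0.8
#' w[1, 3] <- w[3, 1] <- 0.2
#' cl <- metric_closure(proximity_to_distance(proximity_graph(w)))
#' cl$edge_labels[1, 3]   # "semi-metric": 0.25 + 0.25 < 4
#' cl$distortion[1, 3]    # 8
metric_closure <- function(d, tol = 1e-9) {
  d <- as_distance_graph(d)
  n <- d$n_nodes
  dd <- d$distances
  idx <- which(is.finite(dd) & upper.tri(dd), arr.ind = TRUE)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(idx) > 0) g <- igraph::add_edges(g, t(idx))
  closed <- igraph::distances(g, weights = dd[idx], algorithm = "johnson")
  dimnames(closed) <- dimnames(dd)
  new_closure_result(direct = dd, closed = closed, node_ids = d$node_ids,
                     tol = tol)
}

#' Brute-force metric closure (test oracle)
#'
#' Same contract as [metric_closure()], computed by the cubic
#' Floyd-Warshall dynamic-programming recurrence instead of Johnson's
#' algorithm. Intended as an independent oracle for testing; practical up
#' to a few hundred nodes.
#'
#' @inheritParams metric_closure
#' @return a `closure_result`; see [metric_closure()].
#' @export
brute_force_closure <- function(d, tol = 1e-9) {
  d <- as_distance_graph(d)
  n <- d$n_nodes
  if (n > 200)
    stop("brute_force_closure is an oracle for graphs of at most 200 nodes",
         call. = FALSE)
  A <- d$distances
  diag(A) <- 0
  for (k in seq_len(n)) {
    via_k <- outer(A[, k], A[k, ], `+`)   # Inf-safe: Inf + x = Inf
    A <- pmin(A, via_k)
  }
  dimnames(A) <- dimnames(d$distances)
  new_closure_result(direct = d$distances, closed = A,
                     node_ids = d$node_ids, tol = tol)
}

#' Semi-metric percentage (SMP)
#'
#' The fraction of present edges labelled semi-metric: the number of
#' semi-metric node pairs in `subset` divided by the number of pairs in
#' `subset` with a finite direct edge. Absent edges are excluded from both
#' numerator and denominator; self-pairs never count.
#'
#' @param cl a `closure_result` from [metric_closure()] or
#'   [brute_force_closure()].
#' @param subset `"all"` (default; every unordered node pair), or a
#'   two-column matrix of node pairs given as integer indices or node ids.
#' @return a single number in \[0, 1\].
#' @section Undefined SMP: if the subset contains no finite direct edge the
#'   SMP is undefined (not 0) and a classed error
#'   (`semimetric_undefined_smp`) is signalled; see [smp_or_na()] for the
#'   `NA`-returning variant used when profiling many subsets.
#' @export
smp <- function(cl, subset = "all") {
  stopifnot(inherits(cl, "closure_result"))
  idx <- resolve_pair_subset(cl, subset)
  labs <- cl$edge_labels[idx]
  present <- labs != "absent"
  if (!any(present)) {
    stop(structure(
      class = c("semimetric_undefined_smp", "error", "condition"),
      list(message = "SMP undefined: subset contains no finite direct edge",
           call = NULL)))
  }
  sum(labs[present] == "semi-metric") / sum(present)
}

#' SMP, returning NA where undefined
#'
#' Wrapper around [smp()] that maps the undefined-SMP condition to
#' `NA_real_`, convenient when evaluating many region subsets.
#'
#' @inheritParams smp
#' @return a number in \[0, 1\], or `NA_real_` if the subset has no finite
#'   direct edge.
#' @export
smp_or_na <- function(cl, subset = "all") {
  tryCatch(smp(cl, subset),
           semimetric_undefined_smp = function(e) NA_real_)
}

#' @export
print.closure_result <- function(x, ...) {
  ut <- x$edge_labels[upper.tri(x$edge_labels)]
  cat(sprintf(
    "closure_result: %d nodes; %d metric, %d semi-metric, %d absent pairs\n",
    x$n_nodes, sum(ut == "metric"), sum(ut == "semi-metric"),
    sum(ut == "absent")))
  if (any(ut != "absent"))
    cat(sprintf("  whole-graph SMP = %.4f\n", smp(x)))
  invisible(x)
}

# ---- internal ---------------------------------------------------------------

as_distance_graph <- function(x) {
  if (inherits(x, "proximity_graph")) return(proximity_to_distance(x))
  if (!inherits(x, "distance_graph"))
    stop("expected a distance_graph or proximity_graph", call. = FALSE)
  x
}

# shared labelling: the tie rule lives here and only here
new_closure_result <- function(direct, closed, node_ids, tol) {
  n <- nrow(direct)
  labels <- matrix("absent", n, n, dimnames = dimnames(direct))
  distortion <- matrix(NA_real_, n, n, dimnames = dimnames(direct))
  fin <- is.finite(direct) & !diag_mask(n)
  semi <- fin & (closed < direct * (1 - tol))
  met <- fin & !semi
  labels[met] <- "metric"
  labels[semi] <- "semi-metric"
  # a metric edge's closed distance IS its direct distance: snapping
  # removes sub-tolerance float noise and makes the closure idempotent
  closed[met] <- direct[met]
  distortion[met] <- 1
  distortion[semi] <- direct[semi] / closed[semi]
  diag(labels) <- NA_character_
  structure(
    list(closed_distances = closed, direct_distances = direct,
         edge_labels = labels, distortion = distortion,
         node_ids = node_ids, n_nodes = n, tol = tol),
    class = "closure_result")
}

# subset -> logical-safe linear index matrix usable on n x n matrices
resolve_pair_subset <- function(cl, subset) {
  n <- cl$n_nodes
  if (identical(subset, "all")) return(all_pairs(n))
  subset <- as.matrix(subset)
  if (ncol(subset) != 2)
    stop("subset must be a two-column matrix of node pairs", call. = FALSE)
  if (is.character(subset)) {
    m <- match(subset, cl$node_ids)
    if (anyNA(m))
      stop(sprintf("unknown node id(s): %s",
                   paste(unique(subset[is.na(m)]), collapse = ", ")),
           call. = FALSE)
    subset <- matrix(m, ncol = 2)
  }
  subset <- matrix(as.integer(subset), ncol = 2)
  if (any(subset < 1 | subset > n))
    stop("subset contains node indices out of range", call. = FALSE)
  if (any(subset[, 1] == subset[, 2]))
    stop("subset contains self-pairs", call. = FALSE)
  subset
}
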