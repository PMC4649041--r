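#' Region-averaged BOLD time-series set
#'
#' Container for region-averaged BOLD signals: one row per parcellation
#' region, one column per acquired volume.
#'
#' @param series numeric matrix, n_regions x n_timepoints, no missing
#'   values.
#' @param tr_seconds repetition time in seconds (time between volumes).
#' @param node_ids region identifiers aligned to a parcellation; defaults
#'   to rownames.
#' @return an object of class `region_timeseries`.
#' @export
region_timeseries <- function(series, tr_seconds, node_ids = NULL) {
  series <- as.matrix(series)
  if (!is.numeric(series) || anyNA(series))
    stop("series must be a numeric matrix without missing values",
         call. = FALSE)
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1 || tr_seconds <= 0)
    stop("tr_seconds must be a single positive number", call. = FALSE)
  if (is.null(node_ids)) node_ids <- rownames(series)
  if (is.null(node_ids)) node_ids <- paste0("R", seq_len(nrow(series)))
  node_ids <- as.character(node_ids)
  if (length(node_ids) != nrow(series) || anyDuplicated(node_ids))
    stop("node_ids must be unique and match the number of regions",
         call. = FALSE)
  rownames(series) <- node_ids
  structure(
    list(series = series, tr_seconds = tr_seconds, node_ids = node_ids,
         n_regions = nrow(series), n_timepoints = ncol(series)),
    class = "region_timeseries")
}

#' Pearson correlation adjacency of wavelet coefficients
#'
#' The proximity between two regions is the Pearson correlation of their
#' wavelet coefficients at the chosen scale.
#'
#' @param wc a `wavelet_coefficients` element of a
#'   [wavelet_band_decompose()] result (or any object with a numeric
#'   `coeffs` matrix, regions as rows).
#' @return symmetric correlation matrix with unit diagonal, entries in
#'   \[-1, 1\].
#' @export
correlation_adjacency <- function(wc) {
  coeffs <- if (is.matrix(wc)) wc else wc$coeffs
  if (ncol(coeffs) < 3)
    stop("need at least 3 coefficients per region", call. = FALSE)
  v <- apply(coeffs, 1, var)
  if (any(v == 0)) {
    bad <- rownames(coeffs)[which(v == 0)]
    if (is.null(bad)) bad <- which(v == 0)
    stop(sprintf("zero-variance region(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  r <- cor(t(coeffs))
  r <- (r + t(r)) / 2
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 1
  r
}

#' Truncate a correlation matrix to a non-negative proximity graph
#'
#' Builds the adjacency from only the non-negative correlations: negative
#' correlations (anti-phase signals) are a different kind of relation and
#' are excluded — their edges become absent, i.e. infinitely distant after
#' the distance isomorphism.
#'
#' @param corr symmetric correlation matrix (unit diagonal).
#' @param node_ids optional region ids (default: dimnames of `corr`).
#' @return a list with `graph` (a [proximity_graph()] whose weights are
#'   `max(corr, 0)` off-diagonal) and `n_negative` (number of strictly
#'   negative unordered off-diagonal pairs).
#' @export
nonnegative_proximity <- function(corr, node_ids = NULL) {
  corr <- as.matrix(corr)
  node_ids <- resolve_node_ids(corr, node_ids)
  check_square_symmetric(corr, node_ids, what = "correlation")
  ut <- corr[upper.tri(corr)]
  n_negative <- sum(ut < 0)
  w <- pmax(corr, 0)
  diag(w) <- 0
  list(graph = proximity_graph(w, node_ids = node_ids),
       n_negative = n_negative)
}

#' Time series to proximity graph
#'
#' Convenience composition of the connectivity stage:
#' [wavelet_band_decompose()] at `scale`, [correlation_adjacency()], then
#' [nonnegative_proximity()].
#'
#' @param ts a [region_timeseries()].
#' @param scale analysis wavelet scale (default 2, the band in which BOLD
#'   correlations are conventionally examined).
#' @param n_scales decomposition depth (default `max(scale, 4)` capped at
#'   the series-length limit).
#' @return a list: `graph` ([proximity_graph()]), `correlation` (the full
#'   signed matrix, kept for distribution summaries), `n_negative`,
#'   `band_hz`.
#' @export
timeseries_to_proximity <- function(ts, scale = 2, n_scales = NULL) {
  if (is.null(n_scales))
    n_scales <- min(max(scale, 4), floor(log2(ts$n_timepoints)) - 2)
  if (scale > n_scales) n_scales <- scale
  wd <- wavelet_band_decompose(ts, n_scales = n_scales)
  corr <- correlation_adjacency(wd$scales[[scale]])
  np <- nonnegative_proximity(corr, node_ids = ts$node_ids)
  list(graph = np$graph, correlation = corr, n_negative = np$n_negative,
       band_hz = wd$scales[[scale]]$band_hz)
}
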