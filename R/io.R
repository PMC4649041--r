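# Matrix / table I/O. All tabular outputs are tab-delimited text with
# '#'-prefixed metadata lines; infinite distance is serialized as the
# literal token "inf"; numbers are written with 17 significant digits so
# write -> read round-trips are bit-faithful.

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (is.infinite(v)) return(if (v > 0) "inf" else "-inf")
    sprintf("%.17g", v)
  }, "")
  out
}

parse_num <- function(s) {
  s <- trimws(s)
  out <- suppressWarnings(as.numeric(s))
  out[s %in% c("inf", "Inf", "INF")] <- Inf
  out[s %in% c("-inf", "-Inf")] <- -Inf
  out[s %in% c("NA", "nan", "NaN")] <- NA_real_
  bad <- is.na(out) & !(s %in% c("NA", "nan", "NaN"))
  if (any(bad))
    stop(sprintf("non-numeric cell(s): %s",
                 paste(head(unique(s[bad]), 3), collapse = ", ")),
         call. = FALSE)
  out
}

write_lines <- function(lines, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Write / read a square matrix in the package's matrix dialect
#'
#' Tab-delimited square tables: optional `#`-prefixed metadata lines, a
#' header row of node ids (first cell `id`), then one row per node with
#' the node id in the first column. `Inf` is written as the token `inf`,
#' so absent edges survive the round trip; numbers carry 17 significant
#' digits.
#'
#' @param x a [proximity_graph()], [distance_graph()] or plain numeric
#'   matrix with dimnames.
#' @param path file path.
#' @param comments character vector of metadata lines (written with a
#'   leading `# `).
#' @return `write_matrix`: `path`, invisibly. `read_matrix`: a
#'   [proximity_graph()], [distance_graph()] or plain matrix according to
#'   `as`.
#' @export
write_matrix <- function(x, path, comments = character()) {
  m <- if (inherits(x, "proximity_graph")) x$weights
  else if (inherits(x, "distance_graph")) x$distances
  else as.matrix(x)
  ids <- rownames(m)
  if (is.null(ids)) ids <- paste0("V", seq_len(nrow(m)))
  body <- vapply(seq_len(nrow(m)), function(i)
    paste(c(ids[i], fmt_num(m[i, ])), collapse = "\t"), "")
  lines <- c(if (length(comments)) paste("#", comments),
             paste(c("id", ids), collapse = "\t"), body)
  write_lines(lines, path)
}

#' @rdname write_matrix
#' @param as what to return: `"auto"` (distance graph if any entry is
#'   infinite or exceeds 1, else proximity graph), `"proximity"`,
#'   `"distance"` or `"matrix"`.
#' @param tol symmetry tolerance.
#' @export
read_matrix <- function(path, as = c("auto", "proximity", "distance",
                                     "matrix"), tol = 1e-8) {
  as <- match.arg(as)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) < 2) stop("matrix file has no body", call. = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  ids <- header[-1]
  n <- length(ids)
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  if (length(rows) != n)
    stop(sprintf("matrix file is not square: %d columns, %d rows",
                 n, length(rows)), call. = FALSE)
  m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    r <- rows[[i]]
    if (length(r) != n + 1)
      stop(sprintf("row %d has %d cells, expected %d", i, length(r) - 1, n),
           call. = FALSE)
    if (r[1] != ids[i])
      stop(sprintf("row id '%s' does not match header id '%s'",
                   r[1], ids[i]), call. = FALSE)
    m[i, ] <- parse_num(r[-1])
  }
  fin <- is.finite(m) & is.finite(t(m))
  worst <- max(abs(m - t(m))[fin], 0)
  if (worst > tol)
    stop(sprintf("matrix is asymmetric (max |m - t(m)| = %g)", worst),
         call. = FALSE)
  if (as == "matrix") return(m)
  if (as == "auto")
    as <- if (any(is.infinite(m)) || any(m[is.finite(m)] > 1))
      "distance" else "proximity"
  if (as == "distance") distance_graph(m, node_ids = ids)
  else proximity_graph(m, node_ids = ids)
}

#' Read a region time-series table
#'
#' Tab- or whitespace-delimited text, one row per region: first column the
#' region id, remaining columns the time points. If a parcellation is
#' given, regions are matched by id and reordered to parcellation order;
#' missing or surplus regions are reported by id.
#'
#' @param path file path.
#' @param tr_seconds repetition time (s).
#' @param parc optional [parcellation()] to align against.
#' @return a [region_timeseries()].
#' @export
read_timeseries_table <- function(path, tr_seconds, parc = NULL) {
  df <- read.table(path, header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE, colClasses = "character")
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop(sprintf("duplicate region id(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  series <- do.call(rbind, lapply(seq_len(nrow(df)), function(i)
    parse_num(as.character(df[i, -1]))))
  rownames(series) <- ids
  if (!is.null(parc)) {
    missing_r <- setdiff(parc$id, ids)
    extra_r <- setdiff(ids, parc$id)
    if (length(missing_r) || length(extra_r))
      stop(sprintf(
        "region set mismatch: missing [%s], unexpected [%s]",
        paste(missing_r, collapse = ", "),
        paste(extra_r, collapse = ", ")), call. = FALSE)
    series <- series[parc$id, , drop = FALSE]
  }
  region_timeseries(series, tr_seconds = tr_seconds)
}

#' @rdname read_timeseries_table
#' @param ts a [region_timeseries()].
#' @param comments metadata lines.
#' @export
write_timeseries_table <- function(ts, path, comments = character()) {
  stopifnot(inherits(ts, "region_timeseries"))
  body <- vapply(seq_len(ts$n_regions), function(i)
    paste(c(ts$node_ids[i], fmt_num(ts$series[i, ])), collapse = "\t"), "")
  write_lines(c(if (length(comments)) paste("#", comments), body), path)
}

#' Write an edge-classification table
#'
#' One row per present (finite-distance) edge: `node_i`, `node_j`, the
#' proximity `w`, direct and closed distances, the metric/semi-metric
#' label, and the distortion ratio.
#'
#' @param cl a `closure_result`.
#' @param path file path.
#' @param comments metadata lines.
#' @return `path`, invisibly.
#' @export
write_edge_classification <- function(cl, path, comments = character()) {
  stopifnot(inherits(cl, "closure_result"))
  idx <- which(upper.tri(cl$direct_distances) &
                 is.finite(cl$direct_distances), arr.ind = TRUE)
  d <- cl$direct_distances[idx]
  rows <- data.frame(
    node_i = cl$node_ids[idx[, 1]], node_j = cl$node_ids[idx[, 2]],
    w = 1 / (d + 1), d_direct = d,
    d_closed = cl$closed_distances[idx],
    label = cl$edge_labels[idx], distortion = cl$distortion[idx],
    stringsAsFactors = FALSE)
  write_table_with_comments(rows, path, comments)
}

write_table_with_comments <- function(df, path, comments = character()) {
  num <- vapply(df, is.numeric, TRUE)
  for (cn in names(df)[num]) df[[cn]] <- fmt_num(df[[cn]])
  lines <- c(if (length(comments)) paste("#", comments),
             paste(names(df), collapse = "\t"),
             do.call(paste, c(unname(as.list(df)), sep = "\t")))
  write_lines(lines, path)
}

# small stable hash (FNV-1a, 32-bit) for config fingerprints in headers
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    # xor touches the low byte only (b < 256); keep arithmetic in doubles
    h <- h - (h %% 256) + bitwXor(h %% 256, b %% 256)
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (((hi * p) %% 65536) * 65536 + lo * p) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
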