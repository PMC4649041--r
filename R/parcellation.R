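HEMISPHERES <- c("left", "right", "cerebellum")
LOBES <- c("frontal", "parietal", "occipital", "temporal", "limbic",
           "subcortical", "cerebellar")

#' Construct a parcellation table
#'
#' Region metadata for an anatomical parcellation: one row per region with
#' its id, label, hemisphere (`left`, `right`, or `cerebellum` for
#' cerebellar/vermis regions), lobe (`frontal`, `parietal`, `occipital`,
#' `temporal`, `limbic`, `subcortical`, `cerebellar`) and MNI centroid in
#' mm. The package's analyses are written against a 116-region scheme in
#' the style of the Eickhoff-Zilles atlas, but any table with these
#' columns works.
#'
#' @param df data frame with columns `id`, `label`, `hemisphere`, `lobe`,
#'   `x`, `y`, `z`.
#' @return the validated data frame with class `parcellation` prepended.
#' @export
parcellation <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  needed <- c("id", "label", "hemisphere", "lobe", "x", "y", "z")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0)
    stop(sprintf("parcellation is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id))
    stop(sprintf("duplicate region id(s): %s",
                 paste(unique(df$id[duplicated(df$id)]), collapse = ", ")),
         call. = FALSE)
  bad_h <- setdiff(unique(df$hemisphere), HEMISPHERES)
  if (length(bad_h) > 0)
    stop(sprintf("unknown hemisphere value(s): %s",
                 paste(bad_h, collapse = ", ")), call. = FALSE)
  bad_l <- setdiff(unique(df$lobe), LOBES)
  if (length(bad_l) > 0)
    stop(sprintf("unknown lobe value(s): %s",
                 paste(bad_l, collapse = ", ")), call. = FALSE)
  if (!all(vapply(df[c("x", "y", "z")], is.numeric, TRUE)) ||
      anyNA(df[c("x", "y", "z")]))
    stop("centroid columns x, y, z must be numeric and complete",
         call. = FALSE)
  class(df) <- c("parcellation", "data.frame")
  df
}

#' Read / write a parcellation table
#'
#' Tab-delimited text with columns `id`, `label`, `hemisphere`, `lobe`,
#' `x`, `y`, `z` (MNI mm). Lines starting with `#` are ignored.
#'
#' @param path file path.
#' @return [read_parcellation()]: a [parcellation()]. `write_parcellation`
#'   returns `path` invisibly.
#' @export
read_parcellation <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE, quote = "")
  parcellation(df)
}

#' @rdname read_parcellation
#' @param p a [parcellation()].
#' @export
write_parcellation <- function(p, path) {
  stopifnot(inherits(p, "parcellation"))
  write.table(p, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Mean Euclidean centroid distance of a node-pair subset
#'
#' Arithmetic mean of the straight-line distances between region centroids
#' over all pairs in the subset — the geometric "scale" of a subgraph,
#' used to rank region sets from short- to long-range.
#'
#' @param pairs two-column matrix of node pairs (integer row indices into
#'   `p`, or region ids).
#' @param p a [parcellation()].
#' @return mean distance in mm.
#' @export
mean_euclidean_distance <- function(pairs, p) {
  stopifnot(inherits(p, "parcellation"))
  pairs <- as.matrix(pairs)
  if (nrow(pairs) == 0)
    stop("empty subset: mean Euclidean distance undefined", call. = FALSE)
  if (is.character(pairs)) {
    m <- match(pairs, p$id)
    if (anyNA(m))
      stop("unknown region id(s) in pairs", call. = FALSE)
    pairs <- matrix(m, ncol = 2)
  }
  xyz <- as.matrix(p[, c("x", "y", "z")])
  delta <- xyz[pairs[, 1], , drop = FALSE] - xyz[pairs[, 2], , drop = FALSE]
  mean(sqrt(rowSums(delta^2)))
}
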