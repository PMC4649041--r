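#' Consensus semi-metric backbone of a group
#'
#' For every node pair, the consensus is the fraction of the group's
#' subjects in which that pair is labelled semi-metric. The backbone keeps
#' the pairs whose consensus is *strictly* greater than the threshold
#' (default > 0.9, i.e. more than 90% of subjects), highlighting the
#' semi-metric connections consistently shared across the group. A group
#' whose semi-metric topology varies more between subjects satisfies the
#' consensus requirement less often and has a sparser backbone.
#'
#' @param study a [group_study()].
#' @param group which group's backbone (default: first group).
#' @param threshold consensus fraction; strict comparison (default 0.9).
#' @return data frame `node_i`, `node_j` (region ids), `consensus`, sorted
#'   by decreasing consensus; the full consensus matrix is attached as
#'   `attr(, "consensus_matrix")`.
#' @export
backbone <- function(study, group = study$groups[1], threshold = 0.9) {
  stopifnot(inherits(study, "group_study"))
  if (!group %in% study$groups)
    stop(sprintf("unknown group '%s'", group), call. = FALSE)
  if (threshold < 0 || threshold >= 1)
    stop("threshold must be in [0, 1)", call. = FALSE)
  subs <- study_subjects_in(study, group)
  n <- subs[[1]]$closure$n_nodes
  acc <- matrix(0, n, n)
  for (s in subs)
    acc <- acc + (s$closure$edge_labels == "semi-metric" &
                    !is.na(s$closure$edge_labels))
  consensus <- acc / length(subs)
  dimnames(consensus) <- dimnames(subs[[1]]$closure$edge_labels)
  keep <- which(consensus > threshold & upper.tri(consensus), arr.ind = TRUE)
  ids <- study$parcellation$id
  out <- data.frame(node_i = ids[keep[, 1]], node_j = ids[keep[, 2]],
                    consensus = consensus[keep], stringsAsFactors = FALSE)
  out <- out[order(-out$consensus, out$node_i, out$node_j), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "consensus_matrix") <- consensus
  out
}

#' Node-averaged group difference of closed connectomes
#'
#' Embeds every subject's closed (shortest-path) distances back into
#' proximity space via `w = 1/(D + 1)`, averages the embedded networks
#' elementwise within each group, takes the elementwise absolute
#' difference of the two group means, and scores each node by the mean of
#' its row (excluding the diagonal). Semi-metric edges are strongly
#' distorted by the closure, so large node scores mark regions whose
#' indirect connectivity to the rest of the brain differs most between
#' groups.
#'
#' @param study a [group_study()].
#' @param normalize if `TRUE`, divide scores by their maximum for display.
#' @return named numeric vector of per-node scores (names = region ids);
#'   the full absolute-difference matrix is attached as
#'   `attr(, "difference_matrix")`.
#' @export
group_difference_map <- function(study, normalize = FALSE) {
  stopifnot(inherits(study, "group_study"))
  group_mean_embedded <- function(group) {
    subs <- study_subjects_in(study, group)
    mats <- lapply(subs, function(s) {
      D <- s$closure$closed_distances
      w <- ifelse(is.infinite(D), 0, 1 / (D + 1))
      diag(w) <- 0
      w
    })
    Reduce(`+`, mats) / length(mats)
  }
  diff_mat <- abs(group_mean_embedded(study$groups[1]) -
                    group_mean_embedded(study$groups[2]))
  diag(diff_mat) <- NA
  scores <- rowMeans(diff_mat, na.rm = TRUE)
  names(scores) <- study$parcellation$id
  if (normalize && max(scores) > 0) scores <- scores / max(scores)
  attr(scores, "difference_matrix") <- diff_mat
  scores
}

#' Group SMP differences ranked by geometric scale
#'
#' One row per region set with a defined SMP in both groups, ordered by
#' the mean Euclidean distance between region centroids within the set —
#' short-range subgraphs first, long-range last — so the spatial profile
#' of the group difference can be read off directly.
#'
#' @param study a [group_study()].
#' @param profiles optional precomputed [study_smp_profiles()].
#' @return data frame `region_set`, `mean_distance_mm`, `mean_a`,
#'   `mean_b`, `smp_difference` (first group minus second), sorted by
#'   ascending distance.
#' @export
distance_ranked_smp <- function(study, profiles = NULL) {
  stopifnot(inherits(study, "group_study"))
  if (is.null(profiles)) profiles <- study_smp_profiles(study)
  labels <- attr(profiles, "group")
  ga <- study$groups[1]; gb <- study$groups[2]
  rows <- lapply(names(study$hierarchy$subsets), function(nm) {
    pairs <- study$hierarchy$subsets[[nm]]
    if (nrow(pairs) == 0) return(NULL)
    a <- mean(profiles[labels == ga, nm], na.rm = TRUE)
    b <- mean(profiles[labels == gb, nm], na.rm = TRUE)
    if (is.nan(a) || is.nan(b)) return(NULL)
    data.frame(region_set = nm,
               mean_distance_mm = mean_euclidean_distance(
                 pairs, study$parcellation),
               mean_a = a, mean_b = b, smp_difference = a - b,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$mean_distance_mm), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Correlation-distribution summary and negative-edge comparison
#'
#' Pools the signed off-diagonal correlations of all subjects within each
#' group and reports their median, mean and SD, a Shapiro-Wilk normality
#' p-value (on a bounded random subsample when the pooled count exceeds
#' the test's valid range of 5000), and a Welch t-test of the per-subject
#' counts of negative (set-to-zero) correlations between groups.
#'
#' @param study a [group_study()] whose subjects carry a `correlation`
#'   matrix (the signed, pre-truncation correlations).
#' @param max_shapiro_n subsample cap for the normality test.
#' @return list with `per_group` (data frame: group, n_values, median,
#'   mean, sd, shapiro_p), `negative_counts` (per subject) and
#'   `negative_count_test` (list: t, df, p_value; `NA`s with a warning if
#'   both groups have constant counts).
#' @export
correlation_distribution_summary <- function(study, max_shapiro_n = 5000) {
  stopifnot(inherits(study, "group_study"))
  labels <- study_group_labels(study)
  pooled <- lapply(study$groups, function(g) {
    subs <- study_subjects_in(study, g)
    vals <- unlist(lapply(subs, function(s) {
      if (is.null(s$correlation))
        stop(sprintf(
          "subject %s carries no signed correlation matrix", s$subject_id),
          call. = FALSE)
      s$correlation[upper.tri(s$correlation)]
    }))
    vals
  })
  names(pooled) <- study$groups
  per_group <- do.call(rbind, lapply(study$groups, function(g) {
    vals <- pooled[[g]]
    sw_vals <- if (length(vals) > max_shapiro_n)
      sample(vals, max_shapiro_n) else vals
    sw <- if (length(sw_vals) >= 3 && sd(sw_vals) > 0)
      shapiro.test(sw_vals)$p.value else NA_real_
    data.frame(group = g, n_values = length(vals),
               median = median(vals), mean = mean(vals), sd = sd(vals),
               shapiro_p = sw, stringsAsFactors = FALSE)
  }))
  neg <- vapply(study$subjects, function(s) {
    if (!is.null(s$n_negative)) return(as.numeric(s$n_negative))
    sum(s$correlation[upper.tri(s$correlation)] < 0)
  }, numeric(1))
  a <- neg[labels == study$groups[1]]
  b <- neg[labels == study$groups[2]]
  nct <- if (var(a) == 0 && var(b) == 0) {
    warning("negative counts constant in both groups; t-test undefined")
    list(t = NA_real_, df = NA_real_, p_value = NA_real_)
  } else {
    tt <- t.test(a, b, var.equal = FALSE)
    list(t = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value)
  }
  list(per_group = per_group,
       negative_counts = data.frame(
         subject_id = vapply(study$subjects, function(s) s$subject_id, ""),
         group = labels, n_negative = neg, stringsAsFactors = FALSE),
       negative_count_test = nct)
}
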