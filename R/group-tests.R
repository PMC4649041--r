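#' Welch two-sample comparison of SMP samples
#'
#' Two-sample t-test not assuming equal variances (Welch), two-tailed,
#' reporting the difference of group means `a - b` with its 95% Welch
#' confidence interval.
#'
#' @param a,b numeric vectors of per-subject SMPs (first and second
#'   group); `NA`s dropped.
#' @param region_set label for the tested region set.
#' @param conf_level confidence level (default 0.95).
#' @return one-row data frame with columns `region_set`, `mean_a`,
#'   `mean_b`, `difference` (a - b), `ci_lower`, `ci_upper`, `t`, `df`,
#'   `p_value`, `gated` (`TRUE`: the test was run).
#' @export
smp_group_test <- function(a, b, region_set = "set", conf_level = 0.95) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("need at least two subjects per group", call. = FALSE)
  if (var(a) == 0 && var(b) == 0) {
    if (isTRUE(all.equal(mean(a), mean(b))))
      stop(structure(
        class = c("semimetric_degenerate_test", "error", "condition"),
        list(message = "both groups constant and equal: test degenerate",
             call = NULL)))
    stop(structure(
      class = c("semimetric_degenerate_test", "error", "condition"),
      list(message = "zero variance in both groups: Welch test undefined",
           call = NULL)))
  }
  tt <- t.test(a, b, var.equal = FALSE, conf.level = conf_level)
  data.frame(
    region_set = region_set,
    mean_a = mean(a), mean_b = mean(b),
    difference = mean(a) - mean(b),
    ci_lower = tt$conf.int[1], ci_upper = tt$conf.int[2],
    t = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value, gated = TRUE,
    stringsAsFactors = FALSE)
}

gated_row <- function(region_set, a, b) {
  data.frame(
    region_set = region_set,
    mean_a = mean(a, na.rm = TRUE), mean_b = mean(b, na.rm = TRUE),
    difference = mean(a, na.rm = TRUE) - mean(b, na.rm = TRUE),
    ci_lower = NA_real_, ci_upper = NA_real_,
    t = NA_real_, df = NA_real_, p_value = NA_real_, gated = FALSE,
    stringsAsFactors = FALSE)
}

#' Gated hierarchical group comparison of SMPs
#'
#' Tests group differences in SMP over the nested region sets, gating each
#' test on its parent: the whole brain is always tested; a child set is
#' tested only if its parent's two-tailed p-value is below `alpha`
#' (hemispheres, cerebellum and between-hemisphere pairs gate on the whole
#' brain; lobes and the within-hemisphere between-lobe sets gate on their
#' hemisphere). Gated-off sets are still reported, with their group means
#' but no p-value. This mirrors the hierarchy of non-independent tests:
#' descending only where the coarser level shows evidence controls the
#' number of tests without a formal multiplicity correction.
#'
#' @param study a [group_study()].
#' @param alpha gate level (default 0.05, two-tailed).
#' @param p_adjust optional multiplicity correction (`"none"`, default, as
#'   in the gating-only scheme; or any [stats::p.adjust()] method, e.g.
#'   `"BH"`, applied across the tested rows only).
#' @param profiles optional precomputed [study_smp_profiles()] matrix.
#' @return data frame of [smp_group_test()] rows in reporting order
#'   (whole brain; hemispheres; cerebellum; between-hemispheres; left
#'   lobes and between-lobe; right lobes and between-lobe). Region sets
#'   whose SMP is undefined for every subject of a group are dropped with
#'   a message; a set whose SMPs are constant in both groups cannot be
#'   tested and is reported untested (`gated = FALSE`) with a message.
#' @export
gated_hierarchy_test <- function(study, alpha = 0.05, p_adjust = "none",
                                 profiles = NULL) {
  stopifnot(inherits(study, "group_study"))
  if (is.null(profiles)) profiles <- study_smp_profiles(study)
  labels <- attr(profiles, "group")
  ga <- study$groups[1]; gb <- study$groups[2]
  h <- study$hierarchy
  rows <- list()
  p_of <- c()
  for (nm in names(h$subsets)) {
    a <- profiles[labels == ga, nm]
    b <- profiles[labels == gb, nm]
    if (all(is.na(a)) || all(is.na(b))) {
      message(sprintf("region set '%s' has undefined SMP; skipped", nm))
      next
    }
    parent <- h$parents[[nm]]
    open <- is.na(parent) ||
      (!is.na(p_of[parent]) && p_of[parent] < alpha)
    if (open) {
      row <- tryCatch(
        smp_group_test(a, b, region_set = nm),
        semimetric_degenerate_test = function(e) {
          message(sprintf("region set '%s': %s", nm, conditionMessage(e)))
          gated_row(nm, a, b)
        })
      p_of[nm] <- if (row$gated) row$p_value else NA_real_
    } else {
      row <- gated_row(nm, a, b)
      p_of[nm] <- NA_real_
    }
    rows[[nm]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!identical(p_adjust, "none")) {
    tested <- out$gated
    out$p_adjusted <- NA_real_
    out$p_adjusted[tested] <- p.adjust(out$p_value[tested],
                                       method = p_adjust)
  }
  out
}

#' Hemispheric asymmetry of semi-metricity
#'
#' For each subject the asymmetry index `(r - l) / (r + l)` of the right-
#' and left-hemisphere SMPs (bounded in \[-1, 1\]), compared between
#' groups by a two-sided Mann-Whitney (Wilcoxon rank-sum) test.
#'
#' @param study a [group_study()].
#' @param profiles optional precomputed [study_smp_profiles()].
#' @return list with `indices` (data frame: subject_id, group, left, right,
#'   index), `U` (Mann-Whitney statistic for the first group), `p_value`.
#'   Subjects with `r + l = 0` are excluded with a warning.
#' @export
asymmetry_test <- function(study, profiles = NULL) {
  stopifnot(inherits(study, "group_study"))
  if (is.null(profiles)) profiles <- study_smp_profiles(study)
  labels <- attr(profiles, "group")
  l <- profiles[, "left_hemisphere"]
  r <- profiles[, "right_hemisphere"]
  if (anyNA(c(l, r)))
    stop("hemisphere SMP undefined for some subject", call. = FALSE)
  ok <- (r + l) > 0
  if (!all(ok))
    warning(sprintf(
      "excluding %d subject(s) with r + l = 0 from the asymmetry test",
      sum(!ok)))
  idx <- (r[ok] - l[ok]) / (r[ok] + l[ok])
  grp <- labels[ok]
  df <- data.frame(subject_id = rownames(profiles)[ok], group = grp,
                   left = l[ok], right = r[ok], index = idx,
                   stringsAsFactors = FALSE)
  wt <- suppressWarnings(
    wilcox.test(idx[grp == study$groups[1]],
                idx[grp == study$groups[2]]))  # exact when no ties
  list(indices = df, U = unname(wt$statistic), p_value = wt$p.value)
}
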