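#' Assemble a two-group study
#'
#' The unit of all group statistics: a labelled collection of per-subject
#' proximity graphs and their closures, sharing one parcellation and
#' region hierarchy.
#'
#' @param subjects list of subject records, each a list with fields
#'   `subject_id`, `group`, `proximity` (a [proximity_graph()]), and
#'   optionally `closure` (computed here if missing), `correlation` (the
#'   signed pre-truncation correlation matrix) and `n_negative`.
#' @param parcellation a [parcellation()] whose ids match every subject's
#'   node ids (same order).
#' @param hierarchy optional [build_hierarchy()] result (built from
#'   `parcellation` if omitted).
#' @param groups character vector of length 2 fixing group order; group
#'   differences are always reported as `groups[1] - groups[2]`. Defaults
#'   to the order of first appearance.
#' @param tol closure tie tolerance, passed to [metric_closure()].
#' @return an object of class `group_study`.
#' @export
group_study <- function(subjects, parcellation, hierarchy = NULL,
                        groups = NULL, tol = 1e-9) {
  stopifnot(inherits(parcellation, "parcellation"))
  if (length(subjects) < 2)
    stop("a study needs at least two subjects", call. = FALSE)
  ids <- parcellation$id
  for (s in subjects) {
    for (f in c("subject_id", "group", "proximity"))
      if (is.null(s[[f]]))
        stop(sprintf("every subject needs a '%s' field", f), call. = FALSE)
    if (!identical(s$proximity$node_ids, ids))
      stop(sprintf(
        "subject %s: node ids do not match the parcellation", s$subject_id),
        call. = FALSE)
  }
  labels <- vapply(subjects, function(s) as.character(s$group), "")
  if (is.null(groups)) groups <- unique(labels)
  if (length(groups) != 2 || !setequal(groups, unique(labels)))
    stop("study must contain exactly the two groups named in 'groups'",
         call. = FALSE)
  if (!all(table(factor(labels, levels = groups)) > 0))
    stop("both groups must be non-empty", call. = FALSE)
  subjects <- lapply(subjects, function(s) {
    if (is.null(s$closure))
      s$closure <- metric_closure(proximity_to_distance(s$proximity),
                                  tol = tol)
    s
  })
  if (is.null(hierarchy)) hierarchy <- build_hierarchy(parcellation)
  structure(
    list(subjects = subjects, parcellation = parcellation,
         hierarchy = hierarchy, groups = groups),
    class = "group_study")
}

#' @export
print.group_study <- function(x, ...) {
  labels <- vapply(x$subjects, function(s) s$group, "")
  cat(sprintf("group_study: %d subjects (%s), %d nodes, %d region sets\n",
              length(x$subjects),
              paste(sprintf("%s n=%d", x$groups,
                            tabulate(factor(labels, x$groups))),
                    collapse = " vs "),
              nrow(x$parcellation), length(x$hierarchy$subsets)))
  invisible(x)
}

study_group_labels <- function(study) {
  vapply(study$subjects, function(s) as.character(s$group), "")
}

study_subjects_in <- function(study, group) {
  study$subjects[study_group_labels(study) == group]
}

#' Per-subject SMP profile over the region hierarchy
#'
#' Evaluates the semi-metric percentage of every named region set for one
#' subject. Edges are classified once, globally, on the whole-brain
#' closure; each subset SMP then counts the globally assigned labels
#' restricted to that subset's pairs. Subsets with no finite direct edge
#' are undefined and reported as `NA`.
#'
#' @param cl a `closure_result` on the whole-brain graph.
#' @param h a [build_hierarchy()] result.
#' @return named numeric vector, one SMP (or `NA`) per region set.
#' @export
subject_smp_profile <- function(cl, h) {
  stopifnot(inherits(cl, "closure_result"), inherits(h, "region_hierarchy"))
  if (cl$n_nodes != h$n_nodes)
    stop("closure and hierarchy disagree on node count", call. = FALSE)
  vapply(h$subsets, function(pairs) smp_or_na(cl, pairs), numeric(1))
}

#' SMP profiles for every subject in a study
#'
#' @param study a [group_study()].
#' @return numeric matrix, subjects x region sets, with subject ids as row
#'   names; `attr(, "group")` carries the group label per row.
#' @export
study_smp_profiles <- function(study) {
  stopifnot(inherits(study, "group_study"))
  prof <- t(vapply(study$subjects,
                   function(s) subject_smp_profile(s$closure, study$hierarchy),
                   numeric(length(study$hierarchy$subsets))))
  rownames(prof) <- vapply(study$subjects, function(s) s$subject_id, "")
  attr(prof, "group") <- study_group_labels(study)
  prof
}
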