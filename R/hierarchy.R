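#' Build the nested region-set hierarchy
#'
#' Enumerates the nested edge subsets on which group differences in SMP
#' are tested: the whole brain; the left and right cerebral hemispheres
#' and the cerebellum; the between-hemisphere (left x right) pairs; then,
#' within each hemisphere, the within-lobe subsets and the
#' within-hemisphere between-lobe ("between-region") subset. Within each
#' hemisphere the lobe subsets plus the between-lobe subset partition that
#' hemisphere's pairs; cerebellum-to-cerebrum pairs count toward the whole
#' brain only.
#'
#' Each subset is an unordered node-pair collection (two-column matrix of
#' row indices into the parcellation, `i < j`). The `parents` map encodes
#' the gating scheme for hierarchical testing: hemispheres, cerebellum and
#' between-hemispheres gate on the whole brain; lobe and between-lobe
#' subsets gate on their hemisphere.
#'
#' @param p a [parcellation()].
#' @return an object of class `region_hierarchy`: list with `subsets`
#'   (named list of pair matrices, in reporting order), `parents` (named
#'   character vector; `NA` for the whole brain), `n_nodes`, `node_ids`.
#' @export
build_hierarchy <- function(p) {
  stopifnot(inherits(p, "parcellation"))
  n <- nrow(p)
  pairs <- all_pairs(n)
  hem_i <- p$hemisphere[pairs[, 1]]
  hem_j <- p$hemisphere[pairs[, 2]]
  lobe_i <- p$lobe[pairs[, 1]]
  lobe_j <- p$lobe[pairs[, 2]]

  take <- function(keep) pairs[keep, , drop = FALSE]
  subsets <- list(whole_brain = pairs)
  parents <- c(whole_brain = NA_character_)

  for (h in c("left", "right")) {
    nm <- paste0(h, "_hemisphere")
    subsets[[nm]] <- take(hem_i == h & hem_j == h)
    parents[[nm]] <- "whole_brain"
  }
  subsets$cerebellum <- take(hem_i == "cerebellum" & hem_j == "cerebellum")
  parents["cerebellum"] <- "whole_brain"
  subsets$between_hemispheres <- take(
    (hem_i == "left" & hem_j == "right") |
      (hem_i == "right" & hem_j == "left"))
  parents["between_hemispheres"] <- "whole_brain"

  for (h in c("left", "right")) {
    hem_nm <- paste0(h, "_hemisphere")
    within <- hem_i == h & hem_j == h
    for (lb in setdiff(LOBES, "cerebellar")) {
      nm <- paste0(h, "_", lb)
      keep <- within & lobe_i == lb & lobe_j == lb
      if (!any(p$hemisphere == h & p$lobe == lb)) next  # lobe not present
      subsets[[nm]] <- take(keep)
      parents[[nm]] <- hem_nm
    }
    nm <- paste0(h, "_between_lobe")
    subsets[[nm]] <- take(within & lobe_i != lobe_j)
    parents[[nm]] <- hem_nm
  }

  structure(
    list(subsets = subsets, parents = parents, n_nodes = n,
         node_ids = p$id),
    class = "region_hierarchy")
}

#' @export
print.region_hierarchy <- function(x, ...) {
  cat(sprintf("region_hierarchy: %d nodes, %d region sets\n",
              x$n_nodes, length(x$subsets)))
  for (nm in names(x$subsets))
    cat(sprintf("  %-22s %6d pairs  (parent: %s)\n", nm,
                nrow(x$subsets[[nm]]),
                ifelse(is.na(x$parents[[nm]]), "-", x$parents[[nm]])))
  invisible(x)
}
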