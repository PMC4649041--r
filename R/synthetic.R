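#' Synthetic parcellation fixture
#'
#' Generates a plausible parcellation table for testing and simulation:
#' nodes split across the two cerebral hemispheres and the cerebellum,
#' lobes allocated in atlas-like proportions, and centroids drawn
#' uniformly inside plausible MNI bounding boxes per compartment. With the
#' default 116 nodes the split is 45 left, 45 right, 26 cerebellar,
#' mirroring the shape of the 116-region Eickhoff-Zilles scheme (this is
#' a synthetic stand-in, not a reproduction of the atlas).
#'
#' @param n_nodes number of regions (>= 6; default 116).
#' @param seed integer seed; the fixture is deterministic given
#'   `(n_nodes, seed)`.
#' @return a [parcellation()].
#' @export
make_parcellation_fixture <- function(n_nodes = 116, seed = 1) {
  if (n_nodes < 6)
    stop("need at least 6 nodes for a two-hemisphere fixture",
         call. = FALSE)
  set.seed(seed)
  n_cb <- max(1, round(n_nodes * 26 / 116))
  n_left <- floor((n_nodes - n_cb) / 2)
  n_right <- n_nodes - n_cb - n_left

  cerebral_lobes <- function(n_hem) {
    weights <- c(frontal = 14, parietal = 7, occipital = 7, temporal = 8,
                 limbic = 5, subcortical = 4)
    alloc <- floor(weights / sum(weights) * n_hem)
    rem <- n_hem - sum(alloc)
    frac <- weights / sum(weights) * n_hem - alloc
    if (rem > 0) {
      bump <- order(frac, decreasing = TRUE)[seq_len(rem)]
      alloc[bump] <- alloc[bump] + 1
    }
    if (sum(alloc > 0) < 2 && n_hem >= 2) {  # always >= 2 lobes populated
      alloc[] <- 0
      alloc[c("frontal", "temporal")] <- c(n_hem - 1, 1)
    }
    rep(names(alloc), alloc)
  }

  hemi <- c(rep("left", n_left), rep("right", n_right),
            rep("cerebellum", n_cb))
  lobe <- c(cerebral_lobes(n_left), cerebral_lobes(n_right),
            rep("cerebellar", n_cb))
  x <- numeric(n_nodes); y <- numeric(n_nodes); z <- numeric(n_nodes)
  left <- hemi == "left"; right <- hemi == "right"; cb <- hemi == "cerebellum"
  x[left] <- runif(sum(left), -70, -5)
  x[right] <- runif(sum(right), 5, 70)
  x[cb] <- runif(sum(cb), -45, 45)
  y[!cb] <- runif(sum(!cb), -100, 70)
  z[!cb] <- runif(sum(!cb), -25, 80)
  y[cb] <- runif(sum(cb), -85, -40)
  z[cb] <- runif(sum(cb), -55, -10)

  counter <- stats::ave(seq_len(n_nodes),
                        paste(hemi, lobe), FUN = seq_along)
  parcellation(data.frame(
    id = sprintf("R%03d", seq_len(n_nodes)),
    label = sprintf("%s_%s_%02d", hemi, lobe, counter),
    hemisphere = hemi, lobe = lobe,
    x = round(x, 1), y = round(y, 1), z = round(z, 1),
    stringsAsFactors = FALSE))
}

#' Specification of one synthetic group
#'
#' Parameters controlling a group of synthetic subjects. Background edge
#' weights are drawn from a normal distribution with mean `mu_r` and SD
#' `sigma_r` (the raw, signed "correlations"), truncated to \[0, 1\] when
#' forming the proximity graph. On top of the background, `n_triads`
#' indirect-path triads are planted: a weak direct chord of proximity
#' `w_weak` bridged by a two-hop path of strong edges `w_strong` through a
#' hub, which makes the chord provably semi-metric whenever
#' `2 (1/w_strong - 1) < 1/w_weak - 1` (the two-hop path is an upper bound
#' on the shortest path). `jitter` is the per-subject probability that a
#' planted triad is relocated to a random position, modelling
#' between-subject variability of the semi-metric topology.
#'
#' The defaults for the two study groups are [control_spec()] (n = 12,
#' `mu_r` = 0.316, `sigma_r` = 0.036, fewer triads, low jitter) and
#' [case_spec()] (n = 11, `mu_r` = 0.291, `sigma_r` = 0.034, more triads,
#' high jitter): a case group with a narrower correlation-coefficient
#' spread, a higher prevalence of indirect paths, and more heterogeneous
#' semi-metric topology.
#'
#' @param n_subjects number of subjects in the group.
#' @param mu_r,sigma_r mean and SD of the background correlation level.
#' @param n_triads planted indirect-path triads per subject.
#' @param w_strong,w_weak triad proximities (strong two-hop legs, weak
#'   direct chord), `0 < w_weak < w_strong <= 1`.
#' @param jitter triad relocation probability in \[0, 1\].
#' @param n_timepoints,tr_seconds time-series length and repetition time
#'   used when sampling BOLD-like series (defaults 256 points at 2.43 s).
#' @return an object of class `group_spec`.
#' @export
group_spec <- function(n_subjects, mu_r, sigma_r, n_triads = 0,
                       w_strong = 0.4, w_weak = 0.2, jitter = 0,
                       n_timepoints = 256, tr_seconds = 2.43) {
  if (n_subjects < 1) stop("n_subjects must be positive", call. = FALSE)
  if (sigma_r < 0) stop("sigma_r must be non-negative", call. = FALSE)
  if (!(w_weak > 0 && w_weak < w_strong && w_strong <= 1))
    stop("need 0 < w_weak < w_strong <= 1", call. = FALSE)
  if (n_triads > 0 && !(2 * (1 / w_strong - 1) < 1 / w_weak - 1))
    stop(sprintf(
      paste0("infeasible triad: two-hop path 2(1/w_strong - 1) = %g is ",
             "not shorter than the chord 1/w_weak - 1 = %g"),
      2 * (1 / w_strong - 1), 1 / w_weak - 1), call. = FALSE)
  if (jitter < 0 || jitter > 1)
    stop("jitter must be in [0, 1]", call. = FALSE)
  structure(
    list(n_subjects = as.integer(n_subjects), mu_r = mu_r,
         sigma_r = sigma_r, n_triads = as.integer(n_triads),
         w_strong = w_strong, w_weak = w_weak, jitter = jitter,
         n_timepoints = as.integer(n_timepoints), tr_seconds = tr_seconds),
    class = "group_spec")
}

#' @rdname group_spec
#' @export
control_spec <- function(n_subjects = 12, mu_r = 0.316, sigma_r = 0.036,
                         n_triads = 10, jitter = 0.1, ...) {
  group_spec(n_subjects, mu_r, sigma_r, n_triads = n_triads,
             jitter = jitter, ...)
}

#' @rdname group_spec
#' @export
case_spec <- function(n_subjects = 11, mu_r = 0.291, sigma_r = 0.034,
                      n_triads = 40, jitter = 0.5, ...) {
  group_spec(n_subjects, mu_r, sigma_r, n_triads = n_triads,
             jitter = jitter, ...)
}

# random (hub-centred) triads: columns i, hub, j; nodes distinct per triad
draw_triads <- function(n_triads, n_nodes) {
  if (n_triads == 0)
    return(matrix(integer(0), 0, 3,
                  dimnames = list(NULL, c("i", "hub", "j"))))
  t(vapply(seq_len(n_triads),
           function(...) sample.int(n_nodes, 3),
           integer(3))) |>
    `colnames<-`(c("i", "hub", "j"))
}

#' Sample one subject's proximity graph with planted structure
#'
#' Draws a symmetric background of signed correlations from
#' `N(mu_r, sigma_r)`, plants the indirect-path triads, and truncates at
#' zero to form the proximity graph. Returns the analytically guaranteed
#' semi-metric chords: after all planting, a chord (i, j) is guaranteed
#' semi-metric iff some planted two-hop path through its hub is shorter in
#' distance space than the chord's final direct distance (additional
#' background paths can only shorten the closure further, never revoke
#' the violation).
#'
#' @param spec a [group_spec()].
#' @param parc a [parcellation()] defining the nodes.
#' @param triads optional preset triad matrix (columns i, hub, j), e.g. a
#'   group's canonical triads; drawn fresh if `NULL`. Each triad is
#'   relocated with probability `spec$jitter`.
#' @param seed optional integer seed; if `NULL` the current RNG state is
#'   used (so that a caller-level seed governs the whole draw).
#' @return list with `graph` (a [proximity_graph()]), `correlation`
#'   (signed background with planted weights, unit diagonal),
#'   `n_negative`, `planted` (two-column index matrix of guaranteed
#'   semi-metric chords), `triads` (the triads actually used).
#' @export
sample_subject_proximity <- function(spec, parc, triads = NULL,
                                     seed = NULL) {
  stopifnot(inherits(spec, "group_spec"), inherits(parc, "parcellation"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(parc)
  if (n < 3 && spec$n_triads > 0)
    stop("need at least 3 nodes to plant triads", call. = FALSE)

  raw <- matrix(0, n, n)
  ut <- upper.tri(raw)
  raw[ut] <- rnorm(sum(ut), spec$mu_r, spec$sigma_r)
  raw <- raw + t(raw)
  raw[raw > 1] <- 1
  raw[raw < -1] <- -1

  if (is.null(triads)) triads <- draw_triads(spec$n_triads, n)
  if (nrow(triads) > 0 && spec$jitter > 0) {
    move <- runif(nrow(triads)) < spec$jitter
    for (t_i in which(move)) triads[t_i, ] <- sample.int(n, 3)
  }
  for (t_i in seq_len(nrow(triads))) {
    i <- triads[t_i, 1]; k <- triads[t_i, 2]; j <- triads[t_i, 3]
    raw[i, k] <- raw[k, i] <- spec$w_strong
    raw[k, j] <- raw[j, k] <- spec$w_strong
    raw[i, j] <- raw[j, i] <- spec$w_weak
  }
  diag(raw) <- 1

  # guaranteed chords, evaluated on the *final* weights
  planted <- matrix(integer(0), 0, 2)
  for (t_i in seq_len(nrow(triads))) {
    i <- triads[t_i, 1]; k <- triads[t_i, 2]; j <- triads[t_i, 3]
    w_ij <- raw[i, j]; legs <- c(raw[i, k], raw[k, j])
    if (w_ij > 0 && all(legs > 0) &&
        sum(1 / legs - 1) < 1 / w_ij - 1 - 1e-12)
      planted <- rbind(planted, sort(c(i, j)))
  }
  planted <- unique(planted)

  w <- pmax(raw, 0)
  diag(w) <- 0
  list(graph = proximity_graph(w, node_ids = parc$id),
       correlation = raw,
       n_negative = sum(raw[upper.tri(raw)] < 0),
       planted = planted, triads = triads)
}

#' Sample BOLD-like region time series for one subject
#'
#' Draws `n_timepoints` samples from a zero-mean multivariate normal whose
#' correlation matrix approximates a target proximity structure, after a
#' nearest-positive-semidefinite repair by eigenvalue clipping (negative
#' eigenvalues raised to a small floor, then rescaled back to unit
#' diagonal). Because the series are temporally white, the wavelet
#' coefficients at every scale inherit the same cross-correlation, so the
#' scale-2 empirical correlations converge to the target as the series
#' lengthens.
#'
#' @param spec a [group_spec()].
#' @param parc a [parcellation()].
#' @param target optional target correlation matrix (unit diagonal); if
#'   `NULL`, one is drawn via [sample_subject_proximity()].
#' @param seed optional integer seed (see [sample_subject_proximity()]).
#' @return a [region_timeseries()]; the repaired target is attached as
#'   `attr(, "target_correlation")`.
#' @export
sample_subject_timeseries <- function(spec, parc, target = NULL,
                                      seed = NULL) {
  stopifnot(inherits(spec, "group_spec"), inherits(parc, "parcellation"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(target))
    target <- sample_subject_proximity(spec, parc)$correlation
  C <- nearest_psd_correlation(target)
  x <- MASS::mvrnorm(spec$n_timepoints, mu = rep(0, nrow(C)), Sigma = C)
  ts <- region_timeseries(t(x), tr_seconds = spec$tr_seconds,
                          node_ids = parc$id)
  attr(ts, "target_correlation") <- C
  ts
}

# eigenvalue-clipping repair, rescaled to a correlation matrix
nearest_psd_correlation <- function(C, floor_ev = 1e-6) {
  C <- (C + t(C)) / 2
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) >= floor_ev) return(C)
  vals <- pmax(e$values, floor_ev)
  M <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(M))
  if (any(d <= 0)) stop("PSD repair failed", call. = FALSE)
  M <- M / tcrossprod(d)
  diag(M) <- 1
  (M + t(M)) / 2
}

#' Generate a full synthetic two-group study
#'
#' Samples every subject of both groups and assembles a [group_study()]
#' ready for the group-level analyses, together with the generator's
#' ground truth. One pool of canonical triad locations is drawn per study
#' and shared by both groups (a group with `n_triads = k` plants the
#' first `k` pool entries, so the larger group's plants are a superset of
#' the smaller's and, under identical specs, the two groups are exactly
#' exchangeable). A subject's triads deviate from the canonical set with
#' probability `jitter` per triad, so low-jitter groups show consistent
#' semi-metric topology (dense consensus backbone) and high-jitter groups
#' a heterogeneous one (sparse backbone).
#'
#' @param control a [group_spec()] for the control group.
#' @param case a [group_spec()] for the case group.
#' @param parc a [parcellation()]; default [make_parcellation_fixture()]
#'   re-seeded from `seed`.
#' @param seed integer seed governing the whole draw.
#' @param mode `"matrix"` (default: subjects are sampled directly in
#'   correlation space) or `"timeseries"` (BOLD-like series are sampled
#'   per subject and pushed through the wavelet connectivity stage, so
#'   planted guarantees hold only approximately).
#' @param scale wavelet analysis scale for `mode = "timeseries"`.
#' @return list with `study` (a [group_study()], groups ordered
#'   case, control so differences read case minus control) and
#'   `ground_truth` (canonical triads and per-subject guaranteed planted
#'   chords; for `mode = "timeseries"` also the per-subject series).
#' @export
make_group_study <- function(control = control_spec(), case = case_spec(),
                             parc = NULL, seed = 1, mode = c("matrix",
                                                             "timeseries"),
                             scale = 2) {
  mode <- match.arg(mode)
  set.seed(seed)
  if (is.null(parc))
    parc <- make_parcellation_fixture(seed = sample.int(2^31 - 1, 1))
  specs <- list(case = case, control = control)
  pool <- draw_triads(max(case$n_triads, control$n_triads), nrow(parc))
  canonical <- lapply(specs, function(sp)
    pool[seq_len(sp$n_triads), , drop = FALSE])
  subjects <- list()
  truth <- list(canonical_triads = canonical, subjects = list())
  series_store <- list()
  for (g in names(specs)) {
    sp <- specs[[g]]
    for (k in seq_len(sp$n_subjects)) {
      sid <- sprintf("%s_%02d", g, k)
      if (mode == "matrix") {
        draw <- sample_subject_proximity(sp, parc,
                                         triads = canonical[[g]])
        subj <- list(subject_id = sid, group = g, proximity = draw$graph,
                     correlation = draw$correlation,
                     n_negative = draw$n_negative)
      } else {
        draw <- sample_subject_proximity(sp, parc,
                                         triads = canonical[[g]])
        ts <- sample_subject_timeseries(sp, parc,
                                        target = draw$correlation)
        conn <- timeseries_to_proximity(ts, scale = scale)
        subj <- list(subject_id = sid, group = g, proximity = conn$graph,
                     correlation = conn$correlation,
                     n_negative = conn$n_negative)
        series_store[[sid]] <- ts
      }
      truth$subjects[[sid]] <- list(group = g, planted = draw$planted,
                                    triads = draw$triads)
      subjects[[sid]] <- subj
    }
  }
  study <- group_study(subjects, parc, groups = c("case", "control"))
  if (mode == "timeseries") truth$timeseries <- series_store
  list(study = study, ground_truth = truth)
}
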