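# shared fixtures, all built in code

# random symmetric proximity graph; weights uniform in (0, 1] at the given
# edge density, 0 (absent) elsewhere
random_proximity <- function(n, density = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(0, n, n)
  ut <- upper.tri(m)
  k <- sum(ut)
  w <- ifelse(runif(k) < density, runif(k, min = 1e-6, max = 1), 0)
  m[ut] <- w
  m <- m + t(m)
  proximity_graph(m)
}

# the worked 3-node graph: strong path 1-2-3 (w = 0.8) bridging a weak
# direct edge 1-3 (w = 0.2); edge (1,3) is semi-metric with distortion 8
planted_triangle <- function() {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.8
  w[2, 3] <- w[3, 2] <- 0.8
  w[1, 3] <- w[3, 1] <- 0.2
  proximity_graph(w)
}

uniform_triangle <- function(w = 0.5) {
  m <- matrix(w, 3, 3)
  diag(m) <- 0
  proximity_graph(m)
}

# 4-node toy parcellation: 2 left-frontal, 1 left-temporal, 1 right-frontal
toy_parcellation <- function() {
  parcellation(data.frame(
    id = c("LF1", "LF2", "LT1", "RF1"),
    label = c("l_front_1", "l_front_2", "l_temp_1", "r_front_1"),
    hemisphere = c("left", "left", "left", "right"),
    lobe = c("frontal", "frontal", "temporal", "frontal"),
    x = c(-30, -40, -50, 30), y = c(20, 30, -10, 20),
    z = c(10, 20, -5, 10), stringsAsFactors = FALSE))
}

# small study built from explicit per-subject proximity matrices
study_from_weights <- function(weight_list, groups_of, parc,
                               correlations = NULL) {
  subjects <- lapply(seq_along(weight_list), function(i) {
    s <- list(subject_id = sprintf("s%02d", i), group = groups_of[i],
              proximity = proximity_graph(weight_list[[i]],
                                          node_ids = parc$id))
    if (!is.null(correlations)) s$correlation <- correlations[[i]]
    s
  })
  group_study(subjects, parc)
}

# complete graph at uniform weight on the toy parcellation (all metric)
uniform_weights <- function(n, w = 0.5) {
  m <- matrix(w, n, n)
  diag(m) <- 0
  m
}
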