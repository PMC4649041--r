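six_node_parc <- function() {
  parcellation(data.frame(
    id = sprintf("N%d", 1:6), label = sprintf("n%d", 1:6),
    hemisphere = c("left", "left", "left", "right", "right", "right"),
    lobe = c("frontal", "frontal", "temporal",
             "frontal", "temporal", "temporal"),
    x = c(-30, -40, -50, 30, 40, 50), y = c(10, 20, -30, 10, -30, -40),
    z = c(0, 10, -5, 0, -5, -10), stringsAsFactors = FALSE))
}

plant_at <- function(base, i, k, j, w_strong = 0.8, w_weak = 0.1) {
  base[i, k] <- base[k, i] <- w_strong
  base[k, j] <- base[j, k] <- w_strong
  base[i, j] <- base[j, i] <- w_weak
  base
}

test_that("backbone keeps consensus strictly above the threshold", {
  parc <- six_node_parc()
  base <- uniform_weights(6, 0.5)
  planted <- plant_at(base, 1, 2, 3)    # chord (1,3) semi-metric
  other <- plant_at(base, 4, 5, 6)      # chord (4,6) semi-metric
  # group A: 10 subjects, the planted edge in all 10
  st_all <- study_from_weights(
    c(replicate(10, planted, simplify = FALSE), list(base, base)),
    groups_of = c(rep("A", 10), "B", "B"), parc = parc)
  bb <- backbone(st_all, "A", threshold = 0.9)
  expect_identical(nrow(bb), 1L)
  expect_identical(c(bb$node_i, bb$node_j), c("N1", "N3"))
  expect_equal(bb$consensus, 1)

  # 9 of 10: consensus exactly 0.9 is dropped by the strict rule
  st_nine <- study_from_weights(
    c(replicate(9, planted, simplify = FALSE), list(other, base, base)),
    groups_of = c(rep("A", 10), "B", "B"), parc = parc)
  bb9 <- backbone(st_nine, "A", threshold = 0.9)
  expect_identical(nrow(bb9), 0L)
  cm <- attr(bb9, "consensus_matrix")
  expect_equal(cm["N1", "N3"], 0.9)
  expect_true(all(cm >= 0 & cm <= 1))
})

test_that("backbone at 0 is the union and shrinks as the threshold rises", {
  gen <- make_group_study(seed = 31)
  st <- gen$study
  bb0 <- backbone(st, "case", threshold = 0)
  case_subjects <- Filter(function(s) s$group == "case", st$subjects)
  union_pairs <- Reduce(`|`, lapply(case_subjects,
    function(s) s$closure$edge_labels == "semi-metric" &
      !is.na(s$closure$edge_labels)))
  expect_identical(nrow(bb0), sum(union_pairs[upper.tri(union_pairs)]))
  sizes <- vapply(c(0, 0.25, 0.5, 0.75, 0.9),
                  function(th) nrow(backbone(st, "case", threshold = th)),
                  0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("identical groups have a zero difference map", {
  parc <- six_node_parc()
  planted <- plant_at(uniform_weights(6, 0.5), 1, 2, 3)
  st <- study_from_weights(list(planted, planted, planted, planted),
                           groups_of = c("A", "A", "B", "B"), parc = parc)
  scores <- group_difference_map(st)
  expect_true(all(scores == 0))
})

test_that("perturbing one node's edges raises its difference score", {
  parc <- make_parcellation_fixture(20, seed = 32)
  set.seed(33)
  base <- uniform_weights(20, 0.4)
  hit <- base
  hit[5, -5] <- hit[-5, 5] <- 0.1   # node 5 weakened in group B
  st <- study_from_weights(list(base, base, hit, hit),
                           groups_of = c("A", "A", "B", "B"), parc = parc)
  scores <- group_difference_map(st)
  expect_gt(scores[[5]], median(scores))
  expect_identical(unname(which.max(scores)), 5L)
  # group order only flips the sign inside the absolute value
  st_rev <- study_from_weights(list(hit, hit, base, base),
                               groups_of = c("A", "A", "B", "B"),
                               parc = parc)
  expect_equal(unname(group_difference_map(st_rev)), unname(scores))
})

test_that("difference scores are stable under consistent relabelling", {
  parc <- make_parcellation_fixture(12, seed = 34)
  set.seed(35)
  w1 <- random_proximity(12, 0.7)$weights
  w2 <- random_proximity(12, 0.7)$weights
  st <- study_from_weights(list(w1, w1, w2, w2),
                           groups_of = c("A", "A", "B", "B"), parc = parc)
  scores <- group_difference_map(st)
  perm <- sample(12)
  parc_p <- parcellation(parc[perm, ])
  st_p <- study_from_weights(
    list(w1[perm, perm], w1[perm, perm], w2[perm, perm], w2[perm, perm]),
    groups_of = c("A", "A", "B", "B"), parc = parc_p)
  scores_p <- group_difference_map(st_p)
  expect_equal(as.numeric(scores_p), as.numeric(scores[perm]))
  # normalization rescales the maximum to 1
  expect_equal(max(group_difference_map(st, normalize = TRUE)), 1)
})

test_that("distance-ranked SMP table is ordered and self-consistent", {
  gen <- make_group_study(seed = 36)
  st <- gen$study
  ranked <- distance_ranked_smp(st)
  expect_true(!is.unsorted(ranked$mean_distance_mm))
  # rows match independently recomputed subset distances and differences
  profiles <- study_smp_profiles(st)
  labels <- attr(profiles, "group")
  for (k in sample(nrow(ranked), 4)) {
    nm <- ranked$region_set[k]
    expect_equal(ranked$mean_distance_mm[k],
                 mean_euclidean_distance(st$hierarchy$subsets[[nm]],
                                         st$parcellation))
    expect_equal(ranked$smp_difference[k],
                 mean(profiles[labels == "case", nm], na.rm = TRUE) -
                   mean(profiles[labels == "control", nm], na.rm = TRUE))
  }
  # ordering is a property of the sets, not of their input order
  h2 <- st$hierarchy
  h2$subsets <- rev(h2$subsets)
  st2 <- st
  st2$hierarchy <- h2
  ranked2 <- distance_ranked_smp(st2)
  expect_identical(sort(ranked$region_set), sort(ranked2$region_set))
  expect_true(!is.unsorted(ranked2$mean_distance_mm))
})

test_that("pooled correlation summaries and the negative-count test", {
  parc <- six_node_parc()
  set.seed(37)
  mk_corr <- function(seed) {
    set.seed(seed)
    m <- matrix(rnorm(36, 0.15, 0.3), 6, 6)
    m <- (m + t(m)) / 2
    m[m > 1] <- 1; m[m < -1] <- -1
    diag(m) <- 1
    m
  }
  c1 <- mk_corr(1); c2 <- mk_corr(2); c3 <- mk_corr(3); c4 <- mk_corr(4)
  weights <- lapply(list(c1, c2, c3, c4), function(m) {
    w <- pmax(m, 0); diag(w) <- 0; w
  })
  st <- study_from_weights(weights, groups_of = c("A", "A", "B", "B"),
                           parc = parc, correlations = list(c1, c2, c3, c4))
  res <- correlation_distribution_summary(st)

  # identical matrices within a group: pooled SD = within-matrix SD
  st_same <- study_from_weights(weights[c(1, 1, 3, 3)],
                                groups_of = c("A", "A", "B", "B"),
                                parc = parc,
                                correlations = list(c1, c1, c3, c3))
  res_same <- suppressWarnings(correlation_distribution_summary(st_same))
  # pooling identical matrices concatenates their upper triangles
  expect_equal(res_same$per_group$sd[1], sd(rep(c1[upper.tri(c1)], 2)))
  expect_equal(res_same$per_group$median[1], median(c1[upper.tri(c1)]))
  expect_equal(res_same$per_group$mean[1], mean(c1[upper.tri(c1)]))

  # negative-count Welch test matches a direct computation
  neg <- vapply(list(c1, c2, c3, c4),
                function(m) sum(m[upper.tri(m)] < 0), 0)
  direct <- t.test(neg[1:2], neg[3:4], var.equal = FALSE)
  expect_equal(res$negative_count_test$t, unname(direct$statistic))
  expect_equal(res$negative_count_test$p_value, direct$p.value)
  expect_identical(res$negative_counts$n_negative, neg)

  # shapiro p agrees with a direct call on the pooled values
  pooled_a <- c(c1[upper.tri(c1)], c2[upper.tri(c2)])
  expect_equal(res$per_group$shapiro_p[1], shapiro.test(pooled_a)$p.value)
})

test_that("a symmetric correlation distribution has mean close to median", {
  set.seed(38)
  spec <- group_spec(4, mu_r = 0.3, sigma_r = 0.05)
  parc <- make_parcellation_fixture(40, seed = 39)
  draws <- replicate(4, sample_subject_proximity(spec, parc),
                     simplify = FALSE)
  st <- study_from_weights(lapply(draws, function(d) d$graph$weights),
                           groups_of = c("A", "A", "B", "B"), parc = parc,
                           correlations = lapply(draws,
                                                 function(d) d$correlation))
  # background negatives are rare at these parameters; the count test may
  # be degenerate, which is irrelevant to the symmetry check
  res <- suppressWarnings(correlation_distribution_summary(st))
  expect_lt(max(abs(res$per_group$mean - res$per_group$median)), 0.01)
})
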