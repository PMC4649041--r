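toy_study <- function() {
  parc <- toy_parcellation()
  base <- uniform_weights(4, 0.5)
  # plant a semi-metric left edge: strong path LF1-LF2-LT1, weak LF1-LT1
  planted <- base
  planted[1, 2] <- planted[2, 1] <- 0.8
  planted[2, 3] <- planted[3, 2] <- 0.8
  planted[1, 3] <- planted[3, 1] <- 0.1
  planted2 <- planted                      # a second, weaker chord
  planted2[1, 4] <- planted2[4, 1] <- 0.1
  study_from_weights(
    list(planted, planted2, base, base),
    groups_of = c("case", "case", "control", "control"), parc = parc)
}

test_that("a subject with no semi-metric edges profiles to all zeros", {
  parc <- toy_parcellation()
  cl <- metric_closure(proximity_to_distance(
    proximity_graph(uniform_weights(4, 0.5), node_ids = parc$id)))
  prof <- subject_smp_profile(cl, build_hierarchy(parc))
  expect_true(all(prof[!is.na(prof)] == 0))
  expect_true(is.na(prof["right_hemisphere"]))  # single node, no pairs
})

test_that("a planted left-hemisphere edge yields left SMP 1/3", {
  st <- toy_study()
  prof <- subject_smp_profile(st$subjects[[1]]$closure, st$hierarchy)
  expect_equal(unname(prof["left_hemisphere"]), 1 / 3)
  expect_equal(unname(prof["whole_brain"]), 1 / 6)
  expect_equal(unname(prof["left_between_lobe"]), 1 / 2)
  # global classification: whole-brain count consistent with subset counts
  expect_equal(prof[["whole_brain"]] * 6, prof[["left_hemisphere"]] * 3)
})

test_that("Welch test reproduces the closed-form values", {
  row <- smp_group_test(c(0.3, 0.4, 0.5), c(0.6, 0.7, 0.8), "toy")
  expect_equal(row$difference, -0.3)
  se <- sqrt(0.01 / 3 + 0.01 / 3)
  expect_equal(row$t, -0.3 / se, tolerance = 1e-12)
  expect_equal(row$t, -3.674, tolerance = 1e-3)
  expect_equal(row$df, 4)
  ci_half <- qt(0.975, 4) * se
  expect_equal(c(row$ci_lower, row$ci_upper),
               c(-0.3 - ci_half, -0.3 + ci_half))
  expect_true(row$ci_lower <= row$difference &
                row$difference <= row$ci_upper)
})

test_that("identical groups give zero difference and p = 1", {
  row <- smp_group_test(c(0.3, 0.4, 0.5), c(0.3, 0.4, 0.5))
  expect_equal(row$difference, 0)
  expect_equal(row$p_value, 1)
})

test_that("swapping groups negates the difference and flips the CI", {
  a <- c(0.31, 0.42, 0.55, 0.6); b <- c(0.5, 0.52, 0.61)
  r1 <- smp_group_test(a, b)
  r2 <- smp_group_test(b, a)
  expect_equal(r2$difference, -r1$difference)
  expect_equal(r2$ci_lower, -r1$ci_upper)
  expect_equal(r2$ci_upper, -r1$ci_lower)
  expect_equal(r2$p_value, r1$p_value)
})

test_that("constant equal groups raise a degenerate-test condition", {
  expect_error(smp_group_test(c(0.2, 0.2), c(0.2, 0.2)),
               class = "semimetric_degenerate_test")
})

test_that("gating follows the parent p-values exactly", {
  gen <- make_group_study(seed = 21)
  tab <- gated_hierarchy_test(gen$study, alpha = 0.05)
  h <- gen$study$hierarchy
  p_of <- setNames(tab$p_value, tab$region_set)
  gated_of <- setNames(tab$gated, tab$region_set)
  for (k in seq_len(nrow(tab))) {
    parent <- h$parents[[tab$region_set[k]]]
    want <- is.na(parent) ||
      (isTRUE(gated_of[[parent]]) && p_of[[parent]] < 0.05)
    expect_identical(tab$gated[k], want)
  }
  # untested rows never carry a p-value; tested rows always do
  expect_true(all(is.na(tab$p_value[!tab$gated])))
  expect_true(all(!is.na(tab$p_value[tab$gated])))
})

test_that("a planted right-hemisphere effect opens only the right branch", {
  gen <- make_group_study(seed = 22)
  st <- gen$study
  profiles <- study_smp_profiles(st)
  # fabricate profiles: big right-hemisphere group effect, none elsewhere
  labels <- attr(profiles, "group")
  set.seed(1)
  fake <- matrix(rnorm(length(profiles), 0.3, 0.01), nrow(profiles),
                 ncol(profiles), dimnames = dimnames(profiles))
  fake[, "whole_brain"] <- rnorm(nrow(fake), 0.3, 0.005) +
    ifelse(labels == "case", 0.05, 0)
  fake[, "right_hemisphere"] <- rnorm(nrow(fake), 0.3, 0.005) +
    ifelse(labels == "case", 0.08, 0)
  attr(fake, "group") <- labels
  tab <- gated_hierarchy_test(st, profiles = fake)
  get <- function(nm, col) tab[tab$region_set == nm, col]
  expect_true(get("whole_brain", "gated"))
  expect_true(get("right_hemisphere", "gated"))
  expect_lt(get("right_hemisphere", "p_value"), 0.05)
  expect_true(get("right_occipital", "gated"))
  expect_gte(get("left_hemisphere", "p_value"), 0.05)
  expect_false(get("left_frontal", "gated"))
  expect_true(is.na(get("left_frontal", "p_value")))
})

test_that("whole-brain row of the gated table equals the plain Welch test", {
  st <- toy_study()
  profiles <- study_smp_profiles(st)
  labels <- attr(profiles, "group")
  tab <- suppressMessages(gated_hierarchy_test(st))
  direct <- smp_group_test(profiles[labels == "case", "whole_brain"],
                           profiles[labels == "control", "whole_brain"],
                           region_set = "whole_brain")
  expect_equal(tab[tab$region_set == "whole_brain", ], direct)
})

test_that("optional BH correction adds adjusted p-values for tested rows", {
  gen <- make_group_study(seed = 23)
  tab <- gated_hierarchy_test(gen$study, p_adjust = "BH")
  expect_true("p_adjusted" %in% names(tab))
  tested <- tab$gated
  expect_equal(tab$p_adjusted[tested],
               p.adjust(tab$p_value[tested], "BH"))
  expect_true(all(is.na(tab$p_adjusted[!tested])))
})

test_that("asymmetry index is (r - l)/(r + l) and U matches enumeration", {
  expect_equal((0.6 - 0.4) / (0.6 + 0.4), 0.2)
  gen <- make_group_study(seed = 24)
  res <- asymmetry_test(gen$study)
  expect_true(all(res$indices$index >= -1 & res$indices$index <= 1))
  idx_a <- res$indices$index[res$indices$group == "case"]
  idx_b <- res$indices$index[res$indices$group == "control"]
  u_brute <- sum(outer(idx_a, idx_b, `>`)) +
    0.5 * sum(outer(idx_a, idx_b, `==`))
  expect_equal(res$U, u_brute)
  # symmetric subjects get index 0
  sym <- res$indices$right == res$indices$left
  expect_true(all(res$indices$index[sym] == 0))
})

test_that("subjects with r + l = 0 are excluded with a warning", {
  parc <- toy_parcellation()
  base <- uniform_weights(4, 0.5)   # all metric: every SMP 0
  planted <- base
  planted[1, 2] <- planted[2, 1] <- 0.8
  planted[2, 3] <- planted[3, 2] <- 0.8
  planted[1, 3] <- planted[3, 1] <- 0.1
  st <- study_from_weights(list(planted, base, planted, planted),
                           groups_of = c("a", "a", "b", "b"), parc = parc)
  # right hemisphere has one node -> undefined; use left as both r and l
  prof <- study_smp_profiles(st)
  prof[, "right_hemisphere"] <- prof[, "left_hemisphere"]
  attr(prof, "group") <- attr(study_smp_profiles(st), "group")
  expect_warning(asymmetry_test(st, profiles = prof), "r \\+ l = 0")
})
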