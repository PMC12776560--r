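make_submission <- function(ref, sigmas, target_id = "T", seed0 = 1) {
  models <- lapply(seq_along(sigmas), function(i) {
    perturb_chain(ref, sigmas[i], seed = seed0 + i)
  })
  submission_set(target_id, models)
}

test_that("per_target_score takes the best over models x conformations", {
  ref <- generate_chain(30, "helix", seed = 11)
  sub <- make_submission(ref, c(3, 3, 0, 3, 3))
  sol <- solution_set("T", list(ref))
  expect_equal(per_target_score(sub, sol, "tm_align"), 1.0, tolerance = 1e-9)
  expect_equal(per_target_score(sub, sol, "rmsd"), 0, tolerance = 1e-7)

  # model matching only the second conformation still scores via the max
  alt <- generate_chain(30, "two_helix_bend", seed = 12, bend_angle = 80)
  sub2 <- make_submission(alt, c(0, 4, 4, 4, 4), seed0 = 20)
  sol2 <- solution_set("T", list(ref, alt))
  s_both <- per_target_score(sub2, sol2, "tm_align")
  s_alt <- per_target_score(sub2, solution_set("T", list(alt)), "tm_align")
  expect_equal(s_both, s_alt, tolerance = 1e-9)
  expect_equal(s_both, 1.0, tolerance = 1e-9)
})

test_that("per_target_score is monotone in added models and skips unscorable pairs", {
  ref <- generate_chain(25, "coil", seed = 13)
  sol <- solution_set("T", list(ref))
  sub4 <- submission_set("T", lapply(1:4, function(i) perturb_chain(ref, 2.5, seed = 30 + i)))
  sub5 <- submission_set("T", c(sub4$models, list(perturb_chain(ref, 0.3, seed = 40))))
  expect_gte(per_target_score(sub5, sol, "tm_align"),
             per_target_score(sub4, sol, "tm_align"))
  expect_lte(per_target_score(sub5, sol, "rmsd"),
             per_target_score(sub4, sol, "rmsd"))

  # a model with too few solved residues is skipped, not fatal
  husk <- ref
  husk$x[-(1:2)] <- husk$y[-(1:2)] <- husk$z[-(1:2)] <- NA_real_
  mixed <- submission_set("T", list(husk, perturb_chain(ref, 1, seed = 41)))
  expect_no_error(per_target_score(mixed, sol, "tm_align"))
  only_husk <- submission_set("T", list(husk))
  expect_error(per_target_score(only_husk, sol, "tm_align"),
               class = "rnascore_unscorable")
})

test_that("leaderboard_mean averages per group over present targets", {
  sc <- tibble::tibble(group = c("g1", "g1", "g2"),
                       target = c("t1", "t2", "t1"),
                       value = c(0.5, 0.7, 0.9))
  lb <- leaderboard_mean(sc)
  expect_equal(lb$mean_value[lb$group == "g1"], 0.6)
  expect_equal(lb$mean_value[lb$group == "g2"], 0.9)
  expect_equal(lb$n_targets, c(2L, 1L))
})

test_that("best_of_two combines per-target maxima then averages", {
  sc <- tibble::tibble(
    group = rep("g", 4), algorithm = rep(c("a1", "a2"), each = 2),
    target = rep(c("t1", "t2"), 2), value = c(0.8, 0.2, 0.3, 0.9))
  expect_equal(best_of_two(sc, "tm_align")$mean_value, mean(c(0.8, 0.9)))
  # identical algorithms reduce to the single-algorithm mean
  sc2 <- sc
  sc2$value <- rep(c(0.8, 0.2), 2)
  expect_equal(best_of_two(sc2, "tm_align")$mean_value, mean(c(0.8, 0.2)))
  # rmsd takes per-target minima
  expect_equal(best_of_two(sc, "rmsd")$mean_value, mean(c(0.3, 0.2)))
  # random instances match the brute-force combination
  set.seed(5)
  for (i in 1:5) {
    v <- matrix(runif(6), 2, 3)  # 2 algorithms x 3 targets
    tab <- tibble::tibble(group = "g",
                          algorithm = rep(c("a1", "a2"), each = 3),
                          target = rep(paste0("t", 1:3), 2),
                          value = c(v[1, ], v[2, ]))
    expect_equal(best_of_two(tab, "tm_align")$mean_value,
                 mean(pmax(v[1, ], v[2, ])))
  }
})

test_that("two-pass z-scores trim outliers and restandardize (worked example)", {
  vals <- c(0.9, 0.8, 0.85, 0.8, 0.75, 0.9, 0.85, 0.8, 0.85, 0.0)
  sc <- tibble::tibble(group = sprintf("g%02d", 1:10), target = "t1", value = vals)
  z <- zscores(sc, metric = "tm_align")

  # independent two-pass computation, spelled out
  m1 <- mean(vals); s1 <- sd(vals)
  z1 <- (vals - m1) / s1
  expect_lt(z1[10], -2)                      # the 0.0 group is an outlier
  keep <- vals[z1 >= -2]
  m2 <- mean(keep); s2 <- sd(keep)
  expect_equal(m2, 7.5 / 9)
  expect_equal(s2, 0.05)
  z_expected <- (vals - m2) / s2
  expect_equal(z$z, z_expected, tolerance = 1e-9)
  expect_equal(z$trimmed, c(rep(FALSE, 9), TRUE))
  # trimmed groups still receive a final z against pass-2 statistics
  expect_equal(z$z[10], (0 - 7.5 / 9) / 0.05, tolerance = 1e-9)
})

test_that("z-score edge rules: no outliers, all equal, rmsd negation, permutation", {
  sc <- tibble::tibble(group = paste0("g", 1:4), target = "t1",
                       value = c(0.5, 0.6, 0.7, 0.8))
  z <- zscores(sc, metric = "tm_align")
  expect_equal(z$z, (sc$value - mean(sc$value)) / sd(sc$value))  # pass2 == pass1
  expect_false(any(z$trimmed))

  zc <- zscores(tibble::tibble(group = paste0("g", 1:5), target = "t1",
                               value = rep(0.42, 5)), metric = "tm_align")
  expect_equal(zc$z, rep(0, 5))              # degenerate sd rule

  # rmsd is negated so larger z is better
  sr <- tibble::tibble(group = paste0("g", 1:3), target = "t1",
                       value = c(2, 4, 9))
  zr <- zscores(sr, metric = "rmsd")
  expect_gt(zr$z[1], zr$z[3])

  # permuting rows permutes outputs identically
  sc2 <- sc[c(3, 1, 4, 2), ]
  z2 <- zscores(sc2, metric = "tm_align")
  expect_equal(z2[order(z2$group), ]$z, z[order(z$group), ]$z)

  expect_error(zscores(tibble::tibble(group = "g1", target = "t1", value = 1)),
               class = "rnascore_input_error")
})

test_that("rank_groups uses competition ranking with direction by metric", {
  means <- tibble::tibble(
    group = rep(c("a", "b", "c"), 2),
    metric = rep(c("tm_align", "rmsd"), each = 3),
    mean_value = c(0.9, 0.7, 0.8, 2.0, 1.0, 3.0))
  rk <- rank_groups(means)
  expect_equal(rk$rank[rk$metric == "tm_align"], c(1L, 3L, 2L))
  expect_equal(rk$rank[rk$metric == "rmsd"], c(2L, 1L, 3L))  # lower rmsd is better

  tied <- tibble::tibble(group = c("a", "b", "c"), metric = "tm_align",
                         mean_value = c(0.8, 0.8, 0.5))
  expect_equal(rank_groups(tied)$rank, c(1L, 1L, 3L))
})

test_that("compare_groups runs a paired one-sided t-test with degenerate handling", {
  targets <- paste0("t", 1:10)
  base <- runif(10, 0.3, 0.7)
  sc_eq <- tibble::tibble(group = rep(c("a", "b"), each = 10),
                          target = rep(targets, 2), value = rep(base, 2))
  expect_equal(compare_groups(sc_eq, "a", "b")$p_value, 0.5)

  sc_const <- sc_eq
  sc_const$value[1:10] <- base + 0.2  # a uniformly better, zero variance
  expect_lt(compare_groups(sc_const, "a", "b")$p_value, 1e-6)

  set.seed(17)
  for (i in 1:5) {
    va <- runif(8); vb <- va + rnorm(8, 0.05, 0.1)
    sc <- tibble::tibble(group = rep(c("a", "b"), each = 8),
                         target = rep(paste0("t", 1:8), 2), value = c(va, vb))
    ours <- compare_groups(sc, "a", "b")
    oracle <- t.test(va, vb, paired = TRUE, alternative = "greater")
    expect_equal(ours$p_value, unname(oracle$p.value), tolerance = 1e-12)
    expect_equal(ours$statistic, unname(oracle$statistic), tolerance = 1e-9)
  }
  expect_error(compare_groups(sc_eq[c(1, 2, 11, 12), ], "a", "b"),
               class = "rnascore_input_error")
})

test_that("the fold-correctness classifier applies the 0.45 threshold", {
  expect_equal(is_correct_fold(c(0.44, 0.45, 0.46)), c(FALSE, FALSE, TRUE))
})
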