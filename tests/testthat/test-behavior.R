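## small 3-group toy table used across tests
toy_ratings <- function() {
  data.frame(
    participant = rep(1:6, times = 3),
    run = 1,
    condition = rep(c("g1", "g2", "g3"), each = 6),
    rating = c(1, 2, 2, 3, 1, 2,    # g1
               3, 4, 3, 5, 4, 4,    # g2
               2, 3, 2, 2, 3, 2))   # g3
}

test_that("Kruskal-Wallis H matches the brute-force rank-sum oracle", {
  tab <- toy_ratings()
  out <- kruskal_wallis(tab)
  ## independent oracle: ranks, tie-corrected H
  x <- tab$rating
  g <- tab$condition
  r <- rank(x)
  N <- length(x)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * mean(ri)^2)) - 3 * (N + 1)
  ties <- table(x)
  H <- H / (1 - sum(ties^3 - ties) / (N^3 - N))
  expect_equal(out$H, H, tolerance = 1e-10)
  expect_equal(out$df, 2)
  expect_equal(out$p, stats::pchisq(H, 2, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("five groups give df = 4, identical groups give H = 0", {
  tab <- simulate_ratings(20, rng_seed = 3)
  out <- kruskal_wallis(tab)
  expect_equal(out$df, 4)
  flat <- data.frame(participant = 1:10, run = 1,
                     condition = rep(c("a", "b"), 5), rating = 3)
  out0 <- kruskal_wallis(flat)
  expect_equal(out0$H, 0)
  expect_equal(out0$p, 1)
})

test_that("H is invariant under strictly monotone transforms of ratings", {
  tab <- toy_ratings()
  h1 <- kruskal_wallis(tab)$H
  tab2 <- tab
  tab2$rating <- sqrt(tab$rating) + 0.01 * tab$rating  # monotone, stays in 0-5
  expect_equal(kruskal_wallis(tab2)$H, h1, tolerance = 1e-10)
})

test_that("Games-Howell agrees with an independent formula evaluation", {
  tab <- toy_ratings()
  gh <- games_howell(tab)
  ## oracle for the g1-g2 pair, computed from first principles
  x <- tab$rating[tab$condition == "g1"]
  y <- tab$rating[tab$condition == "g2"]
  se2 <- var(x) / 6 + var(y) / 6
  q_oracle <- abs(mean(x) - mean(y)) / sqrt(se2 / 2)
  df_oracle <- se2^2 / ((var(x) / 6)^2 / 5 + (var(y) / 6)^2 / 5)
  row <- gh[gh$group1 == "g1" & gh$group2 == "g2", ]
  expect_equal(row$q, q_oracle, tolerance = 1e-10)
  expect_equal(row$df, df_oracle, tolerance = 1e-10)
  expect_equal(row$p, stats::ptukey(q_oracle, 3, df_oracle,
                                    lower.tail = FALSE), tolerance = 1e-10)
  expect_true(all(gh$p >= 0 & gh$p <= 1))
  ## equal-variance balanced pair: Welch df equals the pooled 2n - 2
  bal <- data.frame(participant = 1:8, run = 1,
                    condition = rep(c("a", "b"), each = 4),
                    rating = c(1, 2, 3, 4, 2, 3, 4, 5))
  expect_equal(games_howell(bal)$df, 2 * 4 - 2, tolerance = 1e-10)
  ## identical groups: q = 0, p = 1
  same <- data.frame(participant = 1:8, run = 1,
                     condition = rep(c("a", "b"), each = 4),
                     rating = rep(c(1, 2, 3, 4), 2))
  row0 <- games_howell(same)
  expect_equal(row0$q, 0)
  expect_equal(row0$p, 1, tolerance = 1e-10)
})

test_that("Games-Howell p-values are symmetric in group order", {
  tab <- toy_ratings()
  gh1 <- games_howell(tab)
  tab_rev <- tab[nrow(tab):1, ]
  tab_rev$condition <- factor(tab_rev$condition,
                              levels = c("g3", "g2", "g1"))
  gh2 <- games_howell(tab_rev)
  for (i in seq_len(nrow(gh1))) {
    match_row <- gh2[(gh2$group1 == gh1$group1[i] &
                        gh2$group2 == gh1$group2[i]) |
                       (gh2$group1 == gh1$group2[i] &
                          gh2$group2 == gh1$group1[i]), ]
    expect_equal(match_row$p, gh1$p[i], tolerance = 1e-10)
    expect_equal(match_row$q, gh1$q[i], tolerance = 1e-10)
  }
})

test_that("Bonferroni pairwise t uses the pair-count multiplier with capping", {
  tab <- simulate_ratings(15, rng_seed = 5)
  bp <- bonferroni_pairwise_t(tab)
  expect_equal(nrow(bp), choose(5, 2))  # 10 pairs for 5 groups
  expect_equal(bp$p_adj, pmin(1, bp$p * 10), tolerance = 1e-12)
  expect_true(all(bp$p_adj <= 1))
  same <- data.frame(participant = 1:8, run = 1,
                     condition = rep(c("a", "b"), each = 4), rating = 2)
  expect_equal(bonferroni_pairwise_t(same)$p_adj, 1)
})

test_that("condition means exclude nonanswers and flag degenerate cells", {
  tab <- data.frame(participant = 1:6, run = 1,
                    condition = rep(c("face_chord", "noface_nochord"), 3),
                    rating = c(4, 2, 5, 1, 4, 0))
  cm <- condition_means(tab)
  expect_equal(cm$condition[1], "face_chord")           # highest mean first
  expect_equal(cm$n[cm$condition == "noface_nochord"], 2)  # the 0 is dropped
  zero <- data.frame(participant = 1, run = 1, condition = "face_chord",
                     rating = 0)
  expect_true(condition_means(zero)$flagged)
  single <- data.frame(participant = 1, run = 1, condition = "a", rating = 3)
  out1 <- condition_means(single)
  expect_true(is.na(out1$se))
  expect_true(out1$flagged)
  expect_error(kruskal_wallis(data.frame(participant = 1, run = 1,
                                         condition = "a", rating = 7)),
               "0..5")
})

test_that("synthetic ratings reproduce the reported qualitative structure", {
  tab <- simulate_ratings(40, rng_seed = 1)
  kw <- kruskal_wallis(tab)
  expect_equal(kw$df, 4)
  expect_lt(kw$p, 0.001)
  cm <- condition_means(tab)
  expect_equal(cm$condition[1], "face_chord")
  expect_equal(cm$condition[nrow(cm)], "noface_nochord")
  gh <- games_howell(tab)
  extreme <- gh[which.max(gh$q), ]
  expect_setequal(c(extreme$group1, extreme$group2),
                  c("face_chord", "noface_nochord"))
})
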