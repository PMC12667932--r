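test_that("tie-averaged ranking behaves on the worked examples", {
  expect_equal(rank_with_ties(c(0.9, 0.7, 0.9)), c(1.5, 3, 1.5))
  expect_equal(sort(rank_with_ties(c(0.3, 0.9, 0.5))), 1:3)
  expect_equal(rank_with_ties(0.4), 1)
  expect_equal(rank_with_ties(c(2, 1), higher_is_better = FALSE), c(2, 1))
  expect_error(rank_with_ties(c(1, NaN)), "NA")
})

test_that("log-normalized score evaluates the printed formula", {
  expect_equal(lognorm_score(1, 1), log(2))
  expect_equal(lognorm_score(3, 3), -log(3 / 4))
  expect_gt(lognorm_score(3, 3), 0)
  # improving any single rank strictly increases the score
  expect_gt(lognorm_score(c(1, 2), 4), lognorm_score(c(2, 2), 4))
  expect_error(lognorm_score(5, 4), "\\[1, N\\]")
})

test_that("hierarchical aggregation reproduces a hand-computed example", {
  # 2 teams, 1 TF, 1 platform, 2 benchmarks; alpha wins b1, beta wins b2
  # with a larger margin-free rank structure:
  tab <- data.frame(
    team = rep(c("alpha", "beta"), each = 2),
    submission = "s1", tf = "TF1", platform = "CHS",
    negative_kind = rep("shades", 4),
    metric = rep(c("auroc", "auprc"), 2),
    value = c(0.9, 0.6, 0.8, 0.7))
  rk <- hierarchical_aggregate(tab)
  # level 1 ranks: auroc alpha 1 beta 2; auprc alpha 2 beta 1
  b <- rk$benchmark
  expect_equal(b$rank[b$team == "alpha" & grepl("auroc", b$benchmark)], 1)
  expect_equal(b$rank[b$team == "alpha" & grepl("auprc", b$benchmark)], 2)
  # level 2 scores: both teams -log(1/3) - log(2/3): a tie
  s_exp <- -log(1 / 3) - log(2 / 3)
  expect_equal(rk$experiment_tf$score, rep(s_exp, 2))
  expect_equal(rk$experiment_tf$rank, rep(1.5, 2))
  expect_equal(rk$overall$rank, rep(1.5, 2))
})

test_that("single benchmark aggregation preserves the metric order", {
  tab <- data.frame(team = c("a", "b", "c"), submission = "s1", tf = "TF1",
                    platform = "CHS", negative_kind = "random",
                    metric = "auroc", value = c(0.7, 0.9, 0.5))
  rk <- hierarchical_aggregate(tab)
  expect_equal(rk$overall$team, c("b", "a", "c"))
  expect_equal(rk$overall$rank, 1:3)
})

test_that("aggregation is row-order invariant and label-equivariant", {
  tab <- toy_metric_table(seed = 11)
  rk1 <- hierarchical_aggregate(tab)
  rk2 <- hierarchical_aggregate(tab[sample(nrow(tab)), ])
  expect_equal(rk1$overall, rk2$overall)
  # permuting team labels permutes the output identically
  swap <- c(alpha = "beta", beta = "gamma", gamma = "alpha")
  tab2 <- tab
  tab2$team <- unname(swap[tab2$team])
  rk3 <- hierarchical_aggregate(tab2)
  o1 <- rk1$overall; o3 <- rk3$overall
  expect_equal(o3$rank[match(unname(swap[o1$team]), o3$team)], o1$rank)
})

test_that("a team dominating every benchmark ranks first at every level", {
  tab <- toy_metric_table(seed = 12)
  tab$value[tab$team == "beta"] <- tab$value[tab$team == "beta"] / 2
  tab$value[tab$team == "alpha"] <- 0.95 + runif(sum(tab$team == "alpha")) / 100
  rk <- hierarchical_aggregate(tab)
  expect_equal(rk$overall$team[1], "alpha")
  expect_equal(rk$overall$rank[1], 1)
  expect_true(all(rk$team_tf$rank[rk$team_tf$team == "alpha"] == 1))
  expect_true(all(rk$experiment_tf$rank[rk$experiment_tf$team == "alpha"] == 1))
})

test_that("all-equal metrics tie every team at every level", {
  tab <- toy_metric_table(values = 0.5)
  rk <- hierarchical_aggregate(tab)
  expect_true(all(rk$overall$rank == 2))
  expect_true(all(rk$team_tf$rank == 2))
})

test_that("missing submissions receive the lowest possible rank", {
  tab <- toy_metric_table(seed = 13)
  # drop one TF entirely for team gamma
  tab_miss <- tab[!(tab$team == "gamma" & tab$tf == "TF2"), ]
  filled <- penalize_missing(tab_miss, teams = c("alpha", "beta", "gamma"))
  expect_equal(nrow(filled), nrow(tab))
  rk <- hierarchical_aggregate(filled)
  g_tf2 <- rk$benchmark[rk$benchmark$team == "gamma" &
                          rk$benchmark$tf == "TF2", ]
  expect_true(all(g_tf2$rank == 3))
  # no missing cells: table unchanged
  expect_equal(nrow(penalize_missing(tab)), nrow(tab))
  # a team missing everything ranks last overall
  filled2 <- penalize_missing(tab, teams = c("alpha", "beta", "gamma", "ghost"))
  rk2 <- hierarchical_aggregate(filled2)
  expect_equal(rk2$overall$team[4], "ghost")
  expect_equal(rk2$overall$rank[4], 4)
})

test_that("aggregation handles partially missing tables without penalty rows", {
  tab <- toy_metric_table(seed = 14)
  tab_miss <- tab[!(tab$team == "beta" & tab$metric == "auprc" &
                      tab$tf == "TF1" & tab$negative_kind == "shades"), ]
  rk <- hierarchical_aggregate(tab_miss)
  miss_row <- rk$benchmark[rk$benchmark$team == "beta" &
                             rk$benchmark$tf == "TF1" &
                             rk$benchmark$benchmark == "shades:auprc", ]
  expect_equal(miss_row$rank, 3)  # N solutions = 3
  expect_true(is.na(miss_row$value))
})

test_that("stability subsampling retains ~75% of cells and is seed-stable", {
  tab <- toy_metric_table(tfs = paste0("TF", 1:10),
                          platforms = c("CHS", "HTS"), seed = 15)
  st <- stability_analysis(tab, drop_prob = 0.25, n_reps = 60, seed = 21)
  expect_equal(mean(st$retained_fraction), 0.75, tolerance = 0.05)
  st2 <- stability_analysis(tab, drop_prob = 0.25, n_reps = 60, seed = 21)
  expect_equal(st$rank_freq, st2$rank_freq)
  # zero drop probability reproduces the full ranking in every replicate
  st0 <- stability_analysis(tab, drop_prob = 0, n_reps = 5, seed = 22)
  full <- hierarchical_aggregate(tab)$overall
  for (tm in full$team) {
    f <- st0$rank_freq[st0$rank_freq$team == tm, ]
    expect_equal(nrow(f), 1)
    expect_equal(f$rank, full$rank[full$team == tm])
    expect_equal(f$frequency, 1)
  }
})
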