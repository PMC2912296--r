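# liquid-vs-elastic discrimination and cohort statistics

test_that("elasticity index spans the liquid and Hookean ideals", {
  expect_equal(elasticity_index(1, 1, 1, 1.5), 0)       # ideal liquid
  expect_equal(elasticity_index(2, 3, 1, 1.5), 1)       # ideal elastic
  # published clone-L means: (5.8/5.5 - 1) / 0.52
  expect_equal(elasticity_index(5.5, 5.8, 1, 1.52),
               (5.8 / 5.5 - 1) / 0.52, tolerance = 1e-12)
  expect_equal(round(elasticity_index(5.5, 5.8, 1, 1.52), 3), 0.105)
  expect_error(elasticity_index(1, 1, 1.5, 1.5), "second compression")
  expect_error(elasticity_index(1, 1, 2, 1), "second compression")
})

test_that("classification thresholds E at 0.5 with ties elastic, scale invariant", {
  expect_equal(classify_aggregate(0), "liquid")
  expect_equal(classify_aggregate(1), "elastic")
  expect_equal(classify_aggregate(0.5), "elastic")  # boundary goes elastic
  expect_equal(classify_aggregate(c(0.1, 0.9)), c("liquid", "elastic"))
  # multiplying sigmas or forces by a positive constant leaves E unchanged
  set.seed(1)
  for (i in 1:50) {
    s1 <- runif(1, 2, 12); s2 <- s1 * runif(1, 0.9, 1.8)
    F1 <- runif(1, 0.05, 0.3); F2 <- F1 * runif(1, 1.2, 3)
    k <- runif(1, 0.1, 10)
    E0 <- elasticity_index(s1, s2, F1, F2)
    expect_equal(elasticity_index(k * s1, k * s2, F1, F2), E0)
    expect_equal(elasticity_index(s1, s2, k * F1, k * F2), E0)
  }
})

test_that("paired sigma test handles degenerate and regular cohorts", {
  expect_equal(paired_sigma_test(rep(5, 4), rep(5, 4))$p.value, 1)
  expect_error(paired_sigma_test(c(1, 1, 1, 1), c(2, 2, 2, 2)),
               "degenerate variance")
  expect_error(paired_sigma_test(1, 2), "insufficient pairs")
  # agrees with stats::t.test
  set.seed(2)
  s1 <- runif(10, 5, 6); s2 <- s1 + rnorm(10, 0, 0.2)
  ref <- t.test(s2, s1, paired = TRUE)
  got <- paired_sigma_test(s1, s2)
  expect_equal(got$statistic, unname(ref$statistic))
  expect_equal(got$p.value, ref$p.value)
})

test_that("liquid cohorts rarely reject sigma1 = sigma2 (paired t property)", {
  n_ok <- 0
  for (s in 1:200) {
    cfg <- sim_config(seed = s, noise_F = 0.02, noise_geom = 0.02)
    rec <- analyze_compressions(simulate_cohort(20, 1.0, cfg))
    if (paired_sigma_test(rec$sigma1, rec$sigma2)$p.value > 0.05) {
      n_ok <- n_ok + 1
    }
  }
  expect_gte(n_ok, 0.90 * 200)
})

test_that("pooled two-proportion z matches the textbook formula", {
  expect_equal(two_proportion_z(0.4, 30, 0.4, 50), 0)
  # p1 = 0.5, p2 = 0.3, n = 50 each: pbar = 0.4, se = sqrt(0.24 * 0.04)
  expect_equal(two_proportion_z(0.5, 50, 0.3, 50),
               0.2 / sqrt(0.24 * 0.04), tolerance = 1e-12)
  expect_equal(round(two_proportion_z(0.5, 50, 0.3, 50), 4), 2.0412)
  expect_error(two_proportion_z(1.2, 10, 0.5, 10), "not a proportion")
  expect_error(two_proportion_z(0, 10, 0, 10), "degenerate pooled")
})

test_that("cohort table reproduces the published sigma2/sigma1 ratios", {
  cm <- clone_means()
  for (i in seq_len(nrow(cm))) {
    rec <- records_with_means(cm$sigma1_mean[i], cm$sigma2_mean[i],
                              ratio_F = cm$ratio_F[i], clone = cm$clone[i])
    stats <- cohort_liquidity_table(rec)
    expect_equal(stats$ratio_sigma, cm$ratio_sigma[i],
                 label = paste("clone", cm$clone[i]))
    expect_equal(stats$ratio_F, cm$ratio_F[i])
  }
})

test_that("cohort table degenerate and error paths", {
  # all-identical liquid records: ratio 1, all liquid, p = 1
  rec <- data.frame(aggregate_id = paste0("a", 1:4), clone = "M",
                    sFn_ug_ml = 30, sigma1 = 7, sigma2 = 7,
                    F1 = 0.1, F2 = 0.2, V_um3 = 1e7)
  stats <- cohort_liquidity_table(rec)
  expect_equal(stats$ratio_sigma, 1.00)
  expect_equal(stats$frac_liquid, 100)
  expect_equal(stats$frac_liquid + stats$frac_elastic, 100)
  expect_equal(stats$p_paired, 1)
  mixed <- rbind(rec, transform(rec, clone = "H"))
  expect_error(cohort_liquidity_table(mixed), "heterogeneous cohort")
  expect_error(cohort_liquidity_table(rec[1, ]), "insufficient records")
})

test_that("fraction of liquid and elastic aggregates sums to 100", {
  expect_equal(fraction_liquid(rep("liquid", 20)),
               c(pct_liquid = 100, pct_elastic = 0))
  expect_equal(fraction_liquid(c(rep("liquid", 19), "elastic")),
               c(pct_liquid = 95, pct_elastic = 5))
  expect_error(fraction_liquid(character(0)), "no records")
  set.seed(3)
  for (i in 1:20) {
    v <- sample(c("liquid", "elastic"), sample(1:40, 1), replace = TRUE)
    expect_equal(sum(fraction_liquid(v)), 100)
  }
})

test_that("volume independence regression: exact cases and liquid property", {
  # constant sigma: flat line, r2 = 0
  rec <- data.frame(sigma = rep(5, 5), V_um3 = c(1, 2, 3, 4, 5) * 1e7)
  fit <- volume_independence(rec)
  expect_equal(fit$slope, 0)
  expect_equal(fit$r2, 0)
  # perfect line: r2 = 1
  fit2 <- volume_independence(data.frame(sigma = c(1, 2, 3), V_um3 = c(1, 2, 3)))
  expect_equal(fit2$r2, 1)
  expect_equal(fit2$slope, 1)
  expect_error(volume_independence(data.frame(sigma = c(1, 2), V_um3 = c(1, 2))),
               "insufficient data")
  expect_error(volume_independence(data.frame(sigma = c(1, 2, 3), V_um3 = rep(1, 3))),
               "degenerate regressor")
  # only liquid-verdict records enter the fit
  rec3 <- data.frame(sigma1 = c(5, 5, 5, 50), sigma2 = c(5, 5, 5, 50),
                     V_um3 = c(1, 2, 3, 4) * 1e7,
                     verdict = c("liquid", "liquid", "liquid", "elastic"))
  expect_equal(volume_independence(rec3)$slope, 0)
})

test_that("group comparison: ANOVA + Tukey behave on known structures", {
  g <- list(a = c(5, 6, 5.5, 5.2), b = c(5, 6, 5.5, 5.2))
  res <- compare_groups_sigma(g)
  expect_lt(res$F, 1e-20)
  expect_gt(res$pairwise$p_adj[1], 0.99)
  # two groups: ANOVA F equals the squared pooled-variance t statistic
  set.seed(4)
  x <- rnorm(12, 5, 1); y <- rnorm(10, 6, 1)
  res2 <- compare_groups_sigma(list(x = x, y = y))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(res2$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res2$p, tt$p.value, tolerance = 1e-10)
  expect_error(compare_groups_sigma(list(a = 1, b = c(1, 2))),
               "insufficient group size")
  # one high-tension group among equals: only its pairwise contrasts significant
  n_good <- 0
  for (s in 1:100) {
    set.seed(s)
    g4 <- list(L = rnorm(20, 5.5, 0.3), M = rnorm(20, 10.4, 0.7),
               H = rnorm(20, 5.5, 0.3), HH = rnorm(20, 5.6, 0.16))
    res4 <- compare_groups_sigma(g4)
    with_M <- grepl("M", sub("HH", "", res4$pairwise$contrast))
    ok <- all(res4$pairwise$p_adj[with_M] < 0.001) &&
      all(res4$pairwise$p_adj[!with_M] > 0.001)
    n_good <- n_good + ok
  }
  expect_gte(n_good, 95)
})

test_that("summarize_cohorts produces one row per clone x condition", {
  rec <- rbind(records_with_means(5.5, 5.8, clone = "L"),
               records_with_means(10.4, 10.6, clone = "M"))
  out <- summarize_cohorts(rec)
  expect_equal(nrow(out), 2)
  expect_setequal(out$clone, c("L", "M"))
  expect_setequal(out$ratio_sigma, c(1.05, 1.02))
})
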