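test_that("permeability index is lower-chamber fluorescence over reference", {
  expect_equal(permeability_index(150, 100), 1.5)
  expect_equal(permeability_index(100, 100), 1.0)
  expect_error(permeability_index(100, 0), class = "frapkit_data_error")
  tab <- permeability_fold_table(c(100, 110, 150, 170),
                                 rep(c("basal", "Ad5"), each = 2), "basal")
  expect_equal(tab$fold_over_basal, c(100, 110, 150, 170) / 105)
})

test_that("group summaries report mean, sample sd and SEM", {
  s <- summarize_groups(c(1, 2, 3), rep("a", 3))
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  expect_equal(s$sem, 1 / sqrt(3))
  # single observation: undefined spread markers
  s1 <- summarize_groups(5, "a")
  expect_equal(s1$mean, 5)
  expect_true(is.na(s1$sd) && is.na(s1$sem))
  # constant group
  s0 <- summarize_groups(rep(7, 4), rep("a", 4))
  expect_equal(s0$sd, 0)
  expect_equal(s0$sem, 0)
})

test_that("one-way ANOVA reproduces the hand-computed decomposition", {
  res <- anova_one_way(c(1, 2, 3, 4, 5, 6), rep(c("g1", "g2"), each = 3))
  # by hand: grand 3.5; SSB = 3*(2-3.5)^2 + 3*(5-3.5)^2 = 13.5; SSW = 4
  expect_equal(res$sumsq, c(13.5, 4))
  expect_equal(res$df, c(1L, 4L))
  expect_equal(res$statistic[1], 13.5)
  expect_equal(res$p.value[1],
               stats::pf(13.5, 1, 4, lower.tail = FALSE))
})

test_that("identical groups give F = 0 and p = 1", {
  res <- anova_one_way(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_equal(res$statistic[1], 0)
  expect_equal(res$p.value[1], 1)
})

test_that("two-group one-way F equals the squared pooled t statistic", {
  set.seed(7)
  for (i in 1:5) {
    x <- rnorm(6); y <- rnorm(5, mean = 1)
    res <- anova_one_way(c(x, y), rep(c("x", "y"), c(6, 5)))
    tt <- stats::t.test(x, y, var.equal = TRUE)
    expect_equal(res$statistic[1], unname(tt$statistic)^2, tolerance = 1e-12)
    expect_equal(res$p.value[1], tt$p.value, tolerance = 1e-12)
  }
})

test_that("one-way results agree with stats::aov", {
  set.seed(11)
  v <- rnorm(18, mean = rep(c(0, 0.5, 2), each = 6))
  g <- rep(c("a", "b", "c"), each = 6)
  res <- anova_one_way(v, g)
  ref <- summary(stats::aov(v ~ g))[[1]]
  expect_equal(res$sumsq, ref$`Sum Sq`, tolerance = 1e-12)
  expect_equal(res$statistic[1], ref$`F value`[1], tolerance = 1e-12)
  expect_equal(res$p.value[1], ref$`Pr(>F)`[1], tolerance = 1e-12)
})

test_that("one-way p agrees with a permutation p on a small table", {
  set.seed(13)
  v <- c(rnorm(5), rnorm(5, mean = 1.2))
  g <- rep(c("a", "b"), each = 5)
  res <- anova_one_way(v, g)
  f_obs <- f_stat_oneway(v, g)
  n_perm <- 10000
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    if (f_stat_oneway(v, sample(g)) >= f_obs) exceed <- exceed + 1L
  }
  p_perm <- (exceed + 1) / (n_perm + 1)
  # Monte-Carlo standard error ~ sqrt(p(1-p)/n); allow 4 sigma
  se <- sqrt(p_perm * (1 - p_perm) / n_perm)
  expect_lt(abs(res$p.value[1] - p_perm), 4 * se + 0.005)
})

test_that("groups with fewer than 2 observations are refused", {
  expect_error(anova_one_way(c(1, 2, 3), c("a", "a", "b")),
               class = "frapkit_data_error")
  expect_error(anova_one_way(c(1, 2), c("a", "a")),
               class = "frapkit_data_error")
})

test_that("two-way ANOVA reproduces the brute-force mean decomposition", {
  d <- expand.grid(factorA = c("a1", "a2"), factorB = c("b1", "b2"),
                   rep = 1:2)
  d$value <- c(1, 3, 5, 7, 2, 4, 6, 8)  # cells {1,2},{3,4},{5,6},{7,8}
  res <- anova_two_way(d)
  # brute force from cell/marginal/grand means:
  # grand 4.5; A means 3.5/5.5 -> SS_A = 8; B means 2.5/6.5 -> SS_B = 32;
  # cell means 1.5,3.5,5.5,7.5 are additive -> SS_AB = 0; resid = 8 * 0.25
  expect_equal(res$sumsq, c(8, 32, 0, 2))
  expect_equal(res$df, c(1L, 1L, 1L, 4L))
  expect_equal(res$statistic[1:3], c(16, 64, 0))
})

test_that("constant tables give all-zero F statistics", {
  d <- expand.grid(factorA = c("a1", "a2"), factorB = c("b1", "b2"),
                   rep = 1:3)
  d$value <- 5
  res <- anova_two_way(d)
  expect_equal(res$statistic[1:3], c(0, 0, 0))
  expect_equal(res$p.value[1:3], c(1, 1, 1))
})

test_that("balanced sums of squares are additive and match stats::aov", {
  set.seed(23)
  for (i in 1:5) {
    d <- expand.grid(factorA = c("a1", "a2", "a3"),
                     factorB = c("b1", "b2"), rep = 1:4)
    d$value <- rnorm(nrow(d), mean = as.integer(factor(d$factorA)) +
                       2 * as.integer(factor(d$factorB)))
    res <- anova_two_way(d)
    total <- sum((d$value - mean(d$value))^2)
    expect_equal(sum(res$sumsq), total, tolerance = 1e-9)
    ref <- summary(stats::aov(value ~ factorA * factorB, data = d))[[1]]
    expect_equal(res$sumsq, ref$`Sum Sq`, tolerance = 1e-9)
    expect_equal(res$statistic[1:3], ref$`F value`[1:3], tolerance = 1e-9)
    expect_equal(res$p.value[1:3], ref$`Pr(>F)`[1:3], tolerance = 1e-9)
  }
})

test_that("unbalanced designs are an explicit error, not an approximation", {
  d <- expand.grid(factorA = c("a1", "a2"), factorB = c("b1", "b2"),
                   rep = 1:2)
  d$value <- rnorm(8)
  expect_error(anova_two_way(d[-1, ]), "unbalanced",
               class = "frapkit_data_error")
  # singleton cells are also refused
  d1 <- d[d$rep == 1, ]
  expect_error(anova_two_way(d1), class = "frapkit_data_error")
})

test_that("additive truth yields a near-null interaction F over simulations", {
  cm <- outer(c(1, 2), c(0, 3), "+")
  rownames(cm) <- c("a1", "a2"); colnames(cm) <- c("b1", "b2")
  f_int <- vapply(1:200, function(i) {
    sim <- simulate_assay_table(sim_assay_config(cm, n_replicates = 5,
                                                 noise_sd = 1, seed = 3000 + i))
    anova_two_way(sim$table)$statistic[3]
  }, 0)
  # interaction F has null expectation df2/(df2 - 2) = 16/14
  expect_equal(mean(f_int), 16 / 14, tolerance = 0.25)
})
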