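test_that("median split puts median-valued scores in the low group", {
  s <- median_split(c(10, 20))
  expect_equal(s$threshold, 15)
  expect_equal(length(s$low_ids), 1)
  expect_equal(length(s$high_ids), 1)

  # 21 scores, median attained: 11 low / 10 high as in the published cohort
  scores <- c(3, 5, 8, 10, 11, 11, 12, 13, 14, 14, 15,
              16, 18, 20, 22, 25, 26, 27, 29, 32, 33)
  s21 <- median_split(scores)
  expect_equal(s21$threshold, 15)
  expect_equal(length(s21$low_ids), 11)
  expect_equal(length(s21$high_ids), 10)

  expect_warning(sall <- median_split(rep(7, 5)), "empty high group")
  expect_equal(length(sall$low_ids), 5)
})

test_that("JZS t Bayes factors are even, monotone and log-consistent", {
  b1 <- bf_ttest_jzs(1.5, 11, 10)
  b2 <- bf_ttest_jzs(-1.5, 11, 10)
  expect_equal(b1$bf10, b2$bf10, tolerance = 1e-9)
  expect_equal(b1$log10_bf10, log10(b1$bf10), tolerance = 1e-12)
  ts <- c(0, 0.5, 1, 2, 3, 5)
  bfs <- vapply(ts, function(t) bf_ttest_jzs(t, 11, 10)$bf10, numeric(1))
  expect_true(all(diff(bfs) > 0))
  expect_lt(bfs[1], 1)
})

test_that("correlation Bayes factors are even, monotone and log-consistent", {
  for (pr in c("jzs", "stretched_beta")) {
    b1 <- bf_pearson(0.4, 21, prior = pr)
    b2 <- bf_pearson(-0.4, 21, prior = pr)
    expect_equal(b1$bf10, b2$bf10, tolerance = 1e-8)
    expect_equal(b1$log10_bf10, log10(b1$bf10), tolerance = 1e-12)
    rs <- c(0, 0.2, 0.4, 0.6, 0.8)
    bfs <- vapply(rs, function(r) bf_pearson(r, 21, prior = pr)$bf10,
                  numeric(1))
    expect_true(all(diff(bfs) > 0))
    expect_lt(bfs[1], 1)
  }
})

test_that("Bayes factors match dense-grid quadrature oracles", {
  for (t in c(0, 0.62, 1.8, 3.32)) {
    for (nn in list(c(11, 10), c(15, 15))) {
      got <- bf_ttest_jzs(t, nn[1], nn[2])$bf10
      expect_equal(got, oracle_bf_ttest(t, nn[1], nn[2]),
                   tolerance = 1e-6)
      got_p <- bf_ttest_jzs(t, nn[1], nn[2], effective_n = "pooled")$bf10
      expect_equal(got_p, oracle_bf_ttest(t, nn[1], nn[2],
                                          effective_n = "pooled"),
                   tolerance = 1e-6)
    }
  }
  for (r in c(-0.5, 0, 0.24, 0.72)) {
    for (n in c(10, 21)) {
      expect_equal(bf_pearson(r, n)$bf10, oracle_bf_pearson_jzs(r, n),
                   tolerance = 1e-6)
      expect_equal(bf_pearson(r, n, prior = "stretched_beta")$bf10,
                   oracle_bf_pearson_sb(r, n),
                   tolerance = 1e-6)
    }
  }
})

test_that("Jarque-Bera matches moment oracles and the zero case", {
  # (-a, 0, 0, 0, 0, a) has zero skew and kurtosis exactly n/2 = 3
  x0 <- c(-2, 0, 0, 0, 0, 2, -2, 0, 0, 0, 0, 2)
  jb0 <- jarque_bera(x0)
  expect_equal(jb0$jb, 0, tolerance = 1e-8)

  set.seed(501)
  x <- rlnorm(20)
  jb <- jarque_bera(x)
  if (requireNamespace("e1071", quietly = TRUE)) {
    sk <- e1071::skewness(x, type = 1)
    ku <- e1071::kurtosis(x, type = 1)
    expect_equal(jb$jb, 20 / 6 * (sk^2 + ku^2 / 4), tolerance = 1e-10)
  }
  expect_equal(jb$p, pchisq(jb$jb, 2, lower.tail = FALSE), tolerance = 1e-12)
  expect_error(jarque_bera(rnorm(5)))
})

test_that("the repeated-measures ANOVA matches a hand-computed fixture", {
  # 3 subjects x 2 numerosity levels x 2 conditions
  d <- expand.grid(subject = c("s1", "s2", "s3"), A = c("a1", "a2"),
                   B = c("b1", "b2"), stringsAsFactors = FALSE)
  d$value <- c(4, 6, 5, 8, 9, 10, # b1: a1 then a2
               5, 6, 7, 12, 13, 15) # b2: a1 then a2
  tab <- rm_anova_2way(d)
  # hand-computed sums of squares for this table:
  # grand mean 8.3333; A means (5.5, 11.1667), B means (7, 9.6667)
  expect_equal(tab$ss[tab$effect == "A"], 3 * 2 * 2 * (8.3333333 - 5.5)^2,
               tolerance = 1e-5)
  expect_equal(tab$ss[tab$effect == "B"], 3 * 2 * 2 * (9.6666667 - 8.3333333)^2,
               tolerance = 1e-5)
  # and against the aov error-strata route
  fo <- oracle_rm_anova(d)
  expect_equal(tab$F[tab$effect == "A"], unname(fo["A"]), tolerance = 1e-8)
  expect_equal(tab$F[tab$effect == "B"], unname(fo["B"]), tolerance = 1e-8)
  expect_equal(tab$F[tab$effect == "A:B"], unname(fo["AB"]), tolerance = 1e-8)
  expect_equal(tab$df1, c(1, 1, 1))
  expect_equal(tab$df2, c(2, 2, 2))
})

test_that("constant data give zero F and missing cells error out", {
  d <- expand.grid(subject = 1:4, A = 1:3, B = 1:2)
  d$value <- rep(c(1, 2, 3, 4), 6) # subject effects only
  tab <- rm_anova_2way(d)
  expect_equal(tab$F, c(0, 0, 0))
  expect_error(rm_anova_2way(d[-1, ]), "complete and balanced")
})

test_that("classical r and t match hand-computed five-point values", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 7)
  ct <- pearson_r(x, y)
  # hand: sxy = 12, sxx = 10, syy = 21.2
  expect_equal(ct$r, 12 / sqrt(10 * 21.2), tolerance = 1e-12)
  expect_equal(pearson_r(x, x)$r, 1, tolerance = 1e-12)

  a <- c(4, 5, 6, 7)
  b <- c(1, 2, 3, 10)
  tt <- two_sample_t(a, b)
  sp2 <- (3 * var(a) + 3 * var(b)) / 6
  expect_equal(tt$t, (mean(a) - mean(b)) / sqrt(sp2 * (1 / 4 + 1 / 4)),
               tolerance = 1e-12)
  expect_equal(tt$df, 6)
  expect_equal(two_sample_t(a, a)$t, 0)
  expect_error(pearson_r(rep(1, 5), 1:5), "zero-variance")
})
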