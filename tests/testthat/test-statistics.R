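test_that("stage labels parse, order, and coarsen", {
  s <- parse_stage(c("f1a", "1b", "F2", "4"))
  expect_identical(as.character(s), c("F1a", "F1b", "F2", "F4"))
  expect_true(s[1] < s[2] && s[2] < s[3] && s[3] < s[4])
  expect_identical(as.character(coarse_stage(c("F1a", "F1c", "F3"))),
                   c("F1", "F1", "F3"))
  expect_error(parse_stage("F9"), "F9")
})

test_that("Fleiss kappa handles the canonical hand-computed cases", {
  # perfect agreement
  m <- matrix(rep(c("F2", "F3", "F4"), each = 4), 3, 4, byrow = TRUE)
  expect_equal(fleiss_kappa(m), 1.0)
  # all ratings in a single category: chance agreement 1, agreement perfect
  expect_equal(fleiss_kappa(matrix("F3", 5, 4)), 1.0)
  # 2 items, 2 raters, (A,B) and (B,A): P_bar = 0, Pe_bar = 0.5 -> -1
  m2 <- rbind(c("A", "B"), c("B", "A"))
  expect_equal(fleiss_kappa(m2), -1.0)
  expect_error(fleiss_kappa(matrix("A", 2, 1)), "raters")
})

test_that("Fleiss kappa matches the brute-force pair-counting oracle", {
  set.seed(21)
  for (i in 1:100) {
    n <- sample(4:15, 1); r <- sample(2:6, 1)
    k <- sample(2:4, 1)
    m <- matrix(sample(LETTERS[1:k], n * r, replace = TRUE), n, r)
    ko <- fleiss_oracle(m)
    if (!is.finite(ko)) next
    expect_equal(fleiss_kappa(m), ko, tolerance = 1e-12)
  }
})

test_that("kappa bands reproduce the printed agreement ranges", {
  expect_identical(kappa_band(0.44), "moderate")
  expect_identical(kappa_band(0.73), "substantial")
  expect_identical(kappa_band(0.405), "moderate")  # rounds to 0.41
  expect_identical(kappa_band(0.20), "slight")
  expect_identical(kappa_band(0.21), "fair")
  expect_identical(kappa_band(0.85), "almost perfect")
  expect_identical(kappa_band(0), "poor/none")
  expect_identical(kappa_band(-0.6), "poor/none")
  # total over [-1, 1]
  bands <- kappa_band(seq(-1, 1, by = 0.005))
  expect_true(all(bands %in% c("poor/none", "slight", "fair", "moderate",
                               "substantial", "almost perfect")))
  expect_error(kappa_band(1.5), "kappa")
})

test_that("paired t-test flags significance and rejects degenerate input", {
  expect_error(paired_t_test(c(1, 2, 3), c(2, 3, 4)), "zero variance")
  expect_error(paired_t_test(c(1, 2, 3), c(1, 2, 3)), "zero variance")
  expect_error(paired_t_test(1, 2), "n >= 2")
  set.seed(5)
  pre <- rnorm(200, 0, 1); post <- rnorm(200, 1, 1)
  res <- paired_t_test(pre, post)
  expect_true(res$significant)
  expect_lt(res$p_value, 0.05)
  expect_equal(res$mean_difference, mean(post - pre))
  # agrees with the reference implementation
  expect_equal(res$p_value, t.test(post, pre, paired = TRUE)$p.value)
})

test_that("ANOVA + Tukey behaves at the null and for two groups", {
  set.seed(8)
  x <- rnorm(30); g <- rep(c("a", "b", "c"), each = 10)
  null_same <- anova_tukey(rep(c(1, 2), 15), g)  # identical group means
  expect_lt(null_same$anova$F, 1e-20)
  expect_true(all(null_same$tukey$p_adj > 0.99))
  # two groups: Tukey p equals the pooled-variance t-test p
  x2 <- rnorm(20, mean = rep(c(0, 1), each = 10))
  g2 <- rep(c("a", "b"), each = 10)
  at <- anova_tukey(x2, g2)
  tt <- t.test(x2[g2 == "b"], x2[g2 == "a"], var.equal = TRUE)
  expect_equal(at$tukey$p_adj, tt$p.value, tolerance = 1e-9)
  expect_error(anova_tukey(rnorm(3), c("a", "a", "b")), ">= 2 members")
})

test_that("Tukey family-wise error is controlled under the null", {
  set.seed(31)
  nrej <- 0L; nsim <- 2000L
  g <- rep(c("a", "b", "c", "d"), each = 10)
  for (i in seq_len(nsim)) {
    res <- anova_tukey(rnorm(40), g)
    if (any(res$tukey$p_adj < 0.05)) nrej <- nrej + 1L
  }
  expect_lte(nrej / nsim, 0.07)
})

test_that("a stage-like ECA gradient is fully separated by Tukey", {
  set.seed(17)
  vals <- c(rnorm(10, 2.6, 0.4), rnorm(10, 5.7, 0.4), rnorm(10, 10.9, 0.8))
  g <- rep(c("F2", "F3", "F4"), each = 10)
  res <- anova_tukey(vals, g)
  expect_true(all(res$tukey$p_adj < 0.05))
  expect_lt(res$anova$p_value, 1e-4)
})

test_that("stage summaries match naive oracles", {
  s <- summarize_by_stage(c(2, 4, 6), rep("F2", 3))
  expect_equal(s$mean, 4); expect_equal(s$min, 2); expect_equal(s$max, 6)
  s1 <- summarize_by_stage(5, "F3")
  expect_equal(s1$sd, 0); expect_equal(s1$iqr, 0); expect_equal(s1$sem, 0)
  set.seed(3)
  v <- rnorm(37); g <- sample(c("F2", "F3"), 37, replace = TRUE)
  s2 <- summarize_by_stage(v, g)
  for (lv in s2$group) {
    vv <- v[g == lv]
    expect_equal(s2$iqr[s2$group == lv], iqr_oracle(vv), tolerance = 1e-12)
    expect_equal(s2$sem[s2$group == lv], sd(vv) / sqrt(length(vv)))
    expect_equal(s2$mean[s2$group == lv], sum(vv) / length(vv))
  }
})
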