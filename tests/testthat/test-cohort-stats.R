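balanced_frame <- function(seed = 1, n = 5, fun = function(tr, age) 0) {
  set.seed(seed)
  g <- expand.grid(treatment = c("control", "CBZ"), age = c(43, 63, 93),
                   rep = seq_len(n), stringsAsFactors = FALSE)
  g$y <- mapply(fun, g$treatment, g$age) + rnorm(nrow(g))
  g
}

test_that("a pure factor-A shift produces no B or interaction sums", {
  g <- expand.grid(treatment = c("control", "CBZ"), age = c(43, 63, 93),
                   rep = 1:3, stringsAsFactors = FALSE)
  g$y <- ifelse(g$treatment == "CBZ", 2, 0)   # zero within-cell noise
  av <- two_way_anova(g, "y")
  expect_equal(av$ss[av$source == "age"], 0, tolerance = 1e-12)
  expect_equal(av$ss[av$source == "treatment:age"], 0, tolerance = 1e-12)
  expect_gt(av$ss[av$source == "treatment"], 0)
})

test_that("the balanced decomposition identity holds to 1e-9", {
  for (seed in 1:20) {
    g <- balanced_frame(seed)
    av <- two_way_anova(g, "y")
    ss_tot <- sum((g$y - mean(g$y))^2)
    expect_equal(sum(av$ss), ss_tot, tolerance = 1e-9)
  }
})

test_that("F statistics and p values match the aov oracle", {
  for (seed in c(2, 9)) {
    g <- balanced_frame(seed, fun = function(tr, age)
      (tr == "CBZ") * 0.8 + (age == 93) * 0.5)
    av <- two_way_anova(g, "y")
    oracle <- summary(stats::aov(y ~ treatment * age,
                                 data = transform(g,
                                                  treatment = factor(treatment),
                                                  age = factor(age))))[[1]]
    expect_equal(av$statistic[1:3], oracle[["F value"]][1:3],
                 tolerance = 1e-9)
    expect_equal(av$p[1:3], oracle[["Pr(>F)"]][1:3], tolerance = 1e-9)
  }
})

test_that("unbalanced or degenerate designs are rejected", {
  g <- balanced_frame(1)
  expect_error(two_way_anova(g[-1, ], "y"), "unbalanced")
  g1 <- g[g$treatment == "control", ]
  expect_error(two_way_anova(g1, "y"), "two levels")
})

test_that("pooled t matches both the textbook formula and t.test", {
  a <- c(1, 2, 3, 4, 5); b <- c(2, 3, 4, 5, 6)
  r <- student_t(a, b)
  expect_equal(r$statistic, -1, tolerance = 1e-12)  # hand: sp2=2.5, se=1
  oracle <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(r$statistic, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(r$p, oracle$p.value, tolerance = 1e-12)
  # symmetry and identical-group degeneracy
  expect_equal(student_t(b, a)$statistic, 1, tolerance = 1e-12)
  expect_equal(student_t(b, a)$p, r$p, tolerance = 1e-12)
  same <- student_t(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_error(student_t(c(1, 1), c(2, 2)), "degenerate")
})

test_that("exact Mann-Whitney equals enumeration on canonical cases", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 0.1, tolerance = 1e-12)   # 2 / choose(6, 3)
  # identical multisets put U at its center (ties force normal mode)
  r2 <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r2$statistic, 4.5)
  expect_equal(r2$p, 1)
})

test_that("exact mode equals wilcox.test on every untied 3-vs-3 ranking", {
  sets <- utils::combn(6, 3)
  for (k in seq_len(ncol(sets))) {
    a <- sets[, k]
    b <- setdiff(1:6, a)
    ours <- mann_whitney(a, b, mode = "exact")
    oracle <- stats::wilcox.test(a, b, exact = TRUE)
    expect_equal(ours$p, oracle$p.value, tolerance = 1e-12)
    expect_equal(ours$statistic, unname(oracle$statistic),
                 tolerance = 1e-12)
  }
})

test_that("the tie-corrected normal approximation matches wilcox.test", {
  set.seed(11)
  for (k in 1:5) {
    a <- sample(1:8, 15, replace = TRUE)
    b <- sample(3:10, 18, replace = TRUE)
    ours <- mann_whitney(a, b, mode = "normal")
    oracle <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = TRUE))
    expect_equal(ours$p, oracle$p.value, tolerance = 1e-9)
  }
})

test_that("group summaries use the sample SD and flag singletons", {
  g <- data.frame(group = c("A", "A", "A", "B", "B", "C"),
                  y = c(1, 2, 3, 5, 5, 9))
  s <- group_summary(g, "y")
  expect_equal(s$mean[s$group == "A"], 2)
  expect_equal(s$sd[s$group == "A"], 1)      # n-1 denominator
  expect_equal(s$sd[s$group == "B"], 0)
  expect_equal(s$sd[s$group == "C"], 0)
  expect_true(s$degenerate[s$group == "C"])
  expect_false(s$degenerate[s$group == "B"])
})

test_that("the pairwise t holds its nominal type-I error", {
  set.seed(21)
  rejections <- 0
  nsim <- 4000
  for (k in seq_len(nsim)) {
    a <- rnorm(5); b <- rnorm(5)
    rejections <- rejections + (student_t(a, b)$p <= 0.05)
  }
  rate <- rejections / nsim
  expect_gt(rate, 0.035)
  expect_lt(rate, 0.065)
})
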