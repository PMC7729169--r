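test_that("F critical values match published two-decimal anchors", {
  expect_equal(round(f_critical(0.05, 7, 100), 2), 2.10)
  expect_equal(round(f_critical(0.05, 6, 101), 2), 2.19)
  expect_equal(round(f_critical(0.05, 14, 93), 2), 1.80)
  expect_error(f_critical(0.05, 0, 10), "invalid-df")
  expect_lt(f_critical(0.999, 3, 10), 0.05)  # alpha -> 1 limit approaches 0
})

test_that("F critical is strictly decreasing in alpha and in df2", {
  alphas <- c(0.01, 0.025, 0.05, 0.1, 0.25)
  vals <- vapply(alphas, f_critical, numeric(1), df1 = 5, df2 = 40)
  expect_true(all(diff(vals) < 0))
  df2s <- c(2, 5, 10, 50, 200)
  vals2 <- vapply(df2s, function(d) f_critical(0.05, 5, d), numeric(1))
  expect_true(all(diff(vals2) < 0))
})

test_that("factorial ANOVA separates planted effects from null interactions", {
  d <- toy_factorial(main_a = 2, inter = 0, sd = 1, seed = 11)
  a <- factorial_anova(d, "y", c("A", "B"))
  expect_equal(a$term, c("A", "B", "A:B", "Residuals"))
  expect_lt(a$p.value[a$term == "A"], 0.01)
  expect_gt(a$p.value[a$term == "A:B"], 0.01)
  # planted interaction with small noise is detected
  di <- toy_factorial(main_a = 1, inter = 1, sd = 0.1, seed = 12)
  ai <- factorial_anova(di, "y", c("A", "B"))
  expect_lt(ai$p.value[ai$term == "A:B"], 0.01)
  # total SS identity
  expect_equal(sum(a$sumsq), sum((d$y - mean(d$y))^2), tolerance = 1e-8)
  # degenerate and error paths
  d0 <- d; d0$y <- 1
  expect_true(attr(factorial_anova(d0, "y", c("A", "B")), "degenerate"))
  expect_error(factorial_anova(d, "z", c("A", "B")), "missing-column")
})

test_that("ANOVA null rejection rate is calibrated at the nominal level", {
  d <- toy_factorial(a = 3, b = 3, nrep = 4, sd = 1, seed = 5)
  set.seed(99)
  nrep <- 1000
  pvals <- replicate(nrep, {
    d$y <- sample(d$y)
    factorial_anova(d, "y", c("A", "B"), interactions = FALSE)$p.value[1]
  })
  rate <- mean(pvals < 0.01)
  mc_se <- sqrt(0.01 * 0.99 / nrep)
  expect_lt(abs(rate - 0.01), 2 * mc_se + 1e-9)
})

test_that("Tukey letters agree with the studentized-range oracle", {
  set.seed(21)
  d <- data.frame(g = rep(c("lo", "hi"), each = 20),
                  y = c(rnorm(20, 0, 0.5), rnorm(20, 5, 0.5)))
  cl <- tukey_hsd(d, "y", "g", alpha = 0.01)
  expect_equal(cl$letters, c("a", "b"))
  expect_equal(cl$group, c("lo", "hi"))  # ordered by mean
  # oracle: same significance decision as stats::TukeyHSD
  tk <- TukeyHSD(aov(y ~ g, d), conf.level = 0.99)$g
  expect_true(tk[, "p adj"] < 0.01)

  # identical groups share one letter
  d2 <- data.frame(g = rep(c("a", "b", "c"), each = 10), y = rep(1:10, 3))
  expect_true(all(tukey_hsd(d2, "y", "g")$letters == "a"))

  # middle group overlapping both extremes -> a, ab, b
  set.seed(22)
  d3 <- data.frame(g = rep(c("g1", "g2", "g3"), each = 12),
                   y = c(rnorm(12, 0, 1), rnorm(12, 1.1, 1), rnorm(12, 2.2, 1)))
  cl3 <- tukey_hsd(d3, "y", "g", alpha = 0.05)
  expect_equal(cl3$letters, c("a", "ab", "b"))
  # oracle cross-check of the pairwise pattern
  tk3 <- TukeyHSD(aov(y ~ g, d3), conf.level = 0.95)$g[, "p adj"]
  expect_true(tk3[["g3-g1"]] < 0.05)
  expect_true(tk3[["g2-g1"]] > 0.05 && tk3[["g3-g2"]] > 0.05)

  # single group
  expect_equal(tukey_hsd(data.frame(g = "x", y = c(1, 2)), "y", "g")$letters, "a")
})

test_that("Tukey letters are a valid cover respecting mean order", {
  for (seed in 1:5) {
    set.seed(seed)
    k <- sample(3:6, 1)
    d <- data.frame(g = rep(paste0("g", seq_len(k)), each = 8),
                    y = rnorm(8 * k, rep(runif(k, 0, 4), each = 8)))
    cl <- tukey_hsd(d, "y", "g", alpha = 0.05)
    expect_true(all(nchar(cl$letters) >= 1))
    expect_true(!is.unsorted(cl$mean))
    # groups sharing a letter must span a mean-contiguous block
    for (lt in unique(strsplit(paste(cl$letters, collapse = ""), "")[[1]])) {
      idx <- grep(lt, cl$letters)
      expect_equal(idx, seq(min(idx), max(idx)))
    }
  }
})

test_that("distribution checks flag normality and variance structure", {
  set.seed(31)
  d <- data.frame(g = rep(c("a", "b"), each = 250), y = rnorm(500))
  ck <- distribution_checks(d, "y", "g")
  expect_false(ck$degenerate)
  expect_gt(ck$normality$p.value, 0.05)
  # strong heteroscedasticity is detected
  set.seed(32)
  d2 <- data.frame(g = rep(c("a", "b"), each = 50),
                   y = c(rnorm(50, 0, 1), rnorm(50, 0, sqrt(10))))
  expect_lt(distribution_checks(d2, "y", "g")$homoscedasticity$p.value, 0.01)
  # degenerate and error paths
  expect_true(distribution_checks(data.frame(g = c("a", "a", "b", "b"),
                                             y = rep(1, 4)), "y", "g")$degenerate)
  expect_error(distribution_checks(data.frame(g = rep("a", 5), y = rnorm(5)),
                                   "y", "g"), "invalid-grouping")
})
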