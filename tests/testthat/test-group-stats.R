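test_that("percent change follows the (post - baseline) / post definition", {
  expect_equal(percent_change(19, 8.4), (8.4 - 19) / 8.4)
  expect_equal(round(percent_change(19, 8.4), 4), -1.2619)
  expect_equal(percent_change(10, 10), 0)
  expect_warning(pc0 <- percent_change(c(10, 5), c(4, 0)), "undefined")
  expect_true(is.na(pc0[2]) && !is.na(pc0[1]))
})

test_that("paired t-test matches the closed form and handles boundaries", {
  set.seed(1)
  b <- rnorm(20); p <- b + 0.5 + rnorm(20, sd = 0.7)
  res <- paired_change_tests(b, p, name = "shift")
  d <- p - b
  expect_equal(res$statistic, mean(d) / (sd(d) / sqrt(20)), tolerance = 1e-12)
  expect_equal(res$df, "19")
  expect_equal(res$p, 2 * pt(-abs(res$statistic), 19), tolerance = 1e-12)

  # missing pairs dropped pairwise
  b[3] <- NA
  expect_equal(paired_change_tests(b, p)$n, 19)

  # two distinct pairs give a df = 1 result
  r2 <- paired_change_tests(c(1, 2), c(2, 5))
  expect_equal(r2$df, "1")

  expect_error(paired_change_tests(1:5, 1:5 + 2), "zero variance")
  expect_error(paired_change_tests(1, 2), "complete pairs")

  # null calibration: rejection ~ 5%
  set.seed(2)
  rej <- mean(vapply(1:1000, function(i) {
    x <- rnorm(15); y <- rnorm(15)
    paired_change_tests(x, y)$p < 0.05
  }, TRUE))
  expect_gt(rej, 0.03); expect_lt(rej, 0.07)
})

test_that("brain-behaviour correlation reports r with t on n - 2 df", {
  x <- c(1, 2, 3, 4, 5)
  res <- correlate_change_with_mood(x, 2 * x)
  expect_equal(res$estimate, 1)
  expect_equal(res$p, 0)

  set.seed(3)
  xs <- rnorm(58); ys <- 0.5 * xs + rnorm(58)
  r <- cor(xs, ys)
  res2 <- correlate_change_with_mood(xs, ys)
  expect_equal(res2$statistic, r * sqrt(56 / (1 - r^2)), tolerance = 1e-12)
  expect_equal(res2$p, cor.test(xs, ys)$p.value, tolerance = 1e-10)  # oracle

  expect_error(correlate_change_with_mood(1:3, 3:1), "4 complete pairs")
  expect_error(correlate_change_with_mood(rep(1, 6), rnorm(6)), "zero variance")

  # null calibration at n = 58
  set.seed(4)
  stats_null <- vapply(1:1000, function(i)
    correlate_change_with_mood(rnorm(58), rnorm(58))[, c("estimate", "p")], list(1, 1))
  expect_lt(abs(mean(unlist(stats_null["estimate", ]))), 0.02)
  rej <- mean(unlist(stats_null["p", ]) < 0.05)
  expect_gt(rej, 0.03); expect_lt(rej, 0.07)
})

test_that("covariate adjustment recovers group effects and absorbs confounds", {
  set.seed(5)
  n <- 400
  grp <- rep(c("HC", "TRD"), each = n / 2)
  age <- rnorm(n, 35, 10)
  sex <- sample(c("F", "M"), n, replace = TRUE)

  # covariates independent of group: adjusted t ~ unadjusted t
  y <- 0.4 * (grp == "TRD") + rnorm(n)
  t_adj <- adjusted_group_comparison(y, grp, age, sex)$statistic
  t_raw <- unname(t.test(y[grp == "TRD"], y[grp == "HC"], var.equal = TRUE)$statistic)
  expect_equal(t_adj, t_raw, tolerance = 0.15)

  # metric fully explained by age, groups differing only in age: group t ~ 0
  age2 <- age + 10 * (grp == "TRD")
  y2 <- 0.3 * age2 + rnorm(n, sd = 0.1)
  expect_lt(abs(adjusted_group_comparison(y2, grp, age2, sex)$statistic), 2.5)
  # whereas the unadjusted comparison is wildly significant
  expect_gt(abs(t.test(y2 ~ grp)$statistic), 5)

  # residualize route agrees in direction and roughly in magnitude
  t_res <- adjusted_group_comparison(y, grp, age, sex, method = "residualize")$statistic
  expect_equal(sign(t_res), sign(t_adj))
  expect_equal(t_res, t_adj, tolerance = 0.1)

  # degrees of freedom bookkeeping: n - 4
  expect_equal(adjusted_group_comparison(y, grp, age, sex)$df, as.character(n - 4))

  expect_error(adjusted_group_comparison(y, rep("A", n), age, sex), "2 groups")
  expect_error(adjusted_group_comparison(y, grp, rep(1, n), sex), "collinear")

  # null calibration ~ 5%
  set.seed(6)
  rej <- mean(vapply(1:400, function(i) {
    yy <- rnorm(60)
    adjusted_group_comparison(yy, rep(c("a", "b"), 30), rnorm(60), sample(c("F", "M"), 60, TRUE))$p < 0.05
  }, TRUE))
  expect_gt(rej, 0.025); expect_lt(rej, 0.075)
})

test_that("Bonferroni families reproduce the stated thresholds", {
  f6 <- bonferroni_family(c(0.004, 0.02), m = 6)
  expect_equal(round(f6$threshold, 4), 0.0083)
  expect_equal(f6$significant, c(TRUE, FALSE))
  expect_equal(f6$threshold * f6$m, 0.05)
  expect_equal(bonferroni_family(numeric(0), m = 10)$threshold, 0.005)
  expect_equal(bonferroni_family(0.03, m = 1)$threshold, 0.05)
  expect_error(bonferroni_family(0.01, m = 0), "m")
})

test_that("the transition-test family enumerates transitions into selected states", {
  f <- tp_test_family(c(1, 6), 6)
  expect_equal(nrow(f), 10)
  expect_true(all(f$to %in% c(1, 6)) && all(f$from != f$to))
  expect_equal(nrow(tp_test_family(3, 6)), 5)
  expect_equal(nrow(tp_test_family(1:6, 6)), 30)
  expect_equal(nrow(tp_test_family(integer(0), 6)), 0)
  expect_error(tp_test_family(7, 6), "outside")
})

test_that("Welch t from summaries reproduces the printed demographic contrast", {
  res <- welch_t_summary(32.61, 12, 56, 40.7, 11.3, 58)
  expect_equal(round(abs(res$statistic), 2), 3.70)
  expect_lt(res$p, 0.001)

  expect_equal(welch_t_summary(5, 1, 10, 5, 1, 10)$statistic, 0)

  # agreement with a raw-data Welch test when summaries come from the data
  set.seed(7)
  x <- rnorm(30, 1); y <- rnorm(40, 1.4, 1.3)
  res2 <- welch_t_summary(mean(x), sd(x), 30, mean(y), sd(y), 40)
  oracle <- t.test(y, x)
  expect_equal(res2$statistic, unname(oracle$statistic), tolerance = 1e-10)
  expect_equal(res2$p, oracle$p.value, tolerance = 1e-10)

  # equal group sizes: Welch statistic equals the pooled statistic
  pooled <- (6 - 5) / sqrt((1.2^2 + 0.8^2) / 2 * (2 / 2000))
  expect_equal(welch_t_summary(5, 1.2, 2000, 6, 0.8, 2000)$statistic, pooled, tolerance = 1e-6)

  expect_error(welch_t_summary(1, 0, 10, 2, 1, 10), "sd1 > 0")
})

test_that("2x2 chi-square reproduces printed race contrasts and the r x c oracle", {
  # counts reconstructed from printed percentages (HC n = 55, TRD n = 58)
  expect_equal(round(chi2_2x2(11, 44, 0, 58)$statistic, 3), 12.851)
  expect_equal(round(chi2_2x2(10, 45, 6, 52)$statistic, 3), 1.427)
  expect_equal(round(chi2_2x2(4, 51, 1, 57)$statistic, 3), 2.055)

  # proportional table: independence, statistic 0
  expect_equal(chi2_2x2(10, 20, 5, 10)$statistic, 0)

  # oracle: generic Pearson chi-square without continuity correction
  o <- suppressWarnings(chisq.test(matrix(c(11, 0, 44, 58), 2), correct = FALSE))
  expect_equal(chi2_2x2(11, 44, 0, 58)$statistic, unname(o$statistic), tolerance = 1e-12)
  expect_equal(chi2_2x2(11, 44, 0, 58)$p, o$p.value, tolerance = 1e-12)

  expect_error(chi2_2x2(0, 0, 3, 4), "marginal")
  expect_error(chi2_2x2(1.5, 2, 3, 4), "integers")
})

test_that("one-way ANOVA matches the t-squared identity and detects shifts", {
  set.seed(8)
  x <- rnorm(25); y <- rnorm(30, 0.3)
  res <- oneway_anova(c(x, y), rep(c("a", "b"), c(25, 30)))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(res$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)
  expect_equal(res$df, "1,53")

  # a 3-sigma shifted group is overwhelmingly detected
  g3 <- rep(c("a", "b", "c"), each = 30)
  v3 <- c(rnorm(30), rnorm(30), rnorm(30, 3))
  expect_lt(oneway_anova(v3, g3)$p, 0.001)

  # oracle: stats::oneway.test with equal variances
  o <- oneway.test(v3 ~ g3, var.equal = TRUE)
  expect_equal(oneway_anova(v3, g3)$statistic, unname(o$statistic), tolerance = 1e-10)

  # null calibration ~5%
  set.seed(9)
  rej <- mean(vapply(1:1000, function(i)
    oneway_anova(rnorm(45), rep(1:3, each = 15))$p < 0.05, TRUE))
  expect_gt(rej, 0.03); expect_lt(rej, 0.07)

  expect_error(oneway_anova(rnorm(3), c("a", "a", "b")), ">= 2 values")
})

test_that("test results are pure records with consistent significance flags", {
  r <- cap_test_result("x", -2.5, 10, 0.02, 12, family = "f", alpha_adjusted = 0.0083)
  expect_false(r$significant)
  expect_equal(r$direction, -1)
  r2 <- cap_test_result("x", -2.5, 10, 0.005, 12, family = "f", alpha_adjusted = 0.0083)
  expect_true(r2$significant)
  expect_error(cap_test_result("x", 1, 1, 1.5, 3), "p")
})
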