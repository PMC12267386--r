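test_that("Pearson validation recovers exact and degenerate correlations", {
  x <- c(1, 3, 2, 5, 4, 7)
  expect_equal(pearson_validate(x, x)$r, 1)
  expect_equal(pearson_validate(x, -x)$r, -1)
  expect_error(pearson_validate(rep(1, 6), x), "zero variance")
  expect_error(pearson_validate(1:3, 3:1), "at least 4")
})

test_that("Bland-Altman bias and limits of agreement match hand computation", {
  z <- c(10, 20, 30)
  ba0 <- bland_altman(z, z)
  expect_equal(ba0$bias, 0)
  expect_equal(c(ba0$loa_low, ba0$loa_high), c(0, 0))
  # differences 1, 2, 3: bias 2, sample SD 1, LoA 2 +/- 1.96
  # differences here are an exact linear function of the means, so the
  # proportional-bias regression is a perfect fit
  ba <- suppressWarnings(bland_altman(c(2, 4, 6), c(1, 2, 3)))
  expect_equal(ba$bias, 2)
  expect_equal(ba$sd_diff, 1)
  expect_equal(ba$loa_low, 0.04)
  expect_equal(ba$loa_high, 3.96)
  expect_equal(ba$loa_high - ba$loa_low, 2 * 1.96 * ba$sd_diff)
  expect_error(bland_altman(1:2, 2:1), "at least 3")
})

test_that("limits of agreement bracket about 95% of large normal samples", {
  withr::with_seed(10, {
    d <- stats::rnorm(10000, 25, 8)
    ba <- suppressWarnings(bland_altman(d, rep(0, 10000)))
    coverage <- mean(d >= ba$loa_low & d <= ba$loa_high)
    expect_gt(coverage, 0.944)
    expect_lt(coverage, 0.958)
  })
})

test_that("two-condition RM-ANOVA is the squared paired t test", {
  withr::with_seed(11, {
    x <- matrix(stats::rnorm(40, 300, 30), ncol = 2)
    x[, 2] <- x[, 2] + 15
    res <- rm_anova_gg(x)
    tt <- stats::t.test(x[, 1], x[, 2], paired = TRUE)
    expect_equal(res$gg_epsilon, 1)
    expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-12)
    expect_equal(res$p, tt$p.value, tolerance = 1e-12)
    expect_false(res$corrected)
  })
})

test_that("RM-ANOVA F matches the aov error-decomposition oracle", {
  withr::with_seed(12, {
    for (rep_i in 1:5) {
      x <- matrix(stats::rnorm(40, 300, 25), nrow = 10, ncol = 4)
      res <- rm_anova_gg(x, correction = "none")
      long <- data.frame(y = as.vector(x),
                         subj = factor(rep(1:10, 4)),
                         cond = factor(rep(1:4, each = 10)))
      fit <- summary(stats::aov(y ~ cond + Error(subj / cond), data = long))
      tab <- fit[["Error: subj:cond"]][[1]]
      expect_equal(res$F, tab["cond", "F value"], tolerance = 1e-10)
      expect_equal(res$p, tab["cond", "Pr(>F)"], tolerance = 1e-10)
      expect_equal(res$df1, 3)
      expect_equal(res$df2, 27)
      eta <- tab["cond", "Sum Sq"] /
        (tab["cond", "Sum Sq"] + tab["Residuals", "Sum Sq"])
      expect_equal(res$partial_eta_sq, eta, tolerance = 1e-10)
    }
  })
})

test_that("Greenhouse-Geisser correction deflates both degrees of freedom", {
  withr::with_seed(13, {
    # strongly non-spherical data: one condition much noisier
    base <- stats::rnorm(30, 300, 5)
    x <- cbind(base + stats::rnorm(30, 0, 1),
               base + stats::rnorm(30, 10, 1),
               base + stats::rnorm(30, 20, 60))
    res <- rm_anova_gg(x)
    expect_lt(res$mauchly_p, 0.05)
    expect_true(res$corrected)
    expect_gt(res$gg_epsilon, 1 / (ncol(x) - 1))
    expect_lte(res$gg_epsilon, 1)
    expect_equal(res$df1, res$df1_uncorrected * res$gg_epsilon)
    expect_equal(res$df2, res$df2_uncorrected * res$gg_epsilon)
    unc <- rm_anova_gg(x, correction = "none")
    expect_equal(unc$F, res$F)           # F itself is unchanged
    expect_equal(unc$df1, 2)
    expect_gt(res$p, unc$p)              # correction is conservative here
  })
  expect_error(rm_anova_gg(matrix(c(1, NA, 2, 3), 2)), "complete")
})

test_that("Wilcoxon signed-rank reproduces the exact enumeration for n = 5", {
  a <- c(11, 12, 13, 14, 15)
  b <- c(10, 10, 10, 10, 10)
  res <- wilcoxon_signed_rank(a, b, alternative = "greater")
  expect_true(res$exact)
  expect_equal(res$p, 1 / 32)            # all 5 differences positive: 1/2^5
  expect_equal(res$statistic, 15)
  expect_error(wilcoxon_signed_rank(a, a), "degenerate")
  # zeros are dropped before ranking
  res2 <- wilcoxon_signed_rank(c(a, 99), c(b, 99), alternative = "greater")
  expect_equal(res2$n_effective, 5)
  expect_equal(res2$p, 1 / 32)
})

test_that("Friedman with two conditions reduces to the sign-test statistic", {
  withr::with_seed(14, {
    x <- matrix(stats::rnorm(24, 100, 10), ncol = 2)
    res <- friedman(x)
    n <- nrow(x)
    pos <- sum(x[, 1] > x[, 2])
    expect_equal(res$statistic, (2 * pos - n)^2 / n, tolerance = 1e-12)
    expect_equal(res$df, 1)
  })
  expect_error(friedman(matrix(5, 4, 3)), "degenerate")
})

test_that("Bonferroni adjustment reproduces the 4-decimal convention", {
  expect_equal(bonferroni(0.05, 7), 0.0071)
  expect_equal(bonferroni(0.05, 1), 0.05)
  expect_equal(bonferroni(0.05, 12), 0.0042)
  expect_equal(bonferroni(0.05, 6), 0.0083)
  expect_equal(bonferroni(0.05, 3), 0.0167)
  expect_error(bonferroni(0.05, 0), "at least 1")
})

test_that("exact power search returns 46 at r = 0.4 and dominates Fisher-z", {
  expect_identical(power_pearson_n(0.4, 0.05, 0.80, tails = 2), 46L)
  expect_identical(power_pearson_n(0.4, 0.05, 0.80, method = "fisher_z"), 47L)
  # n_required is non-increasing in the effect size
  ns <- vapply(c(0.2, 0.3, 0.4, 0.5, 0.7), power_pearson_n, 0L,
               alpha = 0.05, power = 0.80)
  expect_true(all(diff(ns) <= 0))
  expect_lt(power_pearson(0.4, 45), 0.80)
  expect_gte(power_pearson(0.4, 46), 0.80)
})

test_that("exact power agrees with Monte-Carlo simulation of the r test", {
  n <- 46; rho <- 0.4
  exact <- power_pearson(rho, n)
  withr::with_seed(15, {
    reject <- replicate(4000, {
      x <- stats::rnorm(n)
      y <- rho * x + sqrt(1 - rho^2) * stats::rnorm(n)
      stats::cor.test(x, y)$p.value < 0.05
    })
  })
  mc_se <- sqrt(exact * (1 - exact) / 4000)
  expect_lt(abs(mean(reject) - exact), 3 * mc_se)
})

test_that("agreement_report assembles the full validation battery", {
  withr::with_seed(16, {
    lat <- stats::rnorm(48, 0, 20)
    com <- data.frame(rt_median = 240 + lat + stats::rnorm(48, 0, 8))
    vr <- data.frame(rt_median = 270 + lat + stats::rnorm(48, 0, 8))
    rep <- agreement_report(com, vr)
    expect_equal(nrow(rep$table), 1)
    expect_gt(rep$table$r, 0.7)
    expect_equal(rep$table$bias, mean(vr$rt_median - com$rt_median))
    expect_equal(rep$adjusted_alpha, 0.05)
    expect_lt(rep$table$wilcoxon_p, 0.001)
  })
})
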