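test_that("BH mask equals the step-up definition under exhaustive fuzz", {
  expect_identical(bh_significant(c(0.001, 0.01, 0.02, 0.9), 0.05),
                   c(TRUE, TRUE, TRUE, FALSE))
  expect_identical(bh_significant(rep(1, 5), 0.05), rep(FALSE, 5))
  set.seed(81)
  for (i in 1:1000) {
    n <- sample(1:20, 1)
    p <- round(runif(n)^sample(1:3, 1), 3)
    expect_identical(bh_significant(p, 0.05), bh_stepup_oracle(p, 0.05),
                     info = paste("draw", i))
  }
})

test_that("mixed ANOVA recovers a hand-computed split-plot toy", {
  # 2 groups x 3 within levels, small integer data
  Y <- rbind(c(1, 2, 3), c(2, 3, 4), c(2, 2, 2),
             c(5, 6, 7), c(6, 7, 8), c(5, 5, 8))
  group <- rep(c("younger", "older"), each = 3)
  res <- mixed_anova(Y, group, list(node = 3))
  # oracle from the aov strata directly
  dat <- data.frame(
    y = as.vector(Y), subject = factor(rep(1:6, 3)),
    group = factor(rep(group, 3)), w = factor(rep(1:3, each = 6))
  )
  sm <- summary(stats::aov(y ~ group * w + Error(subject / w), dat))
  tab_b <- sm[["Error: subject"]][[1]]
  expect_equal(res$F[res$effect == "group"], tab_b["group", "F value"])
  expect_equal(res$partial_eta2[res$effect == "group"],
               tab_b["group", "Sum Sq"] /
                 (tab_b["group", "Sum Sq"] + tab_b["Residuals", "Sum Sq"]))
  expect_true(all(res$epsilon > 0 & res$epsilon <= 1))
})

test_that("mixed ANOVA agrees with car's GG-corrected analysis", {
  skip_if_not_installed("car")
  set.seed(82)
  n <- 14; a <- 4
  group <- rep(c("younger", "older"), c(8, 6))
  Y <- matrix(rnorm(n * a), n) + outer(rep(c(0, 1), c(8, 6)), seq_len(a) / 4)
  res <- mixed_anova(Y, group, list(node = a))

  idata <- data.frame(w = factor(seq_len(a)))
  mod <- stats::lm(Y ~ factor(group, levels = c("younger", "older")))
  av <- car::Anova(mod, idata = idata, idesign = ~w, type = 3)
  sm <- summary(av, multivariate = FALSE)
  ut <- sm$univariate.tests
  expect_equal(res$F[res$effect == "group:node"],
               unname(ut["factor(group, levels = c(\"younger\", \"older\")):w",
                         "F value"]),
               tolerance = 1e-6)
  gg <- sm$pval.adjustments
  expect_equal(res$epsilon[res$effect == "group:node"],
               unname(gg[grep(":w", rownames(gg)), "GG eps"]),
               tolerance = 1e-6)
  expect_equal(res$p[res$effect == "group:node"],
               unname(gg[grep(":w", rownames(gg)), "Pr(>F[GG])"]),
               tolerance = 1e-6)
})

test_that("compound-symmetric data give epsilon near 1", {
  set.seed(83)
  n <- 40; a <- 5
  subj <- rnorm(n, sd = 2)
  Y <- matrix(rnorm(n * a), n) + subj # equal variances, equal covariances
  res <- mixed_anova(Y, rep(c("younger", "older"), c(25, 15)),
                     list(node = a))
  expect_gt(res$epsilon[res$effect == "group:node"], 0.85)
})

test_that("group-effect calibration and power on simulated cohorts", {
  set.seed(84)
  # null: identical distributions; rejection rate at alpha=.05 stays nominal
  pvals <- replicate(200, {
    Y <- matrix(rnorm(20 * 4), 20)
    mixed_anova(Y, rep(c("younger", "older"), c(12, 8)),
                list(node = 4))$p[1]
  })
  rate <- mean(pvals < 0.05)
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.08)

  # strong shift on all channels: significant with large partial eta^2
  Y <- matrix(rnorm(50 * 8), 50)
  Y[31:50, ] <- Y[31:50, ] + 1.5
  res <- mixed_anova(Y, rep(c("younger", "older"), c(30, 20)),
                     list(node = 8))
  expect_lt(res$p[res$effect == "group"], 0.001)
  expect_gt(res$partial_eta2[res$effect == "group"], 0.3)
})

test_that("two within factors produce the three interaction strata", {
  set.seed(85)
  n <- 12; a <- 3; b <- 4
  Y <- matrix(rnorm(n * a * b), n)
  res <- mixed_anova(Y, rep(c("younger", "older"), each = 6),
                     list(node = a, scale = b))
  expect_setequal(res$effect,
                  c("group", "group:node", "group:scale", "group:node:scale"))
  expect_true(all(is.finite(res$F)))
  expect_true(all(res$epsilon > 0 & res$epsilon <= 1))
  expect_error(mixed_anova(Y, rep("g", n), list(node = 5, scale = 3)),
               "does not match")
})

test_that("the ANCOVA covariate adjusts the between-group effect", {
  set.seed(86)
  n <- 40; a <- 4
  group <- rep(c("younger", "older"), each = 20)
  # covariate unrelated to anything: group F barely moves
  Y <- matrix(rnorm(n * a), n) + rep(c(0, 0.8), each = 20)
  cov_null <- rnorm(n)
  f0 <- mixed_anova(Y, group, list(node = a))$F[1]
  f1 <- ancova_covariate(Y, group, list(node = a), cov_null)$F[1]
  expect_lt(abs(f1 - f0) / f0, 0.10)

  # group difference entirely mediated by the covariate
  cov_med <- rnorm(n) + rep(c(0, 2), each = 20)
  Y2 <- matrix(0.9 * cov_med, n, a) + matrix(rnorm(n * a, sd = 0.8), n)
  res <- ancova_covariate(Y2, group, list(node = a), cov_med)
  expect_gt(res$p[res$effect == "group"], 0.05)

  expect_error(ancova_covariate(Y, group, list(node = a), rep(1, n)),
               "zero variance")
})

test_that("post-hoc Welch t-tests apply one BH family across all cells", {
  set.seed(87)
  group <- rep(c("younger", "older"), c(20, 14))
  Y <- matrix(rnorm(34 * 16), 34)
  Y[group == "older", 1:4] <- Y[group == "older", 1:4] + 2
  res <- posthoc_ttests(Y, group, expected_family = 16)
  expect_s3_class(res, "corrected_comparisons")
  expect_identical(res$family_size, 16L)
  expect_true(all(res$significant[1:4]))
  # t sign convention: positive when older is higher
  expect_true(all(res$t_values[1:4] > 0))
  # matches column-wise Welch t
  ht <- stats::t.test(Y[group == "older", 1], Y[group == "younger", 1])
  expect_equal(res$t_values[1], unname(ht$statistic))
  expect_identical(res$significant, bh_significant(res$raw_p, 0.05))
  expect_error(posthoc_ttests(Y, group, expected_family = 480), "expected")
})

test_that("comparison family sizes follow the montage bookkeeping", {
  # 16 electrodes pair up into 120 electrode pairs; per 5 bands -> 600
  expect_identical(ncol(utils::combn(montage_16(), 2)), 120L)
  expect_identical(ncol(utils::combn(montage_16(), 2)) * nrow(eeg_bands()),
                   600L)
  # 16 electrodes x 30 scales -> 480; 16 x 5 bands -> 80
  expect_identical(length(montage_16()) * 30L, 480L)
  expect_identical(length(montage_16()) * nrow(eeg_bands()), 80L)
})

test_that("Spearman NS-complexity correlations respect rank invariance", {
  set.seed(88)
  ns <- matrix(runif(30 * 4), 30)
  # index a monotone transform of NS: R = 1 per channel
  res <- spearman_ns_complexity(ns, exp(3 * ns))
  expect_equal(unname(res$R), rep(1, 4))
  # sign flip negates R exactly
  res2 <- spearman_ns_complexity(-ns, exp(3 * ns))
  expect_equal(unname(res2$R), rep(-1, 4))
  expect_error(spearman_ns_complexity(ns[1:3, ], exp(ns[1:3, ])), "at least 4")

  # independent features: small |R|, rarely any BH-significant channel
  hits <- replicate(60, {
    r <- spearman_ns_complexity(matrix(rnorm(32 * 16), 32),
                                matrix(rnorm(32 * 16), 32))
    any(r$significant)
  })
  expect_lte(mean(hits), 0.10)
})

test_that("family-level type-I error of the post-hoc pipeline is controlled", {
  set.seed(89)
  any_hit <- replicate(200, {
    Y <- matrix(rnorm(30 * 16), 30)
    any(posthoc_ttests(Y, rep(c("younger", "older"), c(18, 12)))$significant)
  })
  expect_lte(mean(any_hit), 0.10)
})
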