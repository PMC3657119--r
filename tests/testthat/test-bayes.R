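test_that("constant response recovers its value under the cell-means model", {
  y <- rep(7, 20)
  fit <- gibbs_linear_regression(y, matrix(1, 20, 1), seed = 1)
  expect_equal(mean(fit$beta[, 1]), 7, tolerance = 0.05)
})

test_that("posterior mean agrees with the closed-form least-squares oracle", {
  set.seed(42)
  x <- rnorm(100)
  y <- 3 * x + rnorm(100)
  fit <- gibbs_linear_regression(y, cbind(x = x), seed = 7)
  ols <- unname(coef(lm(y ~ 0 + x)))
  expect_lt(abs(mean(fit$beta[, "x"]) - ols), 2 * mcse(fit$beta[, "x"]))
  # and with a fitted intercept against the two-coefficient OLS fit
  X <- cbind(`(Intercept)` = 1, x = x)
  fit2 <- gibbs_linear_regression(y, X, seed = 8)
  ols2 <- coef(lm(y ~ x))
  expect_lt(abs(mean(fit2$beta[, 1]) - ols2[[1]]), 2 * mcse(fit2$beta[, 1]))
  expect_lt(abs(mean(fit2$beta[, 2]) - ols2[[2]]), 2 * mcse(fit2$beta[, 2]))
})

test_that("independent chains agree to within Monte-Carlo error", {
  set.seed(13)
  x <- rnorm(60)
  y <- 2 - x + rnorm(60, sd = 2)
  X <- cbind(1, x)
  f1 <- gibbs_linear_regression(y, X, seed = 101)
  f2 <- gibbs_linear_regression(y, X, seed = 202)
  for (j in 1:2) {
    expect_lt(abs(mean(f1$beta[, j]) - mean(f2$beta[, j])),
              3 * max(mcse(f1$beta[, j]), mcse(f2$beta[, j])))
  }
})

test_that("design errors are caught before sampling", {
  y <- rnorm(10)
  expect_error(gibbs_linear_regression(y, cbind(1:10, 2 * (1:10))),
               "rank deficient")
  expect_error(gibbs_linear_regression(rnorm(3), matrix(rnorm(9), 3, 3)),
               "too few observations")
  expect_error(gibbs_linear_regression(y, matrix(1, 5, 1)), "rows")
})

test_that("group means reproduce per-level sample means with sensible CIs", {
  d <- data.frame(g = "only", y = rep(50, 12))
  gm <- group_means(d, "y", "g", seed = 3)
  expect_equal(gm$mean, 50, tolerance = 0.05)
  expect_lt(gm$ci_high - gm$ci_low, 1)

  set.seed(5)
  d2 <- data.frame(g = rep(c("A", "B"), each = 40),
                   y = c(rnorm(40, 20, 3), rnorm(40, 35, 3)))
  gm2 <- group_means(d2, "y", "g", seed = 4)
  sample_means <- tapply(d2$y, d2$g, mean)
  for (i in 1:2) {
    expect_lt(abs(gm2$mean[i] - sample_means[[gm2$level_label[i]]]),
              2 * gm2$mcse[i])
    expect_true(gm2$ci_low[i] <= gm2$mean[i] && gm2$mean[i] <= gm2$ci_high[i])
  }
  # equal data in both levels -> approximately equal posteriors
  d3 <- data.frame(g = rep(c("A", "B"), each = 30), y = rep(rnorm(30), 2))
  gm3 <- group_means(d3, "y", "g", seed = 6)
  expect_equal(gm3$mean[1], gm3$mean[2], tolerance = 0.05)
})

test_that("singleton levels are excluded with a warning", {
  d <- data.frame(g = c(rep("A", 10), "lonely"), y = rnorm(11))
  expect_warning(gm <- group_means(d, "y", "g", seed = 2), "lonely")
  expect_identical(gm$level_label, "A")
})

test_that("pairwise differences behave like parametric pairwise comparisons", {
  set.seed(9)
  base <- rnorm(30, 50, 4)
  d <- data.frame(g = rep(c("A", "B", "C"), each = 30),
                  y = c(base, base, base + 10))
  pd <- pairwise_differences(d, "y", "g", seed = 31)
  expect_equal(nrow(pd), 3)
  ab <- pd[pd$level_a == "B" & pd$level_b == "A", ]
  expect_lt(abs(ab$diff_mean), 3 * ab$mcse + 0.5)
  expect_false(ab$credible)
  ca <- pd[pd$level_a == "C" & pd$level_b == "A", ]
  expect_equal(ca$diff_mean, 10, tolerance = 0.5)
  expect_true(ca$credible)
  # sample-difference oracle: posterior diff means track mean differences
  means <- tapply(d$y, d$g, mean)
  for (i in seq_len(nrow(pd))) {
    expect_lt(abs(pd$diff_mean[i] -
                    (means[[pd$level_a[i]]] - means[[pd$level_b[i]]])),
              2 * pd$mcse[i])
  }
  # credible flag mirrors the interval excluding zero
  expect_identical(pd$credible, pd$diff_ci_low > 0 | pd$diff_ci_high < 0)
})

test_that("pairwise differences are antisymmetric under level reordering", {
  set.seed(17)
  d <- data.frame(g = factor(rep(c("A", "B"), each = 25)),
                  y = rnorm(50, rep(c(10, 14), each = 25), 3))
  fwd <- pairwise_differences(d, "y", "g", seed = 51)
  d$g <- factor(d$g, levels = c("B", "A"))
  rev <- pairwise_differences(d, "y", "g", seed = 52)
  expect_lt(abs(fwd$diff_mean + rev$diff_mean),
            2 * (fwd$mcse + rev$mcse))
})

test_that("pairwise table formats as mean (ci_low, ci_high) cells", {
  pd <- tibble::tibble(level_a = "B", level_b = "A", diff_mean = 55.93,
                       diff_ci_low = 51.71, diff_ci_high = 60.08,
                       mcse = 0.01, credible = TRUE)
  wide <- format_pairwise(pd)
  expect_identical(wide$A, "55.9 (51.7, 60.1)")
})
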