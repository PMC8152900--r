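test_that("d2-R concentration performance follows the stated scoring rule", {
  lines <- data.frame(processed = c(20, 20), commission = c(2, 1),
                      overlooked = c(1, 1))
  expect_equal(score_d2r(lines), 40 - 3 - 2)
  expect_equal(score_d2r(data.frame(processed = 40, commission = 0,
                                    overlooked = 0)), 40)
  # manual-style variant subtracts commissions only
  expect_equal(score_d2r(lines, rule = "manual"), 40 - 3)
  expect_error(score_d2r(data.frame(processed = 2, commission = 2,
                                    overlooked = 1)), "exceed")
  expect_error(score_d2r(data.frame(processed = -1, commission = 0,
                                    overlooked = 0)), "nonnegative")
})

test_that("zvt and digit-span scoring are the stated aggregates", {
  expect_equal(score_zvt(c(58, 62, 60, 64)), 61)
  expect_equal(score_digit_span(c(TRUE, TRUE, FALSE, TRUE)), 3)
})

test_that("percent gain is 100*(post-pre)/pre, vectorized", {
  expect_equal(percent_gain(160, 176), 10)
  expect_equal(percent_gain(5, 5), 0)
  pre <- c(100, 200, 50); post <- c(110, 180, 75)
  expect_equal(percent_gain(pre, post),
               vapply(seq_along(pre),
                      function(i) percent_gain(pre[i], post[i]),
                      numeric(1)))
  expect_error(percent_gain(0, 10), "0")
})

test_that("welch_test matches the defining formulas and t.test cross-check", {
  x <- c(1, 2, 3, 4); y <- c(2, 4, 6, 8)
  w <- welch_test(x, y)
  expect_equal(w$t, -1.7321, tolerance = 1e-4)
  expect_equal(w$df, 4.4118, tolerance = 1e-4)
  ref <- t.test(x, y)
  expect_equal(w$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(w$df, unname(ref$parameter), tolerance = 1e-12)
  expect_equal(w$p, ref$p.value, tolerance = 1e-12)
  expect_equal(w$ci, as.numeric(ref$conf.int), tolerance = 1e-12)

  wi <- welch_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(wi$t, 0)
  expect_equal(wi$p, 1)
})

test_that("welch_test reduces to the pooled t for equal n and variance", {
  set.seed(14)
  x <- rnorm(12)
  y <- rnorm(12)
  y <- (y - mean(y)) / sd(y) * sd(x) + mean(y)  # force equal variance
  w <- welch_test(x, y)
  pooled <- t.test(x, y, var.equal = TRUE)
  expect_equal(w$t, unname(pooled$statistic), tolerance = 1e-10)
  expect_equal(w$df, unname(pooled$parameter), tolerance = 1e-6)
})

test_that("printed two-group effect sizes are reproduced by d = t*sqrt(1/n1+1/n2)", {
  expect_equal(round(welch_d(0.42, 32, 16), 2), 0.13)
  expect_equal(round(welch_d(0.15, 32, 16), 2), 0.05)
})

test_that("CI reconstruction from summary statistics round-trips", {
  ci <- welch_ci_from_summary(-6.62, -2.35, 32.82)
  expect_equal(round(ci, 2), c(-12.35, -0.89))
  ci0 <- welch_ci_from_summary(0, 1, 30)
  expect_equal(ci0[1], -ci0[2])
  expect_equal(mean(welch_ci_from_summary(3.3, 2.1, 25)), 3.3)
  expect_error(welch_ci_from_summary(1, 0, 10), "t = 0")
})

test_that("SMM critical values match the independence formula", {
  expect_equal(round(smm_crit(1), 2), 1.96)
  # numerical inversion oracle for K = 10
  f <- function(c) (2 * pnorm(c) - 1)^10 - 0.95
  oracle <- uniroot(f, c(1, 5), tol = 1e-10)$root
  expect_equal(smm_crit(10), oracle, tolerance = 1e-8)
  expect_equal(round(smm_crit(10), 2), 2.8)
})

test_that("design-point statistics and p-values are internally consistent", {
  jp <- jn_point(16.42, 23.12, 3.43)
  expect_equal(round(jp$stat, 2), -1.95)
  expect_equal(round(jp$p, 3), 0.051)
  jp2 <- jn_point(15.86, 21.80, 2.90)
  expect_equal(round(jp2$stat, 2), -2.05)
})

test_that("jn_ancova recovers a planted group offset and is null-calibrated", {
  set.seed(31)
  n1 <- 40; n2 <- 25
  x <- c(rnorm(n1, 100, 15), rnorm(n2, 100, 15))
  grp <- rep(c("a", "b"), c(n1, n2))
  delta <- 4
  y <- 0.5 * x + delta * (grp == "b") + rnorm(n1 + n2, 0, 2)
  res <- jn_ancova(y, x, grp, B = 600, seed = 8)
  expect_equal(nrow(res), 10)
  # predicted difference approximates -delta (g1 - g2) at every point
  expect_true(all(abs((res$est_g1 - res$est_g2) + delta) < 4 * res$se))
  # stat and p columns mutually consistent under the normal reference
  expect_equal(res$p, 2 * pnorm(-abs(res$stat)), tolerance = 1e-3)
  expect_equal(attr(res, "crit"), smm_crit(10))

  # identical parallel lines: everything near zero
  y0 <- 0.5 * x + rnorm(n1 + n2, 0, 1)
  res0 <- jn_ancova(y0, x, grp, B = 600, seed = 9)
  expect_true(all(abs(res0$stat) < 4))
  expect_false(any(res0$significant &
                     abs(res0$stat) < attr(res0, "crit")))
})

test_that("jn_ancova design points span the quartiles with even spacing", {
  set.seed(1)
  x <- rnorm(60)
  y <- rnorm(60)
  g <- rep(0:1, 30)
  res <- jn_ancova(y, x, g, B = 200, seed = 2)
  q <- quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  expect_equal(res$x[1], q[1])
  expect_equal(res$x[10], q[2])
  expect_equal(diff(res$x), rep(diff(q) / 9, 9), tolerance = 1e-12)
  expect_error(jn_ancova(y, rep(1, 60), g), "constant")
})
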