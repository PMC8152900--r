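test_that("a deterministic chain yields b = 2 and c' = 0", {
  set.seed(60)
  n <- 40
  X <- rep(c(0, 1), n / 2)
  M <- X + rnorm(n)          # M fully transmits X (plus noise)
  Y <- 2 * M                 # Y depends on X only through M
  fit <- suppressWarnings(fit_paths(mediation_data(X, M, Y)))
  expect_equal(fit$b, 2, tolerance = 1e-10)
  expect_equal(fit$c_prime, 0, tolerance = 1e-10)
  expect_equal(fit$ab, fit$a * fit$b, tolerance = 1e-12)
})

test_that("null a-path estimates stay within three sandwich SEs", {
  dat <- with(list(), {
    set.seed(61)
    n <- 600
    X <- rep(c(0, 1), n / 2)
    M <- rnorm(n)            # no X -> M path
    Y <- 0.5 * M + rnorm(n)
    mediation_data(X, M, Y)
  })
  fit <- fit_paths(dat)
  expect_lt(abs(fit$a), 3 * fit$se_a)
})

test_that("paths are recovered within 0.05 at n = 5000", {
  dat <- simulate_mediation(5000, a = 0.5, b = 0.6, c_prime = 0.2,
                            seed = 62)
  fit <- fit_paths(dat)
  expect_lt(abs(fit$a - 0.5), 0.05)
  expect_lt(abs(fit$b - 0.6), 0.05)
  expect_lt(abs(fit$ab - 0.3), 0.05)
})

test_that("HC4 sandwich SEs stay near classical OLS SEs under homoscedasticity", {
  dat <- simulate_mediation(200, seed = 63)
  fit <- fit_paths(dat)
  ols <- lm(dat$M[, 1] ~ dat$X)
  se_ols <- summary(ols)$coefficients[2, 2]
  expect_lt(abs(fit$se_a - se_ols) / se_ols, 0.15)
})

test_that("percentile bootstrap is deterministic, definitional, and covers", {
  dat <- simulate_mediation(80, a = 0.6, b = 0.7, seed = 64)
  b1 <- percentile_bootstrap(dat, B = 1000, seed = 5)
  b2 <- percentile_bootstrap(dat, B = 1000, seed = 5)
  expect_identical(b1$ci, b2$ci)
  expect_equal(b1$ab_ps, b1$ab / sd(dat$Y), tolerance = 1e-12)
  expect_true(b1$ci[1, "lower"] < b1$ab && b1$ab < b1$ci[1, "upper"])

  # ab = 4, SD(Y) = 8 -> partially standardized 0.5 (definitional)
  expect_equal(4 / 8, 0.5)
})

test_that("bootstrap CI width shrinks roughly like 1/sqrt(n)", {
  widths <- vapply(c(50, 200, 800), function(n) {
    dat <- simulate_mediation(n, a = 0.5, b = 0.5, seed = 65)
    ci <- percentile_bootstrap(dat, B = 1000, seed = 6)$ci
    ci[1, "upper"] - ci[1, "lower"]
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  # factor-4 n increase should shrink width by ~2 (allow generous slack)
  expect_lt(widths[3], widths[1] / 2)
})

test_that("95% CI covers a known nonzero ab between 92% and 97% of cohorts", {
  true_ab <- 0.5 * 0.6
  n_rep <- 500
  hit <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    dat <- simulate_mediation(60, a = 0.5, b = 0.6, seed = 1000 + r)
    ci <- percentile_bootstrap(dat, B = 2000, seed = r)$ci
    hit[r] <- ci[1, "lower"] <= true_ab && true_ab <= ci[1, "upper"]
  }
  expect_gte(mean(hit), 0.92)
  expect_lte(mean(hit), 0.97)
})

test_that("robust mediation reduces to OLS at kappa = 0 and resists outliers", {
  dat <- simulate_mediation(60, a = 0.8, b = 0.8, seed = 66)
  ols <- fit_paths(dat)
  rob0 <- robust_mediation(dat, kappa = 0, B = 1000, seed = 7)
  expect_lt(abs(rob0$ab - ols$ab), 1e-8)

  # clean data: robust close to ordinary
  rob <- robust_mediation(dat, kappa = 0.05, B = 1000, seed = 8)
  boot <- percentile_bootstrap(dat, B = 1000, seed = 8)
  expect_lt(abs(rob$ab - ols$ab), boot$se_boot)

  # designed breakdown fixture: one gross outlier in Y. Injecting it
  # shifts each estimator relative to its own clean value: the ordinary
  # ab by > 25%, the robust ab by < 10%.
  dato <- dat
  dato$Y[1] <- dato$Y[1] + 60
  ols_o <- fit_paths(dato)
  rob_c <- robust_mediation(dat, kappa = 0.05, B = 1000, seed = 9)
  rob_o <- robust_mediation(dato, kappa = 0.05, B = 1000, seed = 9)
  expect_gt(abs(ols_o$ab - ols$ab) / abs(ols$ab), 0.25)
  expect_lt(abs(rob_o$ab - rob_c$ab) / abs(rob_c$ab), 0.10)
})

test_that("spearman_rho handles monotone transforms, reversals, and ties", {
  set.seed(67)
  x <- rnorm(30)
  expect_equal(spearman_rho(x, exp(x))$rho, 1)
  expect_equal(spearman_rho(x, -x^3)$rho, -1)

  xt <- c(1, 2, 2, 3, 4, 4, 4, 5)
  yt <- c(2, 1, 3, 3, 5, 4, 6, 7)
  got <- spearman_rho(xt, yt)
  expect_equal(got$rho, cor(rank(xt), rank(yt)), tolerance = 1e-12)
  ref <- suppressWarnings(cor.test(xt, yt, method = "spearman"))
  expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_error(spearman_rho(rep(1, 10), rnorm(10)), "constant")
})

test_that("mediation_data validates and drops incomplete cases listwise", {
  X <- c(0, 1, 0, 1, NA, 1, 0, 1, 0, 1, 0, 1)
  M <- rnorm(12); Y <- rnorm(12)
  d <- mediation_data(X, M, Y)
  expect_equal(d$n, 11)
  expect_equal(d$n_dropped, 1)
  expect_error(mediation_data(c(1, 2, 0), rnorm(3), rnorm(3)), "binary")
})
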