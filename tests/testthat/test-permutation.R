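test_that("aspin_welch_v matches its formula and welch_test", {
  expect_equal(aspin_welch_v(c(1, 2, 3, 4, 5, 6), c(1, 1, 1, 0, 0, 0)),
               (2 - 5) / sqrt(1 / 3 + 1 / 3), tolerance = 1e-12)
  expect_equal(aspin_welch_v(c(1, 2, 3, 1, 2, 3), c(1, 1, 1, 0, 0, 0)), 0)
  set.seed(40)
  x <- rnorm(12); y <- rnorm(9, 0.5)
  v <- aspin_welch_v(c(x, y), rep(c(1, 0), c(12, 9)))
  expect_equal(v, welch_test(x, y)$t, tolerance = 1e-12)
  # contrast direction flips the sign
  expect_equal(aspin_welch_v(c(x, y), rep(c(1, 0), c(12, 9)),
                             contrast = -1), -v)
})

test_that("freedman_lane_flip reconstructs observed data under identity", {
  set.seed(41)
  n <- 10
  cov <- cbind(rnorm(n), rbinom(n, 1, 0.5))
  y <- rnorm(n)
  expect_equal(freedman_lane_flip(y, cov, rep(1, n)), y, tolerance = 1e-12)
  # no covariates: flipping mean-centered values
  f <- c(1, -1, 1, -1, 1, -1, 1, -1, 1, -1)
  expect_equal(freedman_lane_flip(y, NULL, f),
               mean(y) + f * (y - mean(y)), tolerance = 1e-12)
})

test_that("n = 4 exhaustive flips match direct enumeration of the null", {
  set.seed(42)
  y <- rnorm(4)
  g <- c(1L, 1L, 0L, 0L)
  sch <- perm_scheme(g, method = "exhaustive")
  expect_equal(nrow(sch$flips), 16)
  stats <- neuroplast:::flip_vstat_matrix(matrix(y, ncol = 1), g, NULL,
                                          sch$flips)
  # oracle: rebuild each flip by hand
  fit <- mean(y); r <- y - fit
  oracle <- apply(sch$flips, 1, function(s) {
    yy <- fit + s * r
    aspin_welch_v(yy, g)
  })
  expect_equal(as.vector(stats), oracle, tolerance = 1e-12)
})

test_that("TFCE closed form, zero map, and brute-force oracle agree", {
  a <- array(0, c(5, 5, 5)); a[3, 3, 3] <- 2
  enh <- tfce(a, tfce_params(n_steps = 20))
  expect_equal(enh[3, 3, 3], 0.1 * sum((0.1 * (1:20))^2), tolerance = 1e-12)
  expect_equal(enh[3, 3, 3], 2.87, tolerance = 1e-10)

  expect_equal(tfce(array(0, c(4, 4, 4))), array(0, c(4, 4, 4)))
  # negative values are not enhanced
  neg <- array(-abs(rnorm(64)), c(4, 4, 4))
  expect_equal(tfce(neg), array(0, c(4, 4, 4)))

  set.seed(43)
  x <- array(rnorm(8^3), c(8, 8, 8))
  p <- tfce_params(n_steps = 50)
  expect_lt(max(abs(tfce(x, p) - oracle_tfce(x, p$E, p$H, p$n_steps))),
            1e-9)
  # 6-connectivity path against the oracle too
  p6 <- tfce_params(n_steps = 30, connectivity = 6)
  expect_lt(max(abs(tfce(x, p6) -
                      oracle_tfce(x, p6$E, p6$H, p6$n_steps,
                                  connectivity = 6))), 1e-9)
})

test_that("permutation p-values respect the +1 convention and monotonicity", {
  set.seed(44)
  n <- 12
  g <- rep(c(1L, 0L), c(8, 4))
  dims <- c(4, 4, 2)
  Y <- matrix(rnorm(n * prod(dims)), n)
  Y[g == 1, 10] <- Y[g == 1, 10] + 50  # one overwhelming voxel
  sch <- perm_scheme(g, n_flips = 99, seed = 3)
  res <- run_glm_permutation(Y, g, NULL, sch, dims, array(TRUE, dims))
  # p at the peak equals (1 + #{permuted maxima >= peak TFCE}) / (1 + B)
  expect_equal(min(res$p_fwe),
               (1 + sum(res$max_dist >= max(res$tfce))) / (1 + 99))
  expect_true(all(res$p_fwe > 0 & res$p_fwe <= 1))
  # p monotone nonincreasing in the enhanced statistic
  ord <- order(res$tfce)
  expect_true(all(diff(res$p_fwe[ord]) <= 0))
  # identity flip reproduces the observed statistic
  expect_equal(res$v, aspin_welch_v(Y, g), tolerance = 1e-12)
})

test_that("exhaustive enumeration equals distinct Monte-Carlo sampling at 2^n", {
  set.seed(45)
  n <- 6
  g <- rep(c(1L, 0L), each = 3)
  y <- matrix(rnorm(n * 8), n)
  dims <- c(2, 2, 2)
  ex <- perm_scheme(g, method = "exhaustive")
  mc <- perm_scheme(g, n_flips = 2^n - 1, seed = 10, method = "distinct")
  r1 <- run_glm_permutation(y, g, NULL, ex, dims, array(TRUE, dims))
  r2 <- run_glm_permutation(y, g, NULL, mc, dims, array(TRUE, dims))
  expect_equal(r1$p_fwe, r2$p_fwe, tolerance = 0)
  expect_equal(sort(r1$max_dist), sort(r2$max_dist), tolerance = 1e-12)
})

test_that("schemes are reproducible and carry the identity first", {
  g <- rep(c(1L, 0L), c(5, 3))
  s1 <- perm_scheme(g, 50, seed = 77)
  s2 <- perm_scheme(g, 50, seed = 77)
  expect_identical(s1$flips, s2$flips)
  expect_equal(s1$flips[1, ], rep(1, 8))
  expect_true(all(s1$flips %in% c(-1, 1)))
})
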