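test_that("eigenvector centrality is uniform under exchangeable correlation", {
  d <- c(4, 2, 1); N <- prod(d); Tn <- 40
  base <- rnorm(Tn)
  # identical timeseries at every voxel (add tiny jitter-free copies)
  ts <- array(rep(base, each = N), c(d, Tn))
  ec <- eigenvector_centrality(ts, array(TRUE, d))
  expect_equal(as.vector(ec$values), rep(1 / sqrt(N), N), tolerance = 1e-6)

  # three voxels with exchangeable pairwise correlation
  set.seed(8)
  shared <- rnorm(200)
  d3 <- c(3, 1, 1)
  ts3 <- array(NA_real_, c(d3, 200))
  for (i in 1:3) ts3[i, 1, 1, ] <- shared + rnorm(200)
  ec3 <- eigenvector_centrality(ts3, array(TRUE, d3))
  # exchangeability => near-uniform eigenvector
  expect_equal(as.vector(ec3$values), rep(1 / sqrt(3), 3), tolerance = 0.05)
})

test_that("implicit power iteration equals the explicit eigendecomposition", {
  d <- c(5, 4, 3); Tn <- 120
  ts <- rand_timeseries(d, Tn, seed = 101)
  mask <- array(TRUE, d)
  ec <- eigenvector_centrality(ts, mask)
  Z <- scale(t(matrix(ts, prod(d), Tn)))
  A <- (cor(Z) + 1) / 2
  ev <- eigen(A, symmetric = TRUE)$vectors[, 1]
  ev <- ev * sign(sum(ev))
  expect_lt(max(abs(ec$values[mask] - ev)), 1e-6)
  expect_equal(sum(ec$values[mask]^2), 1, tolerance = 1e-6)
  expect_true(all(ec$values[mask] >= 0))
  expect_true(attr(ec, "iterations") <= 100)
})

test_that("EC is invariant to voxel order, offset, and positive scaling", {
  d <- c(4, 4, 3); Tn <- 80
  # structured data (shared network signal) so the dominant eigenvalue is
  # well separated and power iteration resolves the eigenvector sharply
  set.seed(55)
  shared <- rnorm(Tn)
  ts <- rand_timeseries(d, Tn, seed = 55)
  for (i in 1:2) ts[i, 1, 1, ] <- ts[i, 1, 1, ] + shared
  mask <- array(TRUE, d)
  ec <- eigenvector_centrality(ts, mask, tol = 1e-9)
  # offset + scaling of all timeseries
  ec2 <- eigenvector_centrality(ts * 3.7 + 11, mask, tol = 1e-9)
  expect_lt(max(abs(ec$values - ec2$values)), 1e-6)
  # voxel reordering (permute x slabs)
  perm <- c(3, 1, 4, 2)
  tsp <- ts[perm, , , , drop = FALSE]
  ecp <- eigenvector_centrality(tsp, mask, tol = 1e-9)
  expect_lt(max(abs(ecp$values - ec$values[perm, , ])), 1e-6)
})

test_that("degree centrality matches the explicit row-sum oracle", {
  d <- c(5, 4, 3); Tn <- 100
  ts <- rand_timeseries(d, Tn, seed = 77)
  mask <- array(TRUE, d)
  Z <- scale(t(matrix(ts, prod(d), Tn)))
  R <- cor(Z); diag(R) <- 0
  Rp <- R; Rp[Rp <= 0] <- 0
  dc <- degree_centrality(ts, mask)
  expect_lt(max(abs(dc$values[mask] - rowSums(Rp))), 1e-8)
  # tau = -1: plain row sum including negatives
  dcm <- degree_centrality(ts, mask, tau = -1)
  expect_lt(max(abs(dcm$values[mask] - rowSums(R))), 1e-8)
  # blockwise path equals single-block path
  dcb <- degree_centrality(ts, mask, block_size = 7L)
  expect_equal(dcb$values, dc$values, tolerance = 1e-12)
})

test_that("identical timeseries give DC = N-1; anticorrelated pairs give 0", {
  d <- c(3, 2, 1); N <- prod(d); Tn <- 50
  base <- rnorm(Tn)
  ts <- array(rep(base, each = N), c(d, Tn))
  dc <- degree_centrality(ts, array(TRUE, d))
  expect_equal(as.vector(dc$values), rep(N - 1, N), tolerance = 1e-8)

  d2 <- c(2, 1, 1)
  ts2 <- array(NA_real_, c(d2, Tn))
  ts2[1, 1, 1, ] <- base
  ts2[2, 1, 1, ] <- -base
  dc2 <- degree_centrality(ts2, array(TRUE, d2))
  expect_equal(as.vector(dc2$values), c(0, 0))
})

test_that("zero-variance voxels are rejected with their indices", {
  d <- c(3, 1, 1); Tn <- 20
  ts <- rand_timeseries(d, Tn, seed = 1)
  ts[2, 1, 1, ] <- 5
  expect_error(eigenvector_centrality(ts, array(TRUE, d)),
               "zero-variance.*2")
})

test_that("sbca recovers known correlations and caps r = 1", {
  Tn <- 400
  set.seed(12)
  seed_ts <- rnorm(Tn)
  d <- c(3, 1, 1)
  ts <- array(NA_real_, c(d, Tn))
  ts[1, 1, 1, ] <- seed_ts                       # the seed voxel itself
  r_target <- 0.6
  ts[2, 1, 1, ] <- r_target * seed_ts + sqrt(1 - r_target^2) * rnorm(Tn)
  ts[3, 1, 1, ] <- rnorm(Tn)
  seed_mask <- array(c(TRUE, FALSE, FALSE), d)
  res <- sbca(list(ts), seed_mask, array(TRUE, d))
  # voxel identical to the seed mean: capped Fisher z
  expect_equal(res$z$values[1, 1, 1], atanh(1 - 1e-7))
  expect_equal(res$n_capped, 1L)
  # planted correlation: z near atanh(0.6), sampling tolerance 3/sqrt(T-3)
  expect_lt(abs(res$z$values[2, 1, 1] - atanh(r_target)),
            3 / sqrt(Tn - 3))
  # independent voxel: z near 0
  expect_lt(abs(res$z$values[3, 1, 1]), 3 / sqrt(Tn - 3))
  # standardized beta equals r for simple regression
  expect_equal(res$beta$values[2, 1, 1], tanh(res$z$values[2, 1, 1]),
               tolerance = 1e-12)
})

test_that("z-map parcellation thresholds at mean + k*SD and labels by size", {
  d <- c(6, 6, 6)
  mask <- array(TRUE, d)
  z <- array(0, d)
  expect_equal(max(parcellate_zmap(volume_grid(z), mask)), 0)

  set.seed(6)
  z <- array(rnorm(prod(d), 0, 0.1), d)
  z[2, 2, 2] <- mean(z) + 5 * sd(z)
  lab <- parcellate_zmap(volume_grid(z), mask, k_sd = 3)
  expect_equal(sum(lab > 0), 1)
  expect_equal(lab[2, 2, 2], 1L)

  # two well-separated blobs vs flood-fill oracle
  z2 <- array(rnorm(prod(d), 0, 0.05), d)
  z2[1:2, 1:2, 1] <- 3
  z2[5:6, 5:6, 6] <- 2.5
  lab2 <- parcellate_zmap(volume_grid(z2), mask, k_sd = 2)
  fg <- z2 > mean(z2) + 2 * sd(z2)
  oracle <- oracle_label(fg)
  expect_equal(max(lab2), max(oracle))
  # same partition (labels may be renumbered)
  for (k in seq_len(max(oracle))) {
    got <- unique(lab2[oracle == k])
    expect_length(got, 1)
    expect_gt(got, 0)
  }
  # labels ordered by decreasing size
  expect_true(all(diff(attr(lab2, "sizes")) <= 0))
})
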