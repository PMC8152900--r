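#' TFCE parameters
#'
#' @param E extent exponent (default 0.5).
#' @param H height exponent (default 2.0).
#' @param n_steps number of integration thresholds; each map is enhanced
#'   with its own `dh = max(map) / n_steps`, so the enhancement functional
#'   treats every permutation draw identically (a requirement for exact
#'   max-statistic FWE control).
#' @param connectivity 6, 18, or 26.
#' @return list of class `tfce_params`.
#' @export
tfce_params <- function(E = 0.5, H = 2.0, n_steps = 100L,
                        connectivity = 26L) {
  stopifnot(E >= 0, H >= 0, n_steps >= 10L,
            connectivity %in% c(6L, 18L, 26L))
  structure(list(E = E, H = H, n_steps = as.integer(n_steps),
                 connectivity = as.integer(connectivity)),
            class = "tfce_params")
}

#' Threshold-free cluster enhancement of a statistic map
#'
#' For each voxel `p`, sums `extent(h, p)^E * h^H * dh` over thresholds
#' `h = dh, 2 dh, ..., n_steps * dh`, where `extent(h, p)` is the size of
#' `p`'s connected suprathreshold component at height `h`. Only positive
#' values are enhanced (one-sided contrasts); the opposite direction is
#' run as a separate contrast on the negated map.
#'
#' @param map a [volume_grid] or 3D array of statistic values.
#' @param params a [tfce_params].
#' @param dh threshold step; by default `max(map) / n_steps`.
#' @return object of the same type as `map` with enhanced values.
#' @export
tfce <- function(map, params = tfce_params(), dh = NULL) {
  vals <- if (inherits(map, "volume_grid")) map$values else map
  stopifnot(is.array(vals), length(dim(vals)) == 3L)
  x <- as.vector(vals)
  x[is.na(x)] <- 0
  enh <- .tfce_cpp(x, dim(vals), params$E, params$H, params$n_steps,
                   if (is.null(dh)) -1 else dh, params$connectivity)
  out <- array(enh, dim(vals))
  if (inherits(map, "volume_grid")) {
    g <- volume_grid(out, map$voxel_size, map$affine)
    return(g)
  }
  out
}

#' Sign-flip permutation scheme
#'
#' Holds `n_flips` random sign vectors plus a prepended identity draw
#' (all +1), so the flip matrix has `n_flips + 1` rows. Signs are drawn
#' independently per subject; the two group labels act as exchangeability
#' blocks in the sense that they define the variance groups of the
#' Aspin-Welch statistic, not as flip-constraint units. With
#' `method = "exhaustive"` all `2^n` sign patterns are enumerated
#' (identity first); `method = "distinct"` draws `n_flips` distinct
#' non-identity patterns without replacement.
#'
#' @param groups binary group labels (0 = control, 1 = intervention), one
#'   per subject.
#' @param n_flips number of random draws (ignored for exhaustive).
#' @param seed integer seed.
#' @param method `"mc"`, `"exhaustive"`, or `"distinct"`.
#' @return list of class `perm_scheme` with elements `flips`
#'   (`(n_flips + 1) x n` sign matrix, first row identity), `n_flips`,
#'   `blocks`, `seed`.
#' @export
perm_scheme <- function(groups, n_flips = 5000L, seed = 1L,
                        method = c("mc", "exhaustive", "distinct")) {
  method <- match.arg(method)
  groups <- as.integer(groups)
  n <- length(groups)
  stopifnot(n >= 2L, all(groups %in% c(0L, 1L)))
  if (method == "exhaustive" || method == "distinct") {
    if (n > 20L) stop("full enumeration limited to n <= 20 subjects")
    full <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))[, n:1, drop = FALSE]
    dimnames(full) <- NULL
    id <- which(apply(full, 1, function(r) all(r == 1)))
    others <- full[-id, , drop = FALSE]
    if (method == "exhaustive") {
      flips <- rbind(rep(1, n), others)
      n_flips <- nrow(others)
    } else {
      if (n_flips > nrow(others))
        stop("cannot draw ", n_flips, " distinct flips from ",
             nrow(others), " non-identity patterns")
      pick <- with_seed(seed, sample.int(nrow(others), n_flips))
      flips <- rbind(rep(1, n), others[pick, , drop = FALSE])
    }
  } else {
    flips <- with_seed(seed, rbind(
      rep(1, n),
      matrix(sample(c(-1, 1), n_flips * n, replace = TRUE),
             nrow = n_flips)))
  }
  structure(list(flips = flips, n_flips = as.integer(n_flips),
                 blocks = groups, seed = as.integer(seed)),
            class = "perm_scheme")
}

#' Aspin-Welch v statistic
#'
#' Two-sample statistic with unpooled variances (the Behrens-Fisher-safe
#' analogue of the t statistic):
#' `v = (mean_1 - mean_0) / sqrt(s1^2/n1 + s0^2/n0)`, where group 1 is
#' the intervention group, multiplied by the contrast direction.
#'
#' @param y numeric vector (one value per subject) or `n x V` matrix.
#' @param groups binary labels (0/1), one per subject.
#' @param contrast +1 (greater in intervention) or -1.
#' @return scalar or length-V vector; voxels with zero variance in both
#'   groups are `NA`.
#' @export
aspin_welch_v <- function(y, groups, contrast = 1) {
  groups <- as.integer(groups)
  if (is.vector(y)) y <- matrix(y, ncol = 1L)
  i1 <- groups == 1L; i0 <- groups == 0L
  n1 <- sum(i1); n0 <- sum(i0)
  if (n1 < 2L || n0 < 2L) stop("each group needs at least 2 subjects")
  m1 <- colMeans(y[i1, , drop = FALSE]); m0 <- colMeans(y[i0, , drop = FALSE])
  v1 <- apply(y[i1, , drop = FALSE], 2, var)
  v0 <- apply(y[i0, , drop = FALSE], 2, var)
  se <- sqrt(v1 / n1 + v0 / n0)
  out <- contrast * (m1 - m0) / se
  out[se == 0] <- NA_real_
  if (length(out) == 1L) out <- as.numeric(out)
  out
}

#' Freedman-Lane data reconstruction for one sign-flip
#'
#' Residuals of the data on the nuisance-only model are sign-flipped per
#' subject and the nuisance fit is re-added; the test statistic is then
#' recomputed on the reconstructed data. The identity flip reproduces the
#' observed data exactly.
#'
#' @param y numeric vector or `n x V` matrix of per-subject values.
#' @param nuisance nuisance covariate matrix (intercept added), or NULL
#'   for pure mean-centering.
#' @param flip length-n sign vector.
#' @return reconstructed values, same shape as `y`.
#' @export
freedman_lane_flip <- function(y, nuisance = NULL, flip) {
  vec <- is.vector(y)
  if (vec) y <- matrix(y, ncol = 1L)
  Z <- build_design(nrow(y), nuisance, add_intercept = TRUE)
  qrZ <- qr(Z)
  if (qrZ$rank < ncol(Z)) stop("nuisance design is rank deficient")
  fit <- qr.fitted(qrZ, y)
  res <- y - fit
  out <- fit + flip * res
  if (vec) out <- as.vector(out)
  out
}

# Aspin-Welch v statistics for every flip at once, via the identity
# flipped_i = fit_i + s_i r_i (so sums and sums of squares over each group
# are linear in the flip signs). Returns (n_flips + 1) x V matrix whose
# first row is the observed statistic.
flip_vstat_matrix <- function(Y, groups, nuisance, flips, contrast = 1) {
  n <- nrow(Y)
  Z <- build_design(n, nuisance, add_intercept = TRUE)
  qrZ <- qr(Z)
  if (qrZ$rank < ncol(Z)) stop("nuisance design is rank deficient")
  fit <- qr.fitted(qrZ, Y)
  R <- Y - fit
  i1 <- groups == 1L; i0 <- groups == 0L
  n1 <- sum(i1); n0 <- sum(i0)
  sq <- fit^2 + R^2
  C <- fit * R
  A1 <- colSums(fit[i1, , drop = FALSE]); A0 <- colSums(fit[i0, , drop = FALSE])
  Q1 <- colSums(sq[i1, , drop = FALSE]); Q0 <- colSums(sq[i0, , drop = FALSE])
  S1 <- flips[, i1, drop = FALSE] %*% R[i1, , drop = FALSE]
  S0 <- flips[, i0, drop = FALSE] %*% R[i0, , drop = FALSE]
  X1 <- flips[, i1, drop = FALSE] %*% C[i1, , drop = FALSE]
  X0 <- flips[, i0, drop = FALSE] %*% C[i0, , drop = FALSE]
  m1 <- sweep(S1, 2, A1, "+") / n1
  m0 <- sweep(S0, 2, A0, "+") / n0
  ss1 <- sweep(2 * X1, 2, Q1, "+")
  ss0 <- sweep(2 * X0, 2, Q0, "+")
  v1 <- pmax(ss1 - n1 * m1^2, 0) / (n1 - 1)
  v0 <- pmax(ss0 - n0 * m0^2, 0) / (n0 - 1)
  se <- sqrt(v1 / n1 + v0 / n0)
  out <- contrast * (m1 - m0) / se
  out[se == 0] <- 0
  out
}

expand_to_grid <- function(vals, dims, mask) {
  a <- array(0, dims)
  a[mask] <- vals
  a
}

#' Permutation GLM with TFCE and max-statistic FWE correction
#'
#' Group inference on per-subject change maps: the observed Aspin-Welch
#' v map (intervention vs control, nuisance covariates partialled out by
#' Freedman-Lane sign-flipping of reduced-model residuals) is
#' TFCE-enhanced; for each flip the statistic map is rebuilt and
#' enhanced, and the spatial maximum recorded. The FWE-corrected p-value
#' at voxel v is `(1 + #{flips with max >= TFCE_v}) / (1 + n_flips)`,
#' counting non-identity flips only.
#'
#' @param Y `n x V` matrix of masked per-subject change-map values (use
#'   [stack_maps] to build it from volume grids).
#' @param groups binary group labels (1 = intervention).
#' @param covariates nuisance covariate matrix (age, sex, baseline), or
#'   NULL.
#' @param scheme a [perm_scheme].
#' @param dims 3D grid dimensions.
#' @param mask logical 3D analysis mask with `sum(mask) == ncol(Y)`.
#' @param params a [tfce_params].
#' @param contrast +1 or -1 contrast direction.
#' @return list with `v` (observed statistic), `tfce` (enhanced observed),
#'   `p_fwe` (per masked voxel), `max_dist` (permutation maxima), `dh`.
#' @export
run_glm_permutation <- function(Y, groups, covariates = NULL, scheme,
                                dims, mask, params = tfce_params(),
                                contrast = 1) {
  stopifnot(inherits(scheme, "perm_scheme"))
  groups <- as.integer(groups)
  if (nrow(scheme$flips) != nrow(Y) + 1L &&
      ncol(scheme$flips) != nrow(Y))
    stop("permutation scheme does not match the number of subjects")
  if (ncol(scheme$flips) != nrow(Y))
    stop("permutation scheme does not match the number of subjects")
  mask <- check_mask(mask, dims)
  if (sum(mask) != ncol(Y)) stop("mask voxel count does not match Y columns")
  stats <- flip_vstat_matrix(Y, groups, covariates, scheme$flips, contrast)
  v_obs <- stats[1L, ]
  mx <- max(v_obs, 0)
  if (mx <= 0) {
    return(list(v = v_obs, tfce = rep(0, length(v_obs)),
                p_fwe = rep(1, length(v_obs)),
                max_dist = rep(0, scheme$n_flips), dh = NA_real_))
  }
  dh <- mx / params$n_steps
  vox_idx <- which(as.vector(mask)) - 1L
  enh_obs <- .tfce_cpp(as.vector(expand_to_grid(v_obs, dims, mask)),
                       as.integer(dims), params$E, params$H,
                       params$n_steps, dh, params$connectivity)
  tfce_obs <- enh_obs[vox_idx + 1L]
  maxima <- .tfce_max_batch_cpp(stats[-1L, , drop = FALSE], vox_idx,
                                as.integer(dims), params$E, params$H,
                                params$n_steps, -1, params$connectivity)
  p_fwe <- (1 + vapply(tfce_obs, function(t0) sum(maxima >= t0),
                       numeric(1))) / (1 + scheme$n_flips)
  list(v = v_obs, tfce = tfce_obs, p_fwe = p_fwe, max_dist = maxima,
       dh = dh)
}

#' Stack volume grids into a subjects-by-voxels matrix
#'
#' @param maps list of [volume_grid]s with identical shape.
#' @param mask logical analysis mask.
#' @return `length(maps) x sum(mask)` numeric matrix.
#' @export
stack_maps <- function(maps, mask) {
  d <- dim(maps[[1L]]$values)
  mask <- check_mask(mask, d)
  t(vapply(maps, function(g) {
    stopifnot(identical(dim(g$values), d))
    g$values[mask]
  }, numeric(sum(mask))))
}

# within-voxel permutation-rank p-values, column-wise on a draws x voxels
# statistic matrix: p[b, v] = #{b' : stat[b', v] >= stat[b, v]} / n_draws
rank_p_matrix <- function(stats) {
  B <- nrow(stats)
  apply(stats, 2, function(col) {
    B + 1 - rank(col, ties.method = "min")
  }) / B
}

#' Fisher combination of two p-values
#' @param p1,p2 partial-test p-values in (0, 1].
#' @return `T = -2 (ln p1 + ln p2)`.
#' @export
fisher_combine <- function(p1, p2) -2 * (log(p1) + log(p2))

#' Nonparametric-combination (Fisher) mediation screen
#'
#' Joint voxel-wise test of the two partial hypotheses that make up the
#' mediation pattern: (1) a directional group effect on the residualized
#' change map (Aspin-Welch v, age/sex adjusted) and (2) a directional
#' slope of the residualized behavioral gain on the map (adjusted for
#' age, sex, and group). Both submodels are permuted with the SAME
#' sign-flip vector at every draw (synchronized permutations); each
#' partial statistic is converted to a p-value by its rank within that
#' voxel's own permutation distribution, the two are combined with
#' Fisher's `T = -2 (ln p1 + ln p2)`, the T maps are TFCE-enhanced, and
#' max-statistic FWE correction is applied as in
#' [run_glm_permutation]. Suprathreshold voxels at `alpha` are returned
#' as labeled clusters.
#'
#' @inheritParams run_glm_permutation
#' @param behavior residualized behavioral gain score per subject.
#' @param age,sex nuisance covariates.
#' @param alpha FWE significance level for cluster formation.
#' @param p_method `"rank"` (permutation-rank partial p-values, default)
#'   or `"parametric"` (t reference for the slope, normal for v).
#' @return list with `T` (observed combined map), `tfce`, `p_fwe`,
#'   `clusters` (data.frame: label, extent, peak 0-based x/y/z, peak p),
#'   `labels` (3D label array), `max_dist`.
#' @export
npc_fisher_screen <- function(Y, groups, behavior, age, sex, scheme,
                              dims, mask, params = tfce_params(),
                              contrast = 1, alpha = 0.05,
                              p_method = c("rank", "parametric")) {
  p_method <- match.arg(p_method)
  stopifnot(inherits(scheme, "perm_scheme"))
  groups <- as.integer(groups)
  n <- nrow(Y)
  if (length(behavior) != n) stop("behavior scores incomplete")
  mask <- check_mask(mask, dims)
  if (sum(mask) != ncol(Y)) stop("mask voxel count does not match Y columns")
  flips <- scheme$flips
  if (ncol(flips) != n)
    stop("permutation scheme does not match the number of subjects")

  # partial test 1: group effect on the map, age/sex as nuisance
  nuis1 <- cbind(age = age, sex = sex)
  stats1 <- flip_vstat_matrix(Y, groups, nuis1, flips, contrast)

  # partial test 2: slope of behavior on the map, age/sex/group nuisance.
  # With the map as the regression outcome, Freedman-Lane flips its
  # reduced-model residuals; the t statistic of the behavior regressor is
  # assembled from flip-linear building blocks.
  Z2 <- build_design(n, cbind(age = age, sex = sex, group = groups), TRUE)
  qr2 <- qr(Z2)
  if (qr2$rank < ncol(Z2)) stop("nuisance design is rank deficient")
  fit2 <- qr.fitted(qr2, Y)
  R2 <- Y - fit2
  xt <- qr.resid(qr2, as.numeric(behavior))
  xn <- sqrt(sum(xt^2))
  if (xn == 0) stop("behavior is collinear with the nuisance design")
  u <- xt / xn
  U <- (flips * matrix(u, nrow(flips), n, byrow = TRUE)) %*% R2
  Qmat <- qr.Q(qr2)
  P2 <- 0
  for (j in seq_len(ncol(Qmat))) {
    Gj <- (flips * matrix(Qmat[, j], nrow(flips), n, byrow = TRUE)) %*% R2
    P2 <- P2 + Gj^2
  }
  rss <- sweep(-(P2 + U^2), 2, colSums(R2^2), "+")
  rss[rss < 0] <- 0
  df2 <- n - (qr2$rank + 1L)
  sigma <- sqrt(rss / df2)
  stats2 <- contrast * U / sigma
  stats2[sigma == 0] <- 0

  if (p_method == "rank") {
    p1 <- rank_p_matrix(stats1)
    p2 <- rank_p_matrix(stats2)
  } else {
    p1 <- pnorm(stats1, lower.tail = FALSE)
    p2 <- pt(stats2, df2, lower.tail = FALSE)
    eps <- 1 / (2 * nrow(stats1))
    p1 <- pmin(pmax(p1, eps), 1)
    p2 <- pmin(pmax(p2, eps), 1)
  }
  Tmat <- fisher_combine(p1, p2)

  T_obs <- Tmat[1L, ]
  dh <- max(T_obs) / params$n_steps
  vox_idx <- which(as.vector(mask)) - 1L
  if (dh <= 0) {
    p_fwe <- rep(1, length(T_obs))
    tfce_obs <- rep(0, length(T_obs))
    maxima <- rep(0, scheme$n_flips)
  } else {
    enh_obs <- .tfce_cpp(as.vector(expand_to_grid(T_obs, dims, mask)),
                         as.integer(dims), params$E, params$H,
                         params$n_steps, dh, params$connectivity)
    tfce_obs <- enh_obs[vox_idx + 1L]
    maxima <- .tfce_max_batch_cpp(Tmat[-1L, , drop = FALSE], vox_idx,
                                  as.integer(dims), params$E, params$H,
                                  params$n_steps, -1, params$connectivity)
    p_fwe <- (1 + vapply(tfce_obs, function(t0) sum(maxima >= t0),
                         numeric(1))) / (1 + scheme$n_flips)
  }

  fg <- array(FALSE, dims)
  fg[mask] <- p_fwe < alpha
  labels <- label_clusters(fg, connectivity = params$connectivity)
  sizes <- attr(labels, "sizes")
  p_grid <- array(NA_real_, dims)
  p_grid[mask] <- p_fwe
  clusters <- if (length(sizes)) {
    do.call(rbind, lapply(seq_along(sizes), function(k) {
      idx <- which(labels == k)
      peak <- idx[which.min(p_grid[idx])]
      co <- arrayInd(peak, dims) - 1L
      data.frame(label = k, extent = sizes[k],
                 peak_x = co[1], peak_y = co[2], peak_z = co[3],
                 peak_p = min(p_grid[idx]))
    }))
  } else {
    data.frame(label = integer(0), extent = integer(0),
               peak_x = integer(0), peak_y = integer(0),
               peak_z = integer(0), peak_p = numeric(0))
  }
  list(T = T_obs, tfce = tfce_obs, p_fwe = p_fwe, clusters = clusters,
       labels = labels, max_dist = maxima, dh = dh)
}
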