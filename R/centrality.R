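#' Voxel-wise eigenvector centrality from a 4D timeseries
#'
#' Computes the dominant eigenvector of the voxel-by-voxel similarity
#' matrix `A = (r + 1)/2`, where `r` is the Pearson correlation between
#' voxel timeseries. The shift to `(r+1)/2` makes `A` strictly positive, so
#' by Perron-Frobenius the dominant eigenvector is unique and nonnegative.
#' The matrix is never materialized: with `Z` the column-standardized
#' (unit-variance) timeseries matrix, the power-iteration product is
#' `A v = (Z (Z' v) / (T - 1) + sum(v)) / 2`, which keeps the cost linear
#' in voxels x frames even for large masks.
#'
#' @param ts 4D numeric array (x, y, z, time) of BOLD-like signals.
#' @param mask logical 3D array selecting analysis voxels (>= 2).
#' @param tol power-iteration convergence tolerance on the 2-norm change
#'   of the unit eigenvector.
#' @param max_iter maximum power iterations.
#' @return A [volume_grid] with EC values inside the mask (Euclidean norm 1
#'   over the mask), `NA` outside; attributes `iterations` and
#'   `final_delta` record convergence.
#' @export
eigenvector_centrality <- function(ts, mask, tol = 1e-6, max_iter = 100L) {
  Z <- standardize_timeseries(ts, mask)
  N <- ncol(Z); Tn <- nrow(Z)
  v <- rep(1 / sqrt(N), N)
  delta <- Inf
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    w <- (as.vector(crossprod(Z, Z %*% v)) / (Tn - 1) + sum(v)) / 2
    w <- w / sqrt(sum(w^2))
    delta <- sqrt(sum((w - v)^2))
    v <- w
    if (delta < tol) break
  }
  if (delta >= tol)
    stop(sprintf(
      "eigenvector centrality did not converge in %d iterations (delta %.3g)",
      max_iter, delta))
  out <- array(NA_real_, dim(ts)[1:3])
  out[mask] <- v
  g <- volume_grid(out)
  attr(g, "iterations") <- iter
  attr(g, "final_delta") <- delta
  attr(g, "kind") <- "EC"
  g
}

#' Voxel-wise degree centrality
#'
#' `DC_i = sum_{j != i} r_ij * [r_ij > tau]`: the summed connection
#' strength of each voxel to every other masked voxel, counting only
#' correlations above `tau` (default 0, i.e. negative weights excluded).
#' Computed blockwise so the full correlation matrix is held only in
#' `block_size`-column strips.
#'
#' @inheritParams eigenvector_centrality
#' @param tau correlation threshold; `tau = -1` gives the plain row sum.
#' @param block_size voxels per correlation strip.
#' @return A [volume_grid] of DC values, `NA` outside the mask.
#' @export
degree_centrality <- function(ts, mask, tau = 0, block_size = 512L) {
  Z <- standardize_timeseries(ts, mask)
  N <- ncol(Z); Tn <- nrow(Z)
  dc <- numeric(N)
  for (start in seq(1L, N, by = block_size)) {
    idx <- start:min(start + block_size - 1L, N)
    R <- crossprod(Z[, idx, drop = FALSE], Z) / (Tn - 1)  # |idx| x N
    for (k in seq_along(idx)) R[k, idx[k]] <- 0          # drop self
    R[R <= tau] <- 0
    dc[idx] <- rowSums(R)
  }
  out <- array(NA_real_, dim(ts)[1:3])
  out[mask] <- dc
  g <- volume_grid(out)
  attr(g, "kind") <- "DC"
  g
}

# Masked voxel timeseries as a T x N matrix with zero-mean, unit-variance
# columns. Errors on zero-variance voxels (flagged by index).
standardize_timeseries <- function(ts, mask) {
  d <- dim(ts)
  if (length(d) != 4L) stop("`ts` must be a 4D array (x, y, z, time)")
  if (d[4] < 8L) stop("temporal length must be at least 8 frames")
  mask <- check_mask(mask, d[1:3])
  N <- sum(mask)
  if (N < 2L) stop("need at least 2 masked voxels")
  M <- matrix(ts, nrow = prod(d[1:3]), ncol = d[4])[as.vector(mask), ,
                                                    drop = FALSE]
  mu <- rowMeans(M)
  M <- M - mu
  ss <- sqrt(rowSums(M^2) / (d[4] - 1))
  bad <- which(ss == 0)
  if (length(bad))
    stop("zero-variance timeseries at masked voxel(s): ",
         paste(head(bad, 10L), collapse = ", "))
  t(M / ss)
}

#' Seed-based correlation analysis
#'
#' For each subject, the mean timeseries over the seed mask is correlated
#' with (and regressed on) every masked voxel's timeseries, yielding a
#' standardized regression coefficient map and a Fisher z map; maps are
#' averaged across subjects. Correlations at machine 1 are capped at
#' `atanh(1 - 1e-7)` and flagged.
#'
#' @param subjects list of 4D arrays, one resting-state timeseries per
#'   subject (same grid).
#' @param seed_mask logical array: the seed region (subset of `mask`).
#' @param mask logical array: analysis voxels.
#' @return list with [volume_grid]s `beta` (mean standardized coefficient),
#'   `z` (mean Fisher z), and `n_capped` (count of capped voxels).
#' @export
sbca <- function(subjects, seed_mask, mask) {
  if (!length(subjects)) stop("need at least one subject")
  d <- dim(subjects[[1L]])
  mask <- check_mask(mask, d[1:3])
  seed_mask <- check_mask(seed_mask, d[1:3])
  if (any(seed_mask & !mask)) stop("seed mask must lie within the mask")
  z_cap <- atanh(1 - 1e-7)
  beta_acc <- z_acc <- 0
  n_capped <- 0L
  for (ts in subjects) {
    stopifnot(identical(dim(ts), d))
    Tn <- d[4]
    M <- matrix(ts, nrow = prod(d[1:3]), ncol = Tn)
    seed <- colMeans(M[as.vector(seed_mask), , drop = FALSE])
    if (sd(seed) == 0) stop("seed timeseries has zero variance")
    Z <- standardize_timeseries(ts, mask)
    s <- (seed - mean(seed)) / sd(seed)
    r <- as.vector(crossprod(Z, s)) / (Tn - 1)
    over <- abs(r) >= 1 - 1e-7
    n_capped <- n_capped + sum(over)
    r[over] <- sign(r[over]) * (1 - 1e-7)
    beta_acc <- beta_acc + r       # standardized simple-regression slope = r
    z_acc <- z_acc + atanh(r)
  }
  n <- length(subjects)
  mk <- function(vals) {
    a <- array(NA_real_, d[1:3]); a[mask] <- vals; volume_grid(a)
  }
  list(beta = mk(beta_acc / n), z = mk(z_acc / n), n_capped = n_capped)
}

#' Parcellate a z map into clusters by a mean + k*SD threshold
#'
#' Voxels exceeding the within-mask mean by at least `k_sd` standard
#' deviations form the suprathreshold set, which is split into connected
#' components; labels are ordered by decreasing size (label 0 =
#' background).
#'
#' @param zmap a [volume_grid] (e.g. the mean Fisher z map from [sbca]).
#' @param mask logical analysis mask.
#' @param k_sd threshold in within-mask SD units above the mask mean.
#' @param connectivity 6, 18, or 26 (3D neighborhood).
#' @param min_size drop components smaller than this many voxels.
#' @return integer 3D array of cluster labels; attribute `sizes` holds the
#'   voxel count per label.
#' @export
parcellate_zmap <- function(zmap, mask, k_sd = 2, connectivity = 26L,
                            min_size = 1L) {
  stopifnot(inherits(zmap, "volume_grid"))
  d <- dim(zmap$values)
  mask <- check_mask(mask, d)
  vals <- zmap$values[mask]
  mu <- mean(vals, na.rm = TRUE)
  sdev <- sd(vals, na.rm = TRUE)
  fg <- array(FALSE, d)
  fg[mask] <- !is.na(vals) & vals > mu + k_sd * sdev
  label_clusters(fg, connectivity = connectivity, min_size = min_size)
}

#' Label connected components of a 3D foreground, largest first
#'
#' @param fg logical 3D array of foreground voxels.
#' @param connectivity 6, 18, or 26.
#' @param min_size minimum component size kept.
#' @return integer array of labels (1 = largest component) with attribute
#'   `sizes`.
#' @export
label_clusters <- function(fg, connectivity = 26L, min_size = 1L) {
  stopifnot(is.logical(fg), length(dim(fg)) == 3L)
  raw <- .label_components_cpp(as.vector(fg), dim(fg), as.integer(connectivity))
  out <- array(0L, dim(fg))
  if (!any(raw > 0L)) {
    attr(out, "sizes") <- integer(0)
    return(out)
  }
  sizes <- tabulate(raw)
  keep <- which(sizes >= min_size)
  ord <- keep[order(sizes[keep], decreasing = TRUE)]
  remap <- integer(length(sizes))
  remap[ord] <- seq_along(ord)
  lab <- raw
  lab[raw > 0L] <- remap[raw[raw > 0L]]
  out[] <- lab
  attr(out, "sizes") <- sizes[ord]
  out
}
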