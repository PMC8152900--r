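#' Diffusion tensor estimation and scalar indices
#'
#' The tensor is fit voxel-wise by ordinary least squares on the
#' log-signal model `log(S_i / S0) = -b_i g_i' D g_i` over the six unique
#' tensor elements; eigenvalues are returned sorted descending. Scalar
#' indices follow the standard formulas: mean diffusivity
#' `MD = (l1 + l2 + l3)/3`, radial diffusivity `RD = (l2 + l3)/2`, and
#' fractional anisotropy
#' `FA = sqrt(3/2) * sqrt(sum((l_i - MD)^2)) / sqrt(sum(l_i^2))`.
#'
#' @name diffusion-indices
NULL

#' Validate a DWI acquisition protocol
#'
#' @param bvecs 3 x n matrix (or n x 3) of gradient directions; unit norm
#'   required where `bvals > 0`.
#' @param bvals length-n b-values in s/mm^2; must include at least one 0
#'   and >= 6 non-collinear nonzero directions.
#' @return list with normalized `bvecs` (n x 3) and `bvals`.
#' @export
dwi_protocol <- function(bvecs, bvals) {
  bvecs <- as.matrix(bvecs)
  if (ncol(bvecs) != 3L && nrow(bvecs) == 3L) bvecs <- t(bvecs)
  bvals <- as.numeric(bvals)
  if (nrow(bvecs) != length(bvals))
    stop("bvecs and bvals disagree on the number of volumes")
  if (sum(bvals == 0) < 1L) stop("protocol needs at least one b=0 volume")
  nz <- bvals > 0
  norms <- sqrt(rowSums(bvecs[nz, , drop = FALSE]^2))
  if (any(abs(norms - 1) > 1e-6))
    stop("gradient directions for b>0 volumes must be unit vectors")
  if (sum(nz) < 6L) stop("need at least 6 diffusion-weighted directions")
  X <- tensor_design(bvecs[nz, , drop = FALSE], bvals[nz])
  if (qr(X)$rank < 6L)
    stop("direction set is rank deficient for tensor estimation")
  list(bvecs = bvecs, bvals = bvals)
}

# rows: -b * [gx^2, gy^2, gz^2, 2 gx gy, 2 gx gz, 2 gy gz]
tensor_design <- function(g, b) {
  -b * cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
             2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3])
}

#' Fit the diffusion tensor per voxel
#'
#' @param signals numeric matrix, voxels x volumes (or a vector for one
#'   voxel), of diffusion-weighted signal magnitudes.
#' @param protocol a [dwi_protocol].
#' @return matrix with columns `l1 >= l2 >= l3` (mm^2/s) per voxel and a
#'   logical attribute `flagged` marking voxels with nonpositive signals
#'   (returned as `NA`) or negative eigenvalues.
#' @export
fit_tensor <- function(signals, protocol) {
  if (is.vector(signals)) signals <- matrix(signals, nrow = 1L)
  bvals <- protocol$bvals
  if (ncol(signals) != length(bvals))
    stop("signal columns do not match protocol volumes")
  nz <- bvals > 0
  X <- tensor_design(protocol$bvecs[nz, , drop = FALSE], bvals[nz])
  XtXinvXt <- solve(crossprod(X), t(X))
  nvox <- nrow(signals)
  out <- matrix(NA_real_, nvox, 3,
                dimnames = list(NULL, c("l1", "l2", "l3")))
  flagged <- logical(nvox)
  for (v in seq_len(nvox)) {
    s <- signals[v, ]
    if (any(!is.finite(s)) || any(s <= 0)) { flagged[v] <- TRUE; next }
    s0 <- mean(s[!nz])
    y <- log(s[nz] / s0)
    dvec <- as.vector(XtXinvXt %*% y)
    D <- matrix(c(dvec[1], dvec[4], dvec[5],
                  dvec[4], dvec[2], dvec[6],
                  dvec[5], dvec[6], dvec[3]), 3, 3)
    ev <- sort(eigen(D, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    out[v, ] <- ev
    if (any(ev < 0)) flagged[v] <- TRUE
  }
  attr(out, "flagged") <- flagged
  out
}

check_eigenvalues <- function(e) {
  if (is.vector(e)) e <- matrix(e, nrow = 1L)
  e <- as.matrix(e)
  if (ncol(e) != 3L) stop("expected three eigenvalue columns")
  e
}

#' @rdname diffusion-indices
#' @param e eigenvalue matrix (voxels x 3, sorted descending) as returned
#'   by [fit_tensor], or a length-3 vector.
#' @return numeric vector, one value per voxel. `fa()` returns 0 with a
#'   warning for all-zero tensors.
#' @export
fa <- function(e) {
  e <- check_eigenvalues(e)
  m <- rowMeans(e)
  num <- rowSums((e - m)^2)
  den <- rowSums(e^2)
  out <- sqrt(1.5) * sqrt(num / den)
  zero <- den == 0
  if (any(zero, na.rm = TRUE)) {
    warning("all-zero tensor(s): FA undefined, set to 0")
    out[which(zero)] <- 0
  }
  out
}

#' @rdname diffusion-indices
#' @export
md <- function(e) rowMeans(check_eigenvalues(e))

#' @rdname diffusion-indices
#' @export
rad_diff <- function(e) {
  e <- check_eigenvalues(e)
  (e[, 2] + e[, 3]) / 2
}

#' Forward-simulate DWI signals from a tensor (for recovery checks)
#'
#' @param D 3x3 symmetric positive-definite diffusion tensor (mm^2/s).
#' @param protocol a [dwi_protocol].
#' @param s0 non-diffusion-weighted signal level.
#' @return numeric vector of signals, one per protocol volume.
#' @export
simulate_dwi_signal <- function(D, protocol, s0 = 1000) {
  g <- protocol$bvecs
  b <- protocol$bvals
  adc <- rowSums((g %*% D) * g)
  s0 * exp(-b * adc)
}
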