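#' Volumetric grid containers and NIfTI input/output
#'
#' A `volume_grid` is the package's carrier for 3D scalar maps (diffusion
#' indices, centrality maps, change maps): a numeric 3D array plus voxel
#' dimensions in mm and an optional 4x4 world affine. Voxel indexing is
#' 0-based `(x, y, z)` when reported (e.g. cluster peaks); no reorientation
#' is ever applied. Missing voxels are `NA` and are excluded from all
#' downstream statistics.
#'
#' @param values numeric 3D array of voxel values.
#' @param voxel_size positive length-3 numeric, voxel edge lengths in mm.
#' @param affine optional 4x4 voxel-to-world transform.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(values, voxel_size = c(1, 1, 1), affine = NULL) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("`voxel_size` must be 3 strictly positive lengths (mm)")
  if (!is.null(affine)) {
    affine <- as.matrix(affine)
    if (!all(dim(affine) == c(4L, 4L))) stop("`affine` must be 4x4")
  }
  structure(list(values = values, voxel_size = voxel_size, affine = affine),
            class = "volume_grid")
}

#' @export
dim.volume_grid <- function(x) dim(x$values)

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<volume_grid> %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  r <- range(x$values, na.rm = TRUE)
  cat(sprintf("  values in [%.4g, %.4g], %d missing\n",
              r[1], r[2], sum(is.na(x$values))))
  invisible(x)
}

#' Read a 3D NIfTI volume
#'
#' @param path path to a NIfTI-1 file (`.nii` or `.nii.gz`).
#' @return A [volume_grid].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) stop("malformed NIfTI file: ", path,
                                           " (", conditionMessage(e), ")"))
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img2 <- array(as.numeric(img), dim = d[1:3])
    attr(img2, "pixdim") <- attr(img, "pixdim")
    d <- d[1:3]
    vx <- RNifti::pixdim(img)[1:3]
    return(volume_grid(img2, vx, affine = unclass(RNifti::xform(img))))
  }
  if (length(d) != 3L)
    stop("expected a 3D volume, got ", length(d), " dimensions")
  volume_grid(array(as.numeric(img), dim = d),
              voxel_size = RNifti::pixdim(img)[1:3],
              affine = unclass(RNifti::xform(img)))
}

#' Write a volume to NIfTI
#'
#' The default datatype is `"double"` so that read/write round-trips are
#' lossless; use `"float"` for FSL-style float32 output.
#'
#' @param grid a [volume_grid].
#' @param path output path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI storage type.
#' @return `path`, invisibly.
#' @export
write_volume <- function(grid, path, datatype = "double") {
  stopifnot(inherits(grid, "volume_grid"))
  img <- RNifti::asNifti(grid$values)
  RNifti::pixdim(img) <- grid$voxel_size
  if (!is.null(grid$affine))
    RNifti::qform(img) <- structure(grid$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a {0,1} NIfTI volume as a logical mask
#'
#' @param path path to a NIfTI mask.
#' @return logical 3D array.
#' @export
read_mask <- function(path) {
  g <- read_volume(path)
  m <- g$values != 0
  m[is.na(m)] <- FALSE
  m
}

check_mask <- function(mask, dims) {
  if (!is.logical(mask)) {
    if (is.numeric(mask)) mask <- mask != 0 else
      stop("mask must be logical (or 0/1 numeric)")
  }
  if (!is.array(mask) || !identical(dim(mask), as.integer(dims)))
    stop("mask shape does not match volume shape")
  if (!any(mask)) stop("mask is empty")
  mask
}

#' Voxel-wise percentage change map
#'
#' Computes `100 * (post - pre) / pre` inside the mask. Voxels whose
#' baseline magnitude is at or below `eps` cannot support a percentage
#' change and are set to `NA`; their count is recorded in the
#' `n_degenerate` attribute.
#'
#' @param pre,post [volume_grid]s of the same shape (baseline and
#'   post-intervention maps of one modality).
#' @param mask logical array delimiting the analysis region.
#' @param eps smallest baseline magnitude (modality units) considered
#'   nonzero.
#' @param kind change-map flavor tag.
#' @param source_modality modality tag (e.g. `"EC"`, `"FA"`).
#' @return A [volume_grid] with class `change_map` prepended, `NA` outside
#'   the mask and at degenerate baselines.
#' @export
percentage_change <- function(pre, post, mask = NULL, eps = 1e-6,
                              kind = "percentage_change",
                              source_modality = NA_character_) {
  stopifnot(inherits(pre, "volume_grid"), inherits(post, "volume_grid"))
  if (!identical(dim(pre$values), dim(post$values)))
    stop("pre and post volumes have different shapes")
  d <- dim(pre$values)
  mask <- if (is.null(mask)) array(TRUE, d) else check_mask(mask, d)
  delta <- array(NA_real_, d)
  ok <- mask & !is.na(pre$values) & !is.na(post$values) &
    abs(pre$values) > eps
  n_degenerate <- sum(mask) - sum(ok)
  if (sum(ok) == 0L) stop("all masked voxels have degenerate baselines")
  delta[ok] <- 100 * (post$values[ok] - pre$values[ok]) / pre$values[ok]
  out <- volume_grid(delta, pre$voxel_size, pre$affine)
  class(out) <- c("change_map", class(out))
  out$kind <- kind
  out$source_modality <- source_modality
  attr(out, "n_degenerate") <- n_degenerate
  out
}

#' Least-squares residualization
#'
#' Removes the variance in `y` that is linearly associated with the given
#' covariates (e.g. the baseline score), returning residuals orthogonal to
#' every design column. Used to form residualized change scores before
#' joint testing and mediation.
#'
#' @param y numeric response vector (one value per subject).
#' @param covariates numeric matrix/data.frame of covariates (may be NULL
#'   or zero-column for pure centering).
#' @param add_intercept prepend an intercept column.
#' @return numeric vector of residuals.
#' @export
residualize <- function(y, covariates = NULL, add_intercept = TRUE) {
  y <- as.numeric(y)
  X <- build_design(length(y), covariates, add_intercept)
  if (ncol(X) == 0L) return(y)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  qr.resid(qrX, y)
}

build_design <- function(n, covariates, add_intercept) {
  if (is.null(covariates)) {
    X <- matrix(numeric(0), nrow = n, ncol = 0)
  } else {
    X <- as.matrix(as.data.frame(covariates))
    if (nrow(X) != n) stop("covariate rows do not match length of y")
    storage.mode(X) <- "double"
    if (is.null(colnames(X)) && ncol(X) > 0)
      colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  if (add_intercept) X <- cbind(`(Intercept)` = 1, X)
  X
}

#' Mean map value within a cluster
#'
#' @param map a [volume_grid].
#' @param cluster logical array selecting the cluster voxels.
#' @return scalar mean over cluster voxels, `NA` voxels excluded.
#' @export
extract_cluster_mean <- function(map, cluster) {
  stopifnot(inherits(map, "volume_grid"))
  cluster <- check_mask(cluster, dim(map$values))
  vals <- map$values[cluster]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) stop("all cluster voxels are missing")
  mean(vals)
}
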