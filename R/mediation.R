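#' Assemble a mediation data set
#'
#' @param X binary treatment indicator (0 = control, 1 = intervention).
#' @param M numeric vector or matrix of mediators (e.g. residualized
#'   within-cluster change of a connectivity map); one column per
#'   mediator.
#' @param Y numeric outcome (e.g. residualized behavioral gain).
#' @param covariates optional covariate matrix/data.frame (age, sex).
#' @return list of class `mediation_data`; incomplete cases are dropped
#'   listwise and their count recorded in `n_dropped`.
#' @export
mediation_data <- function(X, M, Y, covariates = NULL) {
  X <- as.numeric(X)
  if (!all(X[!is.na(X)] %in% c(0, 1))) stop("X must be binary 0/1")
  M <- as.matrix(M)
  if (is.null(colnames(M))) colnames(M) <- paste0("M", seq_len(ncol(M)))
  Y <- as.numeric(Y)
  C <- if (is.null(covariates)) NULL else as.matrix(as.data.frame(covariates))
  n <- length(X)
  stopifnot(nrow(M) == n, length(Y) == n, is.null(C) || nrow(C) == n)
  cc <- complete.cases(X, M, Y, if (is.null(C)) rep(TRUE, n) else C)
  structure(list(X = X[cc], M = M[cc, , drop = FALSE], Y = Y[cc],
                 covariates = if (is.null(C)) NULL else C[cc, , drop = FALSE],
                 n = sum(cc), n_dropped = sum(!cc)),
            class = "mediation_data")
}

# point estimates of all mediation paths via two OLS stages; optionally
# case-weighted. Returns a, b, c_prime, ab per mediator.
estimate_paths <- function(X, M, Y, C, w = NULL) {
  k <- ncol(M)
  D1 <- cbind(1, X, C)
  D2 <- cbind(1, X, M, C)
  if (is.null(w)) {
    a <- vapply(seq_len(k), function(j)
      .lm.fit(D1, M[, j])$coefficients[2L], numeric(1))
    cf2 <- .lm.fit(D2, Y)$coefficients
  } else {
    sw <- sqrt(w)
    a <- vapply(seq_len(k), function(j)
      .lm.fit(D1 * sw, M[, j] * sw)$coefficients[2L], numeric(1))
    cf2 <- .lm.fit(D2 * sw, Y * sw)$coefficients
  }
  b <- cf2[3L:(2L + k)]
  c_prime <- cf2[2L]
  list(a = a, b = b, c_prime = c_prime, ab = a * b)
}

#' Mediation path coefficients with heteroscedasticity-consistent SEs
#'
#' Fits the two regression stages of the mediation model
#' `M_j = a_j X + gamma' covariates` and
#' `Y = c' X + sum_j b_j M_j + gamma'' covariates`, with coefficient
#' standard errors from the chosen heteroscedasticity-consistent sandwich
#' estimator.
#'
#' @param data a [mediation_data].
#' @param hc sandwich flavor: `"HC4"` (default), `"HC3"`, or `"HC0"`.
#' @return list with per-mediator `a`, `b`, `ab`, the direct effect
#'   `c_prime`, the total effect `c`, sandwich SEs `se_a`, `se_b`,
#'   `se_c_prime`, and the partially standardized indirect effect
#'   `ab_ps = ab / sd(Y)`.
#' @export
fit_paths <- function(data, hc = c("HC4", "HC3", "HC0")) {
  hc <- match.arg(hc)
  stopifnot(inherits(data, "mediation_data"))
  if (data$n < 10L) stop("need at least 10 complete cases")
  X <- data$X; M <- data$M; Y <- data$Y; C <- data$covariates
  k <- ncol(M)
  d1 <- function(j) {
    df <- data.frame(m = M[, j], X = X)
    if (!is.null(C)) df <- cbind(df, C)
    lm(m ~ ., data = df)
  }
  fits1 <- lapply(seq_len(k), d1)
  df2 <- data.frame(Y = Y, X = X, M)
  if (!is.null(C)) df2 <- cbind(df2, C)
  fit2 <- lm(Y ~ ., data = df2)
  if (any(!is.finite(coef(fit2))))
    stop("outcome design is rank deficient")
  a <- vapply(fits1, function(f) coef(f)[["X"]], numeric(1))
  se_a <- vapply(fits1, function(f)
    sqrt(sandwich::vcovHC(f, type = hc)["X", "X"]), numeric(1))
  V2 <- sandwich::vcovHC(fit2, type = hc)
  mn <- colnames(M)
  b <- coef(fit2)[mn]
  se_b <- sqrt(diag(V2)[mn])
  c_prime <- coef(fit2)[["X"]]
  se_c <- sqrt(V2["X", "X"])
  dft <- data.frame(Y = Y, X = X)
  if (!is.null(C)) dft <- cbind(dft, C)
  c_total <- coef(lm(Y ~ ., data = dft))[["X"]]
  list(a = unname(a), b = unname(b), ab = unname(a * b),
       c_prime = c_prime, c_total = c_total,
       se_a = unname(se_a), se_b = unname(se_b), se_c_prime = se_c,
       ab_ps = unname(a * b) / sd(Y), hc = hc, n = data$n)
}

#' Percentile-bootstrap confidence intervals for the indirect effect
#'
#' Resamples cases with replacement `B` times, recomputes the indirect
#' effect `ab` (and its partially standardized version `ab / sd(Y)`) per
#' draw, and reports empirical 2.5/97.5 percentile bounds. A mediation
#' effect is declared when the CI excludes zero. Resamples in which X is
#' constant are discarded and redrawn (count reported).
#'
#' @param data a [mediation_data].
#' @param B bootstrap draws (>= 1000; the study-scale default is 50000).
#' @param seed integer seed.
#' @param conf confidence level.
#' @return list with point estimates (as [fit_paths]), `ci` and `ci_ps`
#'   (per-mediator percentile bounds), `se_boot`, `n_redrawn`, `B`,
#'   `seed`.
#' @export
percentile_bootstrap <- function(data, B = 50000L, seed = 1L,
                                 conf = 0.95) {
  stopifnot(inherits(data, "mediation_data"), B >= 1000L)
  X <- data$X; M <- data$M; Y <- data$Y; C <- data$covariates
  n <- data$n; k <- ncol(M)
  point <- estimate_paths(X, M, Y, C)
  ab_draws <- matrix(NA_real_, B, k)
  ps_draws <- matrix(NA_real_, B, k)
  n_redrawn <- 0L
  with_seed(derive_seeds(seed, 1L), {
    for (b in seq_len(B)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (sd(X[idx]) > 0) break
        n_redrawn <- n_redrawn + 1L
      }
      est <- estimate_paths(X[idx], M[idx, , drop = FALSE], Y[idx],
                            if (is.null(C)) NULL else C[idx, , drop = FALSE])
      ab_draws[b, ] <- est$ab
      ps_draws[b, ] <- est$ab / sd(Y[idx])
    }
  })
  pr <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  ci <- t(apply(ab_draws, 2, quantile, probs = pr, names = FALSE))
  ci_ps <- t(apply(ps_draws, 2, quantile, probs = pr, names = FALSE))
  colnames(ci) <- colnames(ci_ps) <- c("lower", "upper")
  list(a = point$a, b = point$b, ab = point$ab,
       c_prime = point$c_prime, ab_ps = point$ab / sd(Y),
       ci = ci, ci_ps = ci_ps,
       se_boot = apply(ab_draws, 2, sd),
       excludes_zero = ci[, 1] > 0 | ci[, 2] < 0,
       n_redrawn = n_redrawn, B = B, seed = seed)
}

# Huber-type case weights from robust (MCD) Mahalanobis distances over
# the continuous variables (M, Y, covariates); X is binary and excluded
# from the metric. The cutoff is the chi-square quantile at 1 - kappa, so
# an expected `kappa` fraction of clean multivariate-normal cases is
# downweighted; beyond the cutoff the weight decays as cut/d^2 (the
# squared Huber-type weight used for scatter estimation), which drives
# the influence of gross outliers toward zero.
huber_weights <- function(Mat, kappa) {
  if (kappa <= 0) return(rep(1, nrow(Mat)))
  p <- ncol(Mat)
  # exact subset search is affordable (and deterministic) at study-size n
  nsamp <- if (nrow(Mat) <= 100 && p <= 2) "best" else 5000
  rb <- MASS::cov.rob(Mat, method = "mcd", nsamp = nsamp)
  d2 <- stats::mahalanobis(Mat, rb$center, rb$cov)
  cut <- qchisq(1 - kappa, df = p)
  w <- rep(1, nrow(Mat))
  far <- d2 > cut
  w[far] <- cut / d2[far]
  w
}

#' Huber-type robust mediation with percentile bootstrap
#'
#' Downweights extreme cases via a Huber-type weight on robust
#' (minimum-covariance-determinant) Mahalanobis distances over the joint
#' (M, Y, covariates) sample, with the cutoff chosen so that an expected
#' `kappa` proportion of cases is controlled. Both path regressions are
#' refit by iterated weighted least squares (weights recomputed on the
#' residual scale is not needed: distances are over the joint sample, so
#' a single weighting step is a fixed point and iteration is over the
#' bootstrap only), and the weighted indirect effect is bootstrapped with
#' the percentile method. The study's comparability configuration is
#' covariate-free; covariates are nonetheless supported.
#'
#' @param data a [mediation_data].
#' @param kappa proportion of cases controlled, in `[0, 0.5)`.
#' @param B bootstrap draws.
#' @param seed integer seed.
#' @param conf confidence level.
#' @return as [percentile_bootstrap], plus `kappa` and `weights`.
#' @export
robust_mediation <- function(data, kappa = 0.05, B = 10000L, seed = 1L,
                             conf = 0.95) {
  stopifnot(inherits(data, "mediation_data"), kappa >= 0, kappa < 0.5)
  X <- data$X; M <- data$M; Y <- data$Y; C <- data$covariates
  n <- data$n; k <- ncol(M)
  joint <- cbind(M, Y, C)
  w <- with_seed(derive_seeds(seed, 1L), huber_weights(joint, kappa))
  point <- estimate_paths(X, M, Y, C, w = w)
  ab_draws <- matrix(NA_real_, B, k)
  with_seed(derive_seeds(seed + 1L, 1L), {
    for (b in seq_len(B)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (sd(X[idx]) > 0) break
      }
      wb <- if (kappa > 0)
        tryCatch(huber_weights(joint[idx, , drop = FALSE], kappa),
                 error = function(e) w[idx]) else NULL
      est <- estimate_paths(X[idx], M[idx, , drop = FALSE], Y[idx],
                            if (is.null(C)) NULL else C[idx, , drop = FALSE],
                            w = wb)
      ab_draws[b, ] <- est$ab
    }
  })
  pr <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  ci <- t(apply(ab_draws, 2, quantile, probs = pr, names = FALSE))
  colnames(ci) <- c("lower", "upper")
  list(a = point$a, b = point$b, ab = point$ab, c_prime = point$c_prime,
       ci = ci, se_boot = apply(ab_draws, 2, sd),
       excludes_zero = ci[, 1] > 0 | ci[, 2] < 0,
       kappa = kappa, weights = w, B = B, seed = seed)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Rank correlation with average ranks for ties; the two-sided p-value
#' uses `t = rho sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of
#' freedom.
#'
#' @param x,y numeric vectors (n >= 5).
#' @return list with `rho`, `p`, `n`.
#' @export
spearman_rho <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5L) stop("need at least 5 paired observations")
  if (sd(x) == 0 || sd(y) == 0) stop("constant input")
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  if (abs(rho) >= 1) return(list(rho = rho, p = 0, n = n))
  t <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * pt(-abs(t), n - 2), n = n)
}
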