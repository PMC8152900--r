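#' Cognitive test scoring
#'
#' Scoring rules for the three paper-and-pencil instruments used as
#' behavioral endpoints: the d2-R letter-cancellation test (concentration
#' performance), the ZVT trail-making test (processing speed), and the
#' digit-span test (short-term memory).
#'
#' @name cognitive-scoring
NULL

#' d2-R concentration performance
#'
#' Per test line the record gives the number of processed targets, errors
#' of commission (marked distractors), and errors of overlooking
#' (overlooked targets). Under the default `"literal"` rule the score is
#' the summed processed targets minus the summed commission and
#' overlooking errors. The `"manual"` variant subtracts only commission
#' errors from the processed targets (the conventional CP definition, in
#' which overlooked targets are already absent from the minuend).
#'
#' @param lines data.frame with columns `processed` (processed targets per
#'   line), `commission`, `overlooked`.
#' @param rule `"literal"` (default) or `"manual"`.
#' @return integer concentration-performance score.
#' @export
score_d2r <- function(lines, rule = c("literal", "manual")) {
  rule <- match.arg(rule)
  lines <- as.data.frame(lines)
  need <- c("processed", "commission", "overlooked")
  if (!all(need %in% names(lines)))
    stop("`lines` needs columns: ", paste(need, collapse = ", "))
  with(lines, {
    if (any(processed < 0 | commission < 0 | overlooked < 0))
      stop("counts must be nonnegative")
    if (any(commission + overlooked > processed))
      stop("errors exceed processed symbols on some line(s)")
  })
  p <- sum(lines$processed)
  switch(rule,
         literal = p - sum(lines$commission) - sum(lines$overlooked),
         manual = p - sum(lines$commission))
}

#' ZVT processing-speed score
#'
#' @param form_times completion times in seconds for the four test forms.
#' @return mean completion time (total time divided by the number of
#'   forms).
#' @export
score_zvt <- function(form_times) {
  if (any(!is.finite(form_times)) || any(form_times <= 0))
    stop("form times must be positive")
  sum(form_times) / length(form_times)
}

#' Digit-span score
#'
#' @param trial_outcomes logical vector of per-trial success (forward and
#'   backward trials pooled).
#' @return total number of correctly remembered trials.
#' @export
score_digit_span <- function(trial_outcomes) sum(as.logical(trial_outcomes))

#' Pre/post percentage gain score
#'
#' @param pre,post scalar or vector scores; `pre` must be nonzero.
#' @return `100 * (post - pre) / pre`.
#' @export
percent_gain <- function(pre, post) {
  if (any(pre == 0)) stop("baseline score of 0: percentage gain undefined")
  100 * (post - pre) / pre
}

#' Welch's unpaired t-test with effect size
#'
#' Direct implementation of the unpooled-variance two-sample test:
#' `t = (mean(x) - mean(y)) / sqrt(s1^2/n1 + s2^2/n2)` with
#' Welch-Satterthwaite degrees of freedom, a 95% CI on the mean
#' difference, and Cohen's `d = t * sqrt(1/n1 + 1/n2)` (the design-based
#' conversion that reproduces printed two-group effect sizes).
#'
#' @param x,y numeric vectors for the two groups (n >= 2 each).
#' @param conf confidence level for the CI.
#' @return list with `t`, `df`, `p`, `mean_diff`, `ci`, `d`, `n1`, `n2`.
#' @export
welch_test <- function(x, y, conf = 0.95) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 observations")
  v1 <- var(x); v2 <- var(y)
  se2 <- v1 / n1 + v2 / n2
  md <- mean(x) - mean(y)
  if (se2 == 0) {
    if (md == 0) stop("zero variance in both groups with equal means: ",
                      "t undefined")
    stop("zero variance in both groups")
  }
  t <- md / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(t), df)
  tc <- qt(1 - (1 - conf) / 2, df)
  list(t = t, df = df, p = p, mean_diff = md,
       ci = c(md - tc * sqrt(se2), md + tc * sqrt(se2)),
       d = t * sqrt(1 / n1 + 1 / n2), n1 = n1, n2 = n2)
}

#' Reconstruct a Welch CI from printed summary statistics
#'
#' Given a reported mean difference, t statistic, and fractional degrees
#' of freedom, recovers the standard error `|mean_diff / t|` and the 95%
#' confidence bounds `mean_diff +/- t_{0.975, df} * SE`.
#'
#' @param mean_diff reported mean difference.
#' @param t reported t statistic (nonzero).
#' @param df reported degrees of freedom.
#' @param conf confidence level.
#' @return numeric length-2 vector of CI bounds.
#' @export
welch_ci_from_summary <- function(mean_diff, t, df, conf = 0.95) {
  if (t == 0) stop("t = 0: standard error not recoverable")
  if (df <= 0) stop("df must be positive")
  se <- abs(mean_diff / t)
  tc <- qt(1 - (1 - conf) / 2, df)
  c(mean_diff - tc * se, mean_diff + tc * se)
}

#' Two-group effect size from a Welch statistic
#'
#' @param t Welch t statistic.
#' @param n1,n2 group sizes.
#' @return Cohen's `d = t * sqrt(1/n1 + 1/n2)`.
#' @export
welch_d <- function(t, n1, n2) t * sqrt(1 / n1 + 1 / n2)

#' Critical value of the Studentized maximum modulus (infinite df)
#'
#' Simultaneous two-sided critical value for K independent standardized
#' statistics: the `c` solving `P(max_k |Z_k| <= c) = 1 - alpha`, i.e.
#' `c = qnorm((1 + (1 - alpha)^(1/K)) / 2)`.
#'
#' @param K number of simultaneous comparisons.
#' @param alpha family-wise error level.
#' @return critical value.
#' @export
smm_crit <- function(K, alpha = 0.05) {
  stopifnot(K >= 1, alpha > 0, alpha < 1)
  qnorm((1 + (1 - alpha)^(1 / K)) / 2)
}

#' Johnson-Neyman statistic and p for one design point
#'
#' @param est_control,est_exercise predicted outcomes for the two groups
#'   at a design point.
#' @param se standard error of the difference.
#' @return list with `stat = (est_control - est_exercise)/se` and the
#'   two-sided standard-normal `p`.
#' @export
jn_point <- function(est_control, est_exercise, se) {
  stat <- (est_control - est_exercise) / se
  list(stat = stat, p = 2 * pnorm(-abs(stat)))
}

#' Robust Johnson-Neyman ANCOVA over covariate design points
#'
#' Fits a least-squares regression line of the outcome on the covariate
#' separately in each group (so homogeneity of slopes is not assumed) and
#' compares the groups' predicted outcomes at K design points: the 25th
#' and 75th percentile of the pooled covariate (type-7 percentiles) plus
#' `n_points - 2` evenly spaced values between them. Standard errors of
#' the predicted difference come from a case-resampling bootstrap within
#' each group; simultaneous significance uses the Studentized maximum
#' modulus critical value with infinite degrees of freedom, and per-point
#' two-sided p-values come from the standard normal.
#'
#' @param y outcome vector.
#' @param x covariate vector (e.g. baseline test score).
#' @param group factor/vector with two levels; the first sorted level is
#'   taken as the control/reference group.
#' @param n_points number of design points (>= 2).
#' @param B bootstrap replicates for the SEs.
#' @param alpha simultaneous error level.
#' @param seed integer seed for the bootstrap.
#' @return data.frame with one row per design point: `x`, `est_g1`,
#'   `est_g2`, `se`, `stat`, `p`, `significant`; attributes `crit`,
#'   `groups`.
#' @export
jn_ancova <- function(y, x, group, n_points = 10L, B = 5000L,
                      alpha = 0.05, seed = 1L) {
  group <- as.factor(group)
  if (nlevels(group) != 2L) stop("`group` must have exactly two levels")
  g1 <- levels(group)[1L]; g2 <- levels(group)[2L]
  i1 <- which(group == g1); i2 <- which(group == g2)
  if (length(i1) < 5L || length(i2) < 5L)
    stop("each group needs at least 5 cases")
  if (sd(x[i1]) == 0 || sd(x[i2]) == 0)
    stop("covariate is constant within a group")
  q <- quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  pts <- seq(q[1], q[2], length.out = n_points)
  predict_line <- function(idx, yy = y) {
    cf <- coef(lm(yy[idx] ~ x[idx]))
    cf[1] + cf[2] * pts
  }
  est1 <- predict_line(i1)
  est2 <- predict_line(i2)
  diffs <- matrix(NA_real_, B, n_points)
  seeds <- derive_seeds(seed, 1L)
  with_seed(seeds[1L], {
    for (b in seq_len(B)) {
      b1 <- sample(i1, replace = TRUE)
      b2 <- sample(i2, replace = TRUE)
      while (sd(x[b1]) == 0) b1 <- sample(i1, replace = TRUE)
      while (sd(x[b2]) == 0) b2 <- sample(i2, replace = TRUE)
      diffs[b, ] <- predict_line(b1) - predict_line(b2)
    }
  })
  se <- apply(diffs, 2, sd)
  stat <- (est1 - est2) / se
  crit <- smm_crit(n_points, alpha)
  out <- data.frame(x = pts, est_g1 = est1, est_g2 = est2, se = se,
                    stat = stat, p = 2 * pnorm(-abs(stat)),
                    significant = abs(stat) >= crit)
  attr(out, "crit") <- crit
  attr(out, "groups") <- c(g1, g2)
  out
}
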