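#' Graded exercise test records and fitness indices
#'
#' A GXT record holds the stage workloads (watts, strictly increasing),
#' per-stage heart rate, per-stage blood lactate (possibly missing for
#' some stages), and body mass. From it the package derives the classical
#' cycle-ergometry fitness indices: PWC120/PWC170 (workload at heart rate
#' 120/170 by linear interpolation, per kg body mass), P3 (workload at a
#' fixed 3 mmol/L lactate on a fitted cubic), and the individual anaerobic
#' threshold by the 1.5 mmol method (workload where the fitted curve rises
#' 1.5 mmol/L above its minimum, the "lactate equivalent").
#'
#' @param stages workloads in watts, strictly increasing.
#' @param hr heart rate (beats/min) per stage.
#' @param lactate blood lactate (mmol/L) per stage; `NA` allowed.
#' @param body_mass body mass in kg.
#' @return object of class `gxt_record`.
#' @export
gxt_record <- function(stages, hr, lactate = NULL, body_mass) {
  stages <- as.numeric(stages); hr <- as.numeric(hr)
  if (length(stages) < 2L) stop("need at least 2 GXT stages")
  if (any(diff(stages) <= 0)) stop("stage workloads must strictly increase")
  if (length(hr) != length(stages)) stop("hr length must match stages")
  if (!is.null(lactate) && length(lactate) != length(stages))
    stop("lactate length must match stages")
  if (!is.finite(body_mass) || body_mass <= 0)
    stop("body mass must be positive")
  structure(list(stages = stages, hr = hr,
                 lactate = if (is.null(lactate))
                   rep(NA_real_, length(stages)) else as.numeric(lactate),
                 body_mass = body_mass),
            class = "gxt_record")
}

#' Physical working capacity at a target heart rate
#'
#' Linear interpolation of the workload-heart-rate pairs at `target_hr`,
#' divided by body mass.
#'
#' @param record a [gxt_record].
#' @param target_hr target heart rate in beats/min; must lie within the
#'   observed HR range.
#' @return workload in W/kg.
#' @export
pwc <- function(record, target_hr) {
  stopifnot(inherits(record, "gxt_record"))
  hr <- record$hr; w <- record$stages
  if (target_hr < min(hr) || target_hr > max(hr))
    stop(sprintf("target HR %.0f outside observed range [%.0f, %.0f]",
                 target_hr, min(hr), max(hr)))
  stats::approx(hr, w, xout = target_hr, ties = mean)$y / record$body_mass
}

#' Fit a cubic lactate-workload curve
#'
#' Least-squares third-degree polynomial of lactate on workload; with
#' exactly four points the fit interpolates them.
#'
#' @param record a [gxt_record] with >= 4 non-missing lactate values.
#' @return object of class `lactate_curve`: coefficients (intercept first)
#'   plus the observed workload range.
#' @export
fit_lactate_curve <- function(record) {
  stopifnot(inherits(record, "gxt_record"))
  ok <- !is.na(record$lactate)
  if (sum(ok) < 4L) stop("need at least 4 lactate samples for a cubic fit")
  w <- record$stages[ok]; lac <- record$lactate[ok]
  fit <- lm(lac ~ poly(w, 3, raw = TRUE))
  structure(list(coef = unname(coef(fit)), range = range(w)),
            class = "lactate_curve")
}

#' Evaluate a fitted lactate curve
#' @param curve a `lactate_curve`.
#' @param w workload(s) in watts.
#' @return predicted lactate in mmol/L.
#' @export
predict_lactate <- function(curve, w) {
  stopifnot(inherits(curve, "lactate_curve"))
  cf <- curve$coef
  cf[1] + cf[2] * w + cf[3] * w^2 + cf[4] * w^3
}

# smallest crossing of curve(W) = target inside [lo, hi], by bisection on
# a fine sign-change scan; |dW| < 0.01 W.
smallest_crossing <- function(curve, target, range) {
  lo <- range[1]; hi <- range[2]
  grid <- seq(lo, hi, length.out = 512L)
  f <- predict_lactate(curve, grid) - target
  if (abs(f[1]) < 1e-12) return(grid[1])
  sgn <- sign(f)
  idx <- which(sgn[-1] * sgn[-length(sgn)] <= 0)
  if (!length(idx)) return(NA_real_)
  i <- idx[1]
  a <- grid[i]; b <- grid[i + 1]
  while (b - a > 0.001) {
    mid <- (a + b) / 2
    if (sign(predict_lactate(curve, mid) - target) ==
        sign(predict_lactate(curve, a) - target)) a <- mid else b <- mid
  }
  (a + b) / 2
}

#' Workload at a fixed lactate concentration
#'
#' Finds the smallest workload in the observed range where the fitted
#' cubic reaches `target_lactate` (e.g. 3 mmol/L for P3).
#'
#' @param curve a `lactate_curve`.
#' @param target_lactate target concentration in mmol/L.
#' @param range workload search range (defaults to the observed range).
#' @return workload in watts (resolution < 0.01 W).
#' @export
threshold_workload <- function(curve, target_lactate, range = curve$range) {
  w <- smallest_crossing(curve, target_lactate, range)
  if (is.na(w))
    stop(sprintf("fitted curve never reaches %.2f mmol/L within [%g, %g] W",
                 target_lactate, range[1], range[2]))
  w
}

#' Individual anaerobic threshold by the 1.5 mmol method
#'
#' The anchor is the minimum of the fitted curve over the observed range
#' (the lactate equivalent); the IAT is the workload where the curve rises
#' `delta` (default 1.5) mmol/L above that anchor. If the curve is
#' monotone decreasing over the range, the anchor sits at the right edge.
#'
#' @param curve a `lactate_curve`.
#' @param range workload search range.
#' @param delta rise above the anchor, mmol/L.
#' @return list with `watts` (IAT workload), `lactate` (absolute lactate at
#'   the IAT), and `anchor` (minimum fitted lactate).
#' @export
iat_1p5 <- function(curve, range = curve$range, delta = 1.5) {
  opt <- optimize(function(w) predict_lactate(curve, w),
                  interval = range)
  edges <- predict_lactate(curve, range)
  anchor <- min(opt$objective, edges)
  w_anchor <- if (opt$objective <= min(edges)) opt$minimum else
    range[which.min(edges)]
  target <- anchor + delta
  w <- smallest_crossing(curve, target, c(w_anchor, range[2]))
  if (is.na(w))
    stop("fitted curve never rises ", delta,
         " mmol/L above its minimum within the observed range")
  list(watts = w, lactate = target, anchor = anchor)
}

#' All fitness indices for one GXT record
#'
#' @param record a [gxt_record].
#' @return one-row data.frame: `pwc120`, `pwc170`, `iat`, `p3` (all W/kg;
#'   `NA` where undefined) and `iat_lactate` (mmol/L).
#' @export
fitness_indices <- function(record) {
  safe <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  curve <- tryCatch(fit_lactate_curve(record), error = function(e) NULL)
  iat <- if (is.null(curve)) NULL else
    tryCatch(iat_1p5(curve), error = function(e) NULL)
  data.frame(
    pwc120 = safe(pwc(record, 120)),
    pwc170 = safe(pwc(record, 170)),
    iat = if (is.null(iat)) NA_real_ else iat$watts / record$body_mass,
    iat_lactate = if (is.null(iat)) NA_real_ else iat$lactate,
    p3 = if (is.null(curve)) NA_real_ else
      safe(threshold_workload(curve, 3) / record$body_mass)
  )
}

#' Training lactate normalized to the IAT
#'
#' Per subject, lactate samples are averaged within each training session,
#' session means are averaged, and the result is expressed as a percentage
#' of the subject's absolute IAT lactate. At the cohort level a one-sample
#' t-test against `mu0 = 100` checks that training strained the
#' anaerobic-lactic system, with Cohen's `d = t / sqrt(n)`.
#'
#' @param session_samples for a single subject: list of numeric vectors
#'   (lactate samples per session); for a cohort: list of such lists.
#' @param iat_lactate absolute lactate at the IAT (mmol/L), one per
#'   subject.
#' @param mu0 null percentage for the cohort test.
#' @return for a single subject, the percentage; for a cohort, a list with
#'   `percent` (per subject), `t`, `df`, `p`, `d`, `mean`, `ci95`.
#' @export
training_lactate_index <- function(session_samples, iat_lactate, mu0 = 100) {
  if (any(!is.finite(iat_lactate)) || any(iat_lactate <= 0))
    stop("IAT lactate must be positive")
  one <- function(sessions, iat) {
    stopifnot(length(sessions) >= 1L)
    m <- vapply(sessions, function(s) {
      if (!length(s)) stop("each session needs at least one sample")
      mean(s)
    }, numeric(1))
    100 * mean(m) / iat
  }
  if (is.numeric(session_samples[[1L]])) {
    stopifnot(length(iat_lactate) == 1L)
    return(one(session_samples, iat_lactate))
  }
  stopifnot(length(session_samples) == length(iat_lactate))
  pct <- mapply(one, session_samples, iat_lactate)
  n <- length(pct)
  if (sd(pct) == 0) {
    t <- if (mean(pct) == mu0) 0 else sign(mean(pct) - mu0) * Inf
    return(list(percent = pct, t = t, df = n - 1,
                p = if (t == 0) 1 else 0, d = t / sqrt(n),
                mean = mean(pct), ci95 = rep(mean(pct), 2)))
  }
  tt <- t.test(pct, mu = mu0)
  list(percent = pct,
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, d = unname(tt$statistic) / sqrt(n),
       mean = mean(pct), ci95 = as.numeric(tt$conf.int))
}

#' Cohen's d for a one-sample t-test from its summary statistics
#'
#' @param t one-sample t statistic.
#' @param n sample size.
#' @return `d = t / sqrt(n)`.
#' @export
one_sample_d <- function(t, n) t / sqrt(n)
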