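#' Configuration for a synthetic exercise-intervention cohort
#'
#' Defines the study conditions emulated by the generator: a two-group
#' longitudinal design (exercise n = 32, control n = 16 by default), two
#' sessions, a hub region inside a connected network whose mixing weight
#' increases post-intervention in the exercise group only, behavioral
#' gain scores driven partly by the latent connectivity change (a planted
#' indirect effect), white-matter eigenvalue maps with a group-specific
#' post-intervention decrease of the minor eigenvalues, and graded
#' exercise tests with linear heart-rate and cubic lactate curves.
#'
#' The latent mediator of subject i is `l_i = effect_a * delta_i` for
#' exercise subjects (`delta_i ~ |N(1, 0.5)|`) and 0 for controls. The
#' hub mixing weight changes by `w_scale * l_i`; the behavioral gain is
#' `baseline_term + baseline_slope*(pre - 180) + direct_effect_c*group +
#' effect_b*l_i + noise`. Ground-truth paths are therefore
#' `a = effect_a * E(delta)`, `b = effect_b`, `ab = a * b`.
#'
#' @param n_exercise,n_control group sizes (>= 2 each).
#' @param grid_shape 3D grid dimensions.
#' @param n_frames timeseries length (frames; TR fixed at 1.4 s).
#' @param effect_a connectivity-change effect size (SD units of the
#'   latent delta).
#' @param effect_b slope of behavioral gain on the latent connectivity
#'   change.
#' @param direct_effect_c direct group effect on behavioral gain.
#' @param hub_mask,network_masks,wm_effect_mask logical arrays; defaults
#'   are proportionally placed disjoint blocks.
#' @param noise_sd named list: `ts` (timeseries noise SD), `behavior`
#'   (gain-score noise SD, percent), `diffusion` (multiplicative
#'   eigenvalue noise SD), `hr` (GXT heart-rate noise), `lactate` (GXT
#'   lactate noise).
#' @param w_scale mixing-weight increment per unit latent change.
#' @param w_base baseline network mixing weight.
#' @param baseline_slope dependence of gain on baseline test score.
#' @param wm_effect fractional post decrease of the two minor eigenvalues
#'   per unit delta, exercise group inside `wm_effect_mask`.
#' @param seed root seed; all randomness derives from it.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_exercise = 32L, n_control = 16L,
                          grid_shape = c(16L, 16L, 16L), n_frames = 200L,
                          effect_a = 1.0, effect_b = 0.8,
                          direct_effect_c = 1.0,
                          hub_mask = NULL, network_masks = NULL,
                          wm_effect_mask = NULL,
                          noise_sd = list(), w_scale = 0.4, w_base = 0.6,
                          baseline_slope = -0.05, wm_effect = 0.04,
                          seed = 1L) {
  stopifnot(n_exercise >= 2L, n_control >= 2L, n_frames >= 8L,
            length(grid_shape) == 3L)
  grid_shape <- as.integer(grid_shape)
  ns <- list(ts = 1.0, behavior = 0.3, diffusion = 0.02, hr = 2.0,
             lactate = 0.15)
  ns[names(noise_sd)] <- noise_sd
  if (is.null(hub_mask))
    hub_mask <- block_mask(grid_shape, c(0.30, 0.30, 0.30),
                           c(0.45, 0.45, 0.45))
  if (is.null(network_masks))
    network_masks <- list(block_mask(grid_shape, c(0.60, 0.60, 0.15),
                                     c(0.90, 0.90, 0.45)))
  if (is.null(wm_effect_mask))
    wm_effect_mask <- block_mask(grid_shape, c(0.10, 0.10, 0.60),
                                 c(0.35, 0.35, 0.85))
  for (m in c(list(hub_mask, wm_effect_mask), network_masks))
    if (!identical(dim(m), grid_shape)) stop("mask exceeds grid shape")
  net_all <- Reduce(`|`, network_masks)
  if (any(hub_mask & net_all))
    stop("hub and network masks must be disjoint")
  stopifnot(all(is.finite(c(effect_a, effect_b, direct_effect_c))))
  structure(list(
    n_exercise = as.integer(n_exercise), n_control = as.integer(n_control),
    grid_shape = grid_shape, n_frames = as.integer(n_frames),
    effect_a = effect_a, effect_b = effect_b,
    direct_effect_c = direct_effect_c,
    hub_mask = hub_mask, network_masks = network_masks,
    wm_effect_mask = wm_effect_mask, noise_sd = ns,
    w_scale = w_scale, w_base = w_base, baseline_slope = baseline_slope,
    wm_effect = wm_effect, seed = as.integer(seed)),
    class = "cohort_config")
}

#' Axis-aligned block mask from fractional corners
#' @param dims grid dimensions.
#' @param lo,hi fractional corners in `[0, 1)^3`.
#' @return logical array.
#' @export
block_mask <- function(dims, lo, hi) {
  m <- array(FALSE, dims)
  idx <- lapply(1:3, function(k) {
    a <- max(1L, floor(lo[k] * dims[k]) + 1L)
    b <- min(dims[k], ceiling(hi[k] * dims[k]))
    a:b
  })
  m[idx[[1]], idx[[2]], idx[[3]]] <- TRUE
  m
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Draws subject-level latent variables, covariates, behavioral raw
#' materials, and GXT records; imaging timeseries and eigenvalue maps are
#' generated deterministically on demand by [subject_timeseries] and
#' [subject_eigenvalue_maps] from per-subject sub-seeds, so a cohort
#' object stays small. The whole cohort is a pure function of
#' `config$seed`.
#'
#' @param config a [cohort_config].
#' @return list of class `synthetic_cohort`: `subjects` (data.frame),
#'   `raw` (per-subject cognitive line records and GXT), `truth`
#'   (ground-truth paths, masks, latent values), `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_exercise + config$n_control
  group01 <- c(rep(1L, config$n_exercise), rep(0L, config$n_control))
  seeds <- derive_seeds(config$seed, 6L + 4L * n)
  sub_seeds <- matrix(seeds[-(1:6)], nrow = n)  # ts_pre, ts_post, dwi, gxt

  subjects <- with_seed(seeds[1L], {
    age <- round(runif(n, 18, 35), 1)
    sex <- rbinom(n, 1L, 0.6)  # 1 = female
    delta <- abs(rnorm(n, 1, 0.5))
    latent <- ifelse(group01 == 1L, config$effect_a * delta, 0)
    body_mass <- round(rnorm(n, 67.5, 10), 1)
    body_mass[body_mass < 45] <- 45
    data.frame(id = sprintf("sub%02d", seq_len(n)),
               group = ifelse(group01 == 1L, "exercise", "control"),
               group01 = group01, age = age, sex = sex,
               delta = delta, latent = latent, body_mass = body_mass)
  })

  beh <- with_seed(seeds[2L], {
    d2r_pre <- round(rnorm(n, 180, 25))
    gain <- 10 + config$baseline_slope * (d2r_pre - 180) +
      config$direct_effect_c * group01 +
      config$effect_b * subjects$latent +
      rnorm(n, 0, config$noise_sd$behavior)
    zvt_pre <- round(rnorm(n, 60, 8), 1)
    zvt_gain <- rnorm(n, 0, 3)
    ds_pre <- pmin(28L, pmax(4L, round(rnorm(n, 14, 3))))
    ds_gain <- rnorm(n, 0, 8)
    list(d2r_pre = d2r_pre, gain = gain,
         d2r_post = round(d2r_pre * (1 + gain / 100)),
         zvt_pre = zvt_pre, zvt_post = round(zvt_pre * (1 + zvt_gain / 100), 1),
         ds_pre = ds_pre,
         ds_post = pmin(28L, pmax(0L, round(ds_pre * (1 + ds_gain / 100)))))
  })
  subjects$d2r_pre <- beh$d2r_pre
  subjects$d2r_post <- beh$d2r_post
  subjects$d2r_gain <- percent_gain(beh$d2r_pre, beh$d2r_post)
  subjects$zvt_pre <- beh$zvt_pre
  subjects$zvt_post <- beh$zvt_post
  subjects$ds_pre <- beh$ds_pre
  subjects$ds_post <- beh$ds_post

  raw <- vector("list", n)
  for (i in seq_len(n)) {
    raw[[i]] <- with_seed(seeds[3L] + i, list(
      d2r_lines_pre = d2r_lines(beh$d2r_pre[i]),
      d2r_lines_post = d2r_lines(beh$d2r_post[i]),
      zvt_forms_pre = zvt_forms(beh$zvt_pre[i]),
      zvt_forms_post = zvt_forms(beh$zvt_post[i]),
      ds_trials_pre = rep(c(TRUE, FALSE),
                          c(beh$ds_pre[i], 28L - beh$ds_pre[i])),
      ds_trials_post = rep(c(TRUE, FALSE),
                           c(beh$ds_post[i], 28L - beh$ds_post[i]))))
    raw[[i]]$gxt <- generate_gxt(seed = sub_seeds[i, 4L],
                                 body_mass = subjects$body_mass[i],
                                 noise_hr = config$noise_sd$hr,
                                 noise_lactate = config$noise_sd$lactate)
  }

  m_delta <- 1 * (1 - 2 * pnorm(-2)) + 2 * 0.5 * dnorm(2)  # E|N(1,0.5)|
  truth <- list(
    true_a = config$effect_a * m_delta,
    true_b = config$effect_b,
    true_ab = config$effect_a * m_delta * config$effect_b,
    true_c_prime = config$direct_effect_c,
    hub_mask = config$hub_mask,
    network_mask = Reduce(`|`, config$network_masks),
    wm_effect_mask = config$wm_effect_mask,
    latent = subjects$latent)
  truth$true_ab <- truth$true_a * truth$true_b

  structure(list(subjects = subjects, raw = raw, truth = truth,
                 config = config, sub_seeds = sub_seeds),
            class = "synthetic_cohort")
}

# split a d2-R total score into 14 per-line records with a plausible
# error budget
d2r_lines <- function(cp) {
  n_err <- sample(6:20, 1L)
  processed <- cp + n_err
  lines <- 14L
  p <- as.vector(stats::rmultinom(1, processed, rep(1 / lines, lines)))
  commission <- as.vector(stats::rmultinom(1, sample(0:n_err, 1L),
                                           rep(1 / lines, lines)))
  overlooked_total <- n_err - sum(commission)
  if (overlooked_total < 0) { commission[] <- 0L; overlooked_total <- n_err }
  overlooked <- as.vector(stats::rmultinom(1, overlooked_total,
                                           rep(1 / lines, lines)))
  # per-line consistency: move excess errors to lines with slack, keeping
  # all totals (and hence the CP score) exact
  repeat {
    over <- commission + overlooked - p
    l <- which(over > 0)[1]
    if (is.na(l)) break
    slack <- which(p - commission - overlooked > 0)[1]
    take <- min(over[l], p[slack] - commission[slack] - overlooked[slack])
    t1 <- min(take, overlooked[l])
    overlooked[l] <- overlooked[l] - t1
    overlooked[slack] <- overlooked[slack] + t1
    t2 <- take - t1
    commission[l] <- commission[l] - t2
    commission[slack] <- commission[slack] + t2
  }
  data.frame(processed = p, commission = commission,
             overlooked = overlooked)
}

zvt_forms <- function(mean_time) {
  f <- mean_time + rnorm(4L, 0, 2)
  f <- pmax(f, 10)
  f * (4 * mean_time / sum(f))  # exact mean preserved
}

#' Simulate a graded exercise test record
#'
#' Stage heart rate follows `hr0 + hr_slope * W` plus noise, and the test
#' is terminated after the stage in which HR reaches 170 beats/min.
#' Lactate samples follow a known cubic in workload plus noise; the true
#' generating parameters are attached for recovery checks.
#'
#' @param seed integer seed.
#' @param start,step initial workload and stage increment (watts).
#' @param hr0,hr_slope heart-rate intercept (bpm) and slope (bpm/W).
#' @param lactate_coef length-4 generating cubic coefficients (intercept
#'   first); default `1 + (W/100)^3` shaped with mild subject variation.
#' @param noise_hr,noise_lactate noise SDs (0 gives exact curves).
#' @param body_mass kg.
#' @param max_stages safety cap on stage count.
#' @return a [gxt_record] with attribute `truth` (generating parameters).
#' @export
generate_gxt <- function(seed = 1L, start = 25, step = 25,
                         hr0 = NULL, hr_slope = NULL, lactate_coef = NULL,
                         noise_hr = 2, noise_lactate = 0.15,
                         body_mass = 70, max_stages = 20L) {
  with_seed(seed, {
    if (is.null(hr0)) hr0 <- rnorm(1, 62, 5)
    if (is.null(hr_slope)) hr_slope <- rnorm(1, 0.48, 0.05)
    if (is.null(lactate_coef)) {
      s <- rnorm(1, 100, 8)
      lactate_coef <- c(max(0.5, rnorm(1, 1, 0.1)), 0, 0, 1 / s^3)
    }
    w <- numeric(0); hr <- numeric(0); lac <- numeric(0)
    for (k in seq_len(max_stages)) {
      wk <- start + (k - 1L) * step
      hk <- hr0 + hr_slope * wk + rnorm(1, 0, noise_hr)
      lk <- lactate_coef[1] + lactate_coef[2] * wk +
        lactate_coef[3] * wk^2 + lactate_coef[4] * wk^3 +
        rnorm(1, 0, noise_lactate)
      w <- c(w, wk); hr <- c(hr, hk); lac <- c(lac, max(lk, 0.3))
      if (hk >= 170) break
    }
    rec <- gxt_record(w, hr, lac, body_mass)
    attr(rec, "truth") <- list(hr0 = hr0, hr_slope = hr_slope,
                               lactate_coef = lactate_coef)
    rec
  })
}

#' Per-subject 4D resting-state-like timeseries
#'
#' Deterministic given the cohort: every network/hub voxel carries the
#' session's shared latent signal `g(t)` with mixing weight `w`, plus
#' i.i.d. Gaussian noise; hub weights of exercise subjects are raised
#' post-intervention by `w_scale * latent_i`.
#'
#' @param cohort a [generate_cohort] result.
#' @param i subject index.
#' @param session `"pre"` or `"post"`.
#' @return 4D array (x, y, z, frames).
#' @export
subject_timeseries <- function(cohort, i, session = c("pre", "post")) {
  session <- match.arg(session)
  cfg <- cohort$config
  seed <- cohort$sub_seeds[i, if (session == "pre") 1L else 2L]
  d <- cfg$grid_shape
  nf <- cfg$n_frames
  net <- cohort$truth$network_mask | cfg$hub_mask
  w <- array(0, d)
  w[net] <- cfg$w_base
  if (session == "post" && cohort$subjects$group01[i] == 1L)
    w[cfg$hub_mask] <- cfg$w_base + cfg$w_scale * cohort$subjects$latent[i]
  with_seed(seed, {
    g <- rnorm(nf)
    ts <- array(rnorm(prod(d) * nf, 0, cfg$noise_sd$ts), c(prod(d), nf))
    wi <- which(as.vector(net))
    ts[wi, ] <- ts[wi, ] + outer(as.vector(w)[wi], g)
    array(ts, c(d, nf))
  })
}

#' Per-subject diffusion-tensor eigenvalue maps
#'
#' Baseline eigenvalues (1.5, 0.9, 0.6) x 1e-3 mm^2/s with multiplicative
#' voxel noise; post-intervention, exercise subjects' minor eigenvalues
#' (l2, l3) inside the white-matter effect mask are reduced by
#' `wm_effect * delta_i`, emulating a radial-diffusivity decrease.
#'
#' @inheritParams subject_timeseries
#' @return list of three 3D arrays `l1`, `l2`, `l3` (always
#'   `l1 >= l2 >= l3 > 0`).
#' @export
subject_eigenvalue_maps <- function(cohort, i, session = c("pre", "post")) {
  session <- match.arg(session)
  cfg <- cohort$config
  seed <- cohort$sub_seeds[i, 3L] + (session == "post")
  d <- cfg$grid_shape
  base <- c(1.5e-3, 0.9e-3, 0.6e-3)
  out <- with_seed(seed, lapply(base, function(l0)
    array(l0 * pmax(0.5, rnorm(prod(d), 1, cfg$noise_sd$diffusion)), d)))
  names(out) <- c("l1", "l2", "l3")
  if (session == "post" && cohort$subjects$group01[i] == 1L) {
    f <- 1 - cfg$wm_effect * cohort$subjects$delta[i]
    f <- max(f, 0.5)
    out$l2[cfg$wm_effect_mask] <- out$l2[cfg$wm_effect_mask] * f
    out$l3[cfg$wm_effect_mask] <- out$l3[cfg$wm_effect_mask] * f
  }
  # guarantee ordering under noise
  reord <- pmin(out$l2, out$l1)
  out$l2 <- reord
  out$l3 <- pmin(out$l3, out$l2)
  out
}

#' Percentage-change centrality maps for a whole cohort
#'
#' Computes the chosen centrality measure for every subject and session
#' (timeseries regenerated on demand) and returns the per-subject
#' percentage-change maps plus the baseline maps.
#'
#' @param cohort a [generate_cohort] result.
#' @param measure `"ec"` or `"dc"`.
#' @param mask analysis mask (default: whole grid).
#' @return list with `delta` (n x V percent-change matrix), `baseline`
#'   (n x V), `mask`, `dims`.
#' @export
cohort_delta_centrality <- function(cohort, measure = c("ec", "dc"),
                                    mask = NULL) {
  measure <- match.arg(measure)
  cfg <- cohort$config
  d <- cfg$grid_shape
  if (is.null(mask)) mask <- array(TRUE, d)
  mask <- check_mask(mask, d)
  n <- nrow(cohort$subjects)
  V <- sum(mask)
  delta <- matrix(NA_real_, n, V)
  baseline <- matrix(NA_real_, n, V)
  fun <- if (measure == "ec") eigenvector_centrality else degree_centrality
  for (i in seq_len(n)) {
    pre <- fun(subject_timeseries(cohort, i, "pre"), mask)
    post <- fun(subject_timeseries(cohort, i, "post"), mask)
    baseline[i, ] <- pre$values[mask]
    delta[i, ] <- percentage_change(pre, post, mask)$values[mask]
  }
  list(delta = delta, baseline = baseline, mask = mask, dims = d)
}

#' Residualize change maps on their baseline, voxel-wise
#'
#' @param delta n x V change matrix.
#' @param baseline n x V baseline matrix.
#' @return n x V matrix of voxel-wise residuals of change on baseline
#'   (with intercept).
#' @export
residualize_change <- function(delta, baseline) {
  n <- nrow(delta)
  bc <- scale(baseline, center = TRUE, scale = FALSE)
  dcm <- colMeans(delta)
  slope <- colSums(bc * sweep(delta, 2, dcm)) / colSums(bc^2)
  slope[!is.finite(slope)] <- 0
  delta - matrix(dcm, n, ncol(delta), byrow = TRUE) -
    bc * matrix(slope, n, ncol(delta), byrow = TRUE)
}

#' Null change-map cohorts for type-I error studies
#'
#' Generates per-subject change maps with no group effect (i.i.d.
#' Gaussian voxel noise) plus age/sex covariates — the change-map-level
#' equivalent of a cohort generated with all planted effects at zero,
#' used to measure the family-wise false-positive rate of the inference
#' engine.
#'
#' @param n_exercise,n_control group sizes.
#' @param dims grid dimensions.
#' @param seed integer seed.
#' @return list with `Y` (n x prod(dims) matrix), `groups`, `age`, `sex`,
#'   `mask`, `dims`.
#' @export
generate_null_maps <- function(n_exercise = 32L, n_control = 16L,
                               dims = c(12L, 12L, 12L), seed = 1L) {
  n <- n_exercise + n_control
  with_seed(seed, list(
    Y = matrix(rnorm(n * prod(dims)), n, prod(dims)),
    groups = c(rep(1L, n_exercise), rep(0L, n_control)),
    age = runif(n, 18, 35),
    sex = rbinom(n, 1, 0.6),
    mask = array(TRUE, dims), dims = as.integer(dims)))
}

#' Write a cohort directory
#'
#' Writes `cohort.csv` (one row per subject), per-subject GXT tables
#' under `gxt/`, ground truth as plain-text JSON, and per-subject
#' diffusion index maps (FA/MD/RD, pre and post) as NIfTI under `maps/`.
#'
#' @param cohort a [generate_cohort] result.
#' @param dir output directory (created).
#' @param write_maps write per-subject NIfTI index maps (slower).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, write_maps = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "gxt"), showWarnings = FALSE)
  write.csv(cohort$subjects, file.path(dir, "cohort.csv"),
            row.names = FALSE)
  for (i in seq_len(nrow(cohort$subjects))) {
    g <- cohort$raw[[i]]$gxt
    write.csv(data.frame(stage_w = g$stages, hr_bpm = g$hr,
                         lactate_mmol = g$lactate),
              file.path(dir, "gxt",
                        paste0(cohort$subjects$id[i], ".csv")),
              row.names = FALSE)
  }
  tr <- cohort$truth
  json <- sprintf(
    paste0('{"true_a": %.10g, "true_b": %.10g, "true_ab": %.10g, ',
           '"true_c_prime": %.10g, "n_hub_voxels": %d, ',
           '"latent": [%s]}'),
    tr$true_a, tr$true_b, tr$true_ab, tr$true_c_prime,
    sum(tr$hub_mask), paste(sprintf("%.10g", tr$latent), collapse = ", "))
  writeLines(json, file.path(dir, "ground_truth.json"))
  if (write_maps) {
    dir.create(file.path(dir, "maps"), showWarnings = FALSE)
    for (i in seq_len(nrow(cohort$subjects))) {
      for (ses in c("pre", "post")) {
        ev <- subject_eigenvalue_maps(cohort, i, ses)
        e <- cbind(as.vector(ev$l1), as.vector(ev$l2), as.vector(ev$l3))
        d <- cohort$config$grid_shape
        for (nm in c("fa", "md", "rd")) {
          vals <- switch(nm, fa = fa(e), md = md(e), rd = rad_diff(e))
          write_volume(volume_grid(array(vals, d)),
                       file.path(dir, "maps",
                                 sprintf("%s_%s_%s.nii.gz",
                                         cohort$subjects$id[i], ses, nm)))
        }
      }
    }
  }
  invisible(dir)
}
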