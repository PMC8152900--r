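#' End-to-end NPC mediation screen on a synthetic cohort
#'
#' Runs the full functional-plasticity pipeline on a cohort: per-subject
#' eigenvector-centrality maps for both sessions, percentage-change maps,
#' voxel-wise residualization on baseline, residualized behavioral gain,
#' the synchronized-permutation NPC (Fisher) screen with TFCE and
#' max-statistic FWE correction, and — when a significant cluster
#' emerges — extraction of the within-cluster mean residualized change as
#' the mediator of a percentile-bootstrap mediation analysis.
#'
#' @param cohort a [generate_cohort] result.
#' @param n_flips random sign-flips for the NPC.
#' @param B_boot bootstrap draws for the mediation CI.
#' @param alpha FWE cluster-forming level.
#' @param seed integer seed (permutations and bootstrap).
#' @param params a [tfce_params].
#' @return list with `npc` (the [npc_fisher_screen] result), `dice`
#'   (overlap of the significant voxels with the planted hub mask),
#'   `mediation` (a [percentile_bootstrap] result, or NULL when no
#'   cluster is significant), `delta` (n x V residualized change
#'   matrix), `behavior` (residualized gains).
#' @export
run_cohort_npc <- function(cohort, n_flips = 500L, B_boot = 2000L,
                           alpha = 0.05, seed = 1L,
                           params = tfce_params()) {
  cfg <- cohort$config
  sub <- cohort$subjects
  cd <- cohort_delta_centrality(cohort, "ec")
  Yres <- residualize_change(cd$delta, cd$baseline)
  beh <- residualize(sub$d2r_gain, sub$d2r_pre)
  scheme <- perm_scheme(sub$group01, n_flips = n_flips, seed = seed)
  npc <- npc_fisher_screen(Yres, sub$group01, beh, sub$age, sub$sex,
                           scheme, dims = cd$dims, mask = cd$mask,
                           params = params, contrast = 1, alpha = alpha)
  sig <- array(FALSE, cd$dims)
  sig[cd$mask] <- npc$p_fwe < alpha
  d <- dice(sig, cohort$truth$hub_mask)
  med <- NULL
  if (any(sig)) {
    # all FWE-significant voxels form the extraction mask
    M <- rowMeans(Yres[, sig[cd$mask], drop = FALSE])
    md <- mediation_data(sub$group01, M, beh,
                         covariates = cbind(age = sub$age, sex = sub$sex))
    med <- percentile_bootstrap(md, B = B_boot, seed = seed)
  }
  list(npc = npc, dice = d, mediation = med, delta = Yres,
       behavior = beh)
}

#' Dice overlap of two masks
#' @param a,b logical arrays of identical shape.
#' @return `2 |a & b| / (|a| + |b|)`; 0 when both are empty.
#' @export
dice <- function(a, b) {
  s <- sum(a) + sum(b)
  if (s == 0) return(0)
  2 * sum(a & b) / s
}

#' Family-wise false-positive rate of the TFCE-FWE GLM under the null
#'
#' Generates `n_cohorts` null change-map cohorts (no group effect), runs
#' the permutation GLM with age/sex nuisance covariates on each, and
#' reports the fraction of cohorts in which any voxel reaches
#' `alpha` FWE-corrected — the family-wise false-positive rate, which
#' should be compatible with the nominal level.
#'
#' @param n_cohorts number of replicate null cohorts.
#' @param n_flips sign-flips per cohort.
#' @param dims grid dimensions.
#' @param n_exercise,n_control group sizes.
#' @param alpha nominal FWE level.
#' @param seed integer seed.
#' @param params a [tfce_params].
#' @return list with `rate`, `n_positive`, `n_cohorts`, and the binomial
#'   95% interval `band` around the nominal level.
#' @export
simulate_null_fwe <- function(n_cohorts = 200L, n_flips = 500L,
                              dims = c(12L, 12L, 12L), n_exercise = 32L,
                              n_control = 16L, alpha = 0.05, seed = 1L,
                              params = tfce_params()) {
  seeds <- derive_seeds(seed, 2L * n_cohorts)
  hits <- logical(n_cohorts)
  for (k in seq_len(n_cohorts)) {
    nm <- generate_null_maps(n_exercise, n_control, dims,
                             seed = seeds[k])
    scheme <- perm_scheme(nm$groups, n_flips = n_flips,
                          seed = seeds[n_cohorts + k])
    res <- run_glm_permutation(nm$Y, nm$groups,
                               covariates = cbind(age = nm$age,
                                                  sex = nm$sex),
                               scheme = scheme, dims = nm$dims,
                               mask = nm$mask, params = params)
    hits[k] <- any(res$p_fwe < alpha)
  }
  band <- alpha + c(-1.96, 1.96) * sqrt(alpha * (1 - alpha) / n_cohorts)
  list(rate = mean(hits), n_positive = sum(hits),
       n_cohorts = n_cohorts, band = band)
}

#' Hub recovery and mediation power over replicate planted cohorts
#'
#' For each seed, generates a default planted-effect cohort, runs
#' [run_cohort_npc], and records whether the NPC screen returned a
#' significant cluster overlapping the hub (Dice > `dice_min`) and
#' whether the downstream bootstrap mediation CI excluded zero.
#'
#' @param n_seeds number of replicate cohorts.
#' @param config base [cohort_config]; its seed is replaced per
#'   replicate.
#' @param n_flips,B_boot NPC flips and mediation bootstrap draws.
#' @param dice_min Dice threshold counted as hub recovery.
#' @param seed integer root seed.
#' @return data.frame with one row per replicate (`dice`, `recovered`,
#'   `ci_lower`, `ci_upper`, `excludes_zero`) plus attribute `rates`.
#' @export
simulate_recovery <- function(n_seeds = 25L, config = cohort_config(),
                              n_flips = 500L, B_boot = 2000L,
                              dice_min = 0.3, seed = 1L) {
  seeds <- derive_seeds(seed, 2L * n_seeds)
  rows <- vector("list", n_seeds)
  for (k in seq_len(n_seeds)) {
    cfg <- config
    cfg$seed <- seeds[k]
    cohort <- generate_cohort(cfg)
    res <- run_cohort_npc(cohort, n_flips = n_flips, B_boot = B_boot,
                          seed = seeds[n_seeds + k])
    rows[[k]] <- data.frame(
      seed = cfg$seed, dice = res$dice,
      recovered = res$dice > dice_min,
      ci_lower = if (is.null(res$mediation)) NA_real_ else
        res$mediation$ci[1, "lower"],
      ci_upper = if (is.null(res$mediation)) NA_real_ else
        res$mediation$ci[1, "upper"],
      excludes_zero = !is.null(res$mediation) &&
        res$mediation$excludes_zero[1])
  }
  out <- do.call(rbind, rows)
  attr(out, "rates") <- c(recovery = mean(out$recovered),
                          mediation = mean(out$excludes_zero))
  out
}

#' Simulate a simple mediation data set with known paths
#'
#' `M = a X + e_M`, `Y = b M + c' X + e_Y` with standard-normal errors
#' and a balanced binary treatment: the textbook generating model for
#' path-recovery checks.
#'
#' @param n cases.
#' @param a,b,c_prime true paths.
#' @param seed integer seed.
#' @return a [mediation_data].
#' @export
simulate_mediation <- function(n, a = 0.5, b = 0.6, c_prime = 0.2,
                               seed = 1L) {
  with_seed(seed, {
    X <- rep(c(0, 1), length.out = n)
    M <- a * X + rnorm(n)
    Y <- b * M + c_prime * X + rnorm(n)
    mediation_data(X, M, Y)
  })
}
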