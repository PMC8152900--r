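small_config <- function(seed = 1, ...) {
  cohort_config(n_exercise = 8L, n_control = 6L,
                grid_shape = c(8L, 8L, 8L), n_frames = 40L,
                seed = seed, ...)
}

test_that("cohorts are bitwise reproducible from the root seed", {
  c1 <- generate_cohort(small_config(seed = 5))
  c2 <- generate_cohort(small_config(seed = 5))
  expect_identical(c1$subjects, c2$subjects)
  expect_identical(c1$truth$latent, c2$truth$latent)
  expect_identical(subject_timeseries(c1, 3, "post"),
                   subject_timeseries(c2, 3, "post"))
  expect_identical(c1$raw[[2]]$gxt$lactate, c2$raw[[2]]$gxt$lactate)
  c3 <- generate_cohort(small_config(seed = 6))
  expect_false(identical(c1$subjects$delta, c3$subjects$delta))
})

test_that("masks are disjoint and ground truth is internally consistent", {
  cfg <- cohort_config()
  coh <- generate_cohort(cfg)
  expect_false(any(cfg$hub_mask & coh$truth$network_mask))
  expect_identical(coh$truth$true_ab,
                   coh$truth$true_a * coh$truth$true_b)
  expect_equal(coh$truth$true_b, cfg$effect_b)
  expect_true(all(coh$truth$latent[coh$subjects$group01 == 0] == 0))
  expect_true(all(coh$truth$latent[coh$subjects$group01 == 1] > 0))
  # scoring the generated raw materials reproduces the planted scores
  for (i in c(1, 9)) {
    expect_equal(score_d2r(coh$raw[[i]]$d2r_lines_pre),
                 coh$subjects$d2r_pre[i])
    expect_equal(score_d2r(coh$raw[[i]]$d2r_lines_post),
                 coh$subjects$d2r_post[i])
    expect_equal(score_zvt(coh$raw[[i]]$zvt_forms_pre),
                 coh$subjects$zvt_pre[i], tolerance = 1e-10)
    expect_equal(score_digit_span(coh$raw[[i]]$ds_trials_pre),
                 coh$subjects$ds_pre[i])
  }
})

test_that("eigenvalue maps always satisfy l1 >= l2 >= l3 > 0", {
  coh <- generate_cohort(small_config(seed = 9))
  for (i in c(1, 10)) {
    for (ses in c("pre", "post")) {
      ev <- subject_eigenvalue_maps(coh, i, ses)
      expect_true(all(ev$l1 >= ev$l2))
      expect_true(all(ev$l2 >= ev$l3))
      expect_true(all(ev$l3 > 0))
    }
  }
  # exercise post: radial diffusivity decreases inside the effect mask
  cfg <- small_config(seed = 9)
  i_ex <- which(coh$subjects$group01 == 1)[1]
  pre <- subject_eigenvalue_maps(coh, i_ex, "pre")
  post <- subject_eigenvalue_maps(coh, i_ex, "post")
  rd_pre <- (pre$l2 + pre$l3) / 2
  rd_post <- (post$l2 + post$l3) / 2
  expect_lt(mean(rd_post[cfg$wm_effect_mask]),
            mean(rd_pre[cfg$wm_effect_mask]))
})

test_that("post timeseries differ from pre only in planted hub weights", {
  coh <- generate_cohort(small_config(seed = 12))
  i_ctl <- which(coh$subjects$group01 == 0)[1]
  # controls: same marginal structure, independent noise draws
  pre <- subject_timeseries(coh, i_ctl, "pre")
  post <- subject_timeseries(coh, i_ctl, "post")
  expect_identical(dim(pre), dim(post))
  expect_false(identical(pre, post))
})

test_that("null configuration carries no group signal in gains", {
  cfg <- small_config(seed = 33, effect_a = 0, effect_b = 0,
                      direct_effect_c = 0)
  # aggregate over several null cohorts: group difference is pure noise
  t_stats <- vapply(1:12, function(k) {
    cfgk <- cfg; cfgk$seed <- 100 + k
    coh <- generate_cohort(cfgk)
    welch_test(coh$subjects$d2r_gain[coh$subjects$group01 == 1],
               coh$subjects$d2r_gain[coh$subjects$group01 == 0])$t
  }, numeric(1))
  expect_lt(abs(mean(t_stats)), 2 / sqrt(12) * 2)
  expect_lt(max(abs(t_stats)), 4)
})

test_that("planted hub connectivity change is recovered by the centrality module", {
  cfg <- cohort_config(seed = 11)  # study-scale defaults
  coh <- generate_cohort(cfg)
  cd <- cohort_delta_centrality(coh, "ec")
  hub <- cfg$hub_mask[cd$mask]
  hub_delta <- rowMeans(cd$delta[, hub])
  # latent change vs measured hub Delta-EC across the cohort
  expect_gt(cor(coh$subjects$delta[coh$subjects$group01 == 1],
                hub_delta[coh$subjects$group01 == 1]), 0.5)
  # hub Delta-EC exceeds non-hub Delta-EC in the exercise group
  out_delta <- rowMeans(cd$delta[, !hub])
  ex <- coh$subjects$group01 == 1
  expect_gt(mean(hub_delta[ex]), mean(out_delta[ex]))
})

test_that("GXT generation terminates at HR 170 on the stage grid", {
  rec <- generate_gxt(seed = 2, hr0 = 60, hr_slope = 0.5,
                      noise_hr = 0, noise_lactate = 0)
  # HR = 60 + 0.5 W reaches 170 at W = 220 -> stop at 225 W stage
  expect_equal(max(rec$stages), 225)
  expect_gte(length(rec$stages), 4)
  expect_identical(rec$hr, generate_gxt(seed = 2, hr0 = 60,
                                        hr_slope = 0.5, noise_hr = 0,
                                        noise_lactate = 0)$hr)
})

test_that("cohort directories round-trip through plain-text formats", {
  coh <- generate_cohort(small_config(seed = 3))
  dir <- tempfile("cohort")
  write_cohort(coh, dir)
  tab <- read.csv(file.path(dir, "cohort.csv"))
  expect_equal(nrow(tab), 14)
  expect_true(all(c("id", "group", "age", "sex") %in% names(tab)))
  g1 <- read.csv(file.path(dir, "gxt", paste0(tab$id[1], ".csv")))
  expect_true(all(c("stage_w", "hr_bpm", "lactate_mmol") %in% names(g1)))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  unlink(dir, recursive = TRUE)
})
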