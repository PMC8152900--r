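#!/usr/bin/env Rscript
# Functional-plasticity GLM: per-subject eigenvector-centrality maps for
# both sessions, percentage-change maps, and a sign-flip permutation GLM
# (Aspin-Welch v, age/sex/baseline as nuisance, Freedman-Lane) with TFCE
# and max-statistic FWE correction for the contrast "greater EC increase
# in the exercise group".

library(neuroplast)

coh <- generate_cohort(cohort_config(seed = 1L))
sub <- coh$subjects

cat("computing EC maps for", nrow(sub), "subjects x 2 sessions...\n")
cd <- cohort_delta_centrality(coh, "ec")

# baseline EC enters as a per-subject covariate via its grand mean; the
# voxel-wise baseline adjustment is used in the NPC stage (script 05)
scheme <- perm_scheme(sub$group01, n_flips = 1000L, seed = 4L)
res <- run_glm_permutation(
  cd$delta, sub$group01,
  covariates = cbind(age = sub$age, sex = sub$sex,
                     baseline_ec = rowMeans(cd$baseline)),
  scheme = scheme, dims = cd$dims, mask = cd$mask)

dir.create("results", showWarnings = FALSE)
dims <- cd$dims
to_grid <- function(v) {
  a <- array(NA_real_, dims); a[cd$mask] <- v; volume_grid(a)
}
write_volume(to_grid(res$v), "results/delta_ec_vstat.nii.gz")
write_volume(to_grid(res$tfce), "results/delta_ec_tfce.nii.gz")
write_volume(to_grid(res$p_fwe), "results/delta_ec_pfwe.nii.gz")

sig <- array(FALSE, dims); sig[cd$mask] <- res$p_fwe < 0.05
lab <- label_clusters(sig)
sizes <- attr(lab, "sizes")
cat(sprintf("voxels significant at pFWE < 0.05: %d (in %d cluster(s))\n",
            sum(sig), length(sizes)))
if (length(sizes)) {
  hub_dice <- dice(sig, coh$truth$hub_mask)
  cat(sprintf("largest cluster extent %d; Dice with planted hub = %.2f\n",
              sizes[1], hub_dice))
}
trend <- sum(res$p_fwe < 0.1)
cat(sprintf("trend-level voxels (pFWE < 0.1): %d\n", trend))
cat("wrote results/delta_ec_{vstat,tfce,pfwe}.nii.gz\n")
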