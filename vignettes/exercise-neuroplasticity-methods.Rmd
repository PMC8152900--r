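---
title: "Methods: permutation inference, centrality mapping, and mediation for longitudinal exercise neuroimaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: permutation inference, centrality mapping, and mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroplast)
```

## The scientific problem

A short cardiovascular-exercise intervention can change both cognition
and brain connectivity, and the interesting causal question is whether
the connectivity change *transmits* the cognitive benefit. Answering it
on a longitudinal two-group design (exercise vs. life-as-usual control,
measured before and after the intervention) requires a chain of
statistical machinery:

1. **Voxel-wise connectivity mapping.** Eigenvector centrality (EC) and
   degree centrality (DC) summarize each gray-matter voxel's role in the
   intrinsic functional network without choosing a parcellation.
2. **Change maps.** Percentage-change images between sessions, with
   baseline-associated variance removed by regression (residualized
   change), are the unit of longitudinal analysis.
3. **Permutation GLM.** Group differences in change maps are tested with
   the Aspin--Welch *v* statistic (unpooled variances, because the
   design is unbalanced), sign-flip permutations with Freedman--Lane
   nuisance handling, TFCE enhancement, and max-statistic FWE
   correction.
4. **Joint (NPC) screening.** Mediation requires *both* a
   treatment-to-mediator and a mediator-to-outcome association. The
   nonparametric combination runs the two partial tests under
   synchronized permutations and combines their per-voxel permutation
   p-values with Fisher's $T = -2(\ln p_1 + \ln p_2)$.
5. **Mediation analysis.** The mean residualized change inside the
   surviving cluster enters a regression-based mediation model with
   percentile-bootstrap confidence intervals, HC sandwich standard
   errors, and a Huber-type robust variant.
6. **Fitness and behavior.** Graded-exercise-test (GXT) indices anchor
   the intervention (PWC120/PWC170, P3, IAT), and cognitive endpoints
   are scored, converted to percentage gains, and compared with Welch
   tests and a robust Johnson--Neyman ANCOVA.

Because raw cohort data of such studies are typically not deposited,
the package ships a synthetic-cohort generator with planted ground
truth, so the whole chain is exercisable and testable end to end.

## The synthetic cohort

`generate_cohort()` emulates the design features the analysis relies on,
not the physics of MR acquisition:

* **Design.** Two groups (32 exercise, 16 control by default), two
  sessions, ages uniform 18--35, sex Bernoulli(0.6 female).
* **Functional signal.** Every voxel in a "network" region (including a
  disjoint "hub" block) carries a session-specific shared latent signal
  $g(t)$ with mixing weight $w$ plus unit-variance Gaussian noise:
  $x_v(t) = w_{v,s}\, g(t) + \sigma \varepsilon_{v}(t)$. Post
  intervention, hub weights of exercise subjects rise by
  $w_{\text{scale}} \cdot \ell_i$, where the latent mediator is
  $\ell_i = \texttt{effect\_a} \cdot \delta_i$ with
  $\delta_i \sim |N(1, 0.5)|$. One shared latent (rather than several)
  is the simplest structure that makes EC, DC, and seed-based maps all
  informative.
* **Behavior.** The attention gain (in percent) is
  $10 + \beta_{\text{base}}(\text{pre} - 180) + c'\,\text{group} +
  b\,\ell_i + \varepsilon$. Linking the gain to the *latent* change, not
  the measured one, lets measurement noise attenuate the estimated $b$
  path the way it would in real data. Ground truth satisfies
  $ab = a \cdot b$ exactly with $a = \texttt{effect\_a}\,E(\delta)$.
* **Defaults.** `effect_a = 1.0`, `effect_b = 0.8`, `direct_effect_c =
  1.0`, behavioral noise SD 0.3, network weight scale 0.4, baseline
  weight 0.6. The defaults are deliberately a *strong-effect*
  configuration: the cohort's design contract is that the full pipeline
  recovers the planted hub and detects the planted mediation (bootstrap
  CI excluding zero) in at least 80% of replicate cohorts at study size
  (n = 48), so the behavioral noise was calibrated once, with
  25-replicate precision, to the largest value at which that recovery
  probability is comfortably above the bound (~0.97 at SD 0.3; 0.84 at
  0.6; 0.64 at 1.5). What matters for that power is the *within-group*
  behavioral signal-to-noise - the b-path regression never sees the
  group-mean shift - which is why noise values that still give
  realistic mean effect sizes can leave the chain undetectable.
  Subtler, publication-scale effects are emulated by raising
  `noise_sd$behavior`. The baseline slope (-0.05 %/point) plants the
  negative baseline-to-gain association that motivates the
  Johnson--Neyman adjustment.
* **Diffusion.** Per-voxel tensor eigenvalues start at
  $(1.5, 0.9, 0.6)\times 10^{-3}\,\mathrm{mm^2/s}$ with 2%
  multiplicative noise; post intervention the two minor eigenvalues are
  reduced by `wm_effect` $\times\ \delta_i$ inside a white-matter block
  for exercise subjects only, emulating a radial-diffusivity decrease.
  Maps always satisfy $\lambda_1 \ge \lambda_2 \ge \lambda_3 > 0$.
* **GXT.** Heart rate is linear in workload (terminating after the
  stage reaching 170 bpm on a 25 W / 2 min protocol); lactate follows a
  known cubic. True curve parameters are attached for recovery tests.
* **What is not emulated.** Motion, physiological noise, distortion,
  spatial autocorrelation of noise, registration error. Passing tests
  demonstrate the statistical machinery is correct and calibrated on
  data satisfying its assumptions - not that preprocessing of real MR
  data is handled.

All randomness flows from one root seed through a documented splitting
scheme (`derive_seeds()`), so every fixture is bitwise reproducible and
per-subject volumes can be regenerated on demand instead of stored.

## Eigenvector centrality without the voxel-by-voxel matrix

With $Z$ the $T \times N$ column-standardized timeseries matrix, the
similarity matrix is $A = (R + 1)/2$, $R = Z^\top Z/(T-1)$. The shift
makes $A$ strictly positive, so the dominant eigenvector is unique and
nonnegative (Perron--Frobenius) - negative correlations lower a voxel's
centrality rather than being discarded. Power iteration uses

$$A v = \tfrac{1}{2}\left(\frac{Z^\top (Z v)}{T-1} + \mathbf{1}\,
{\textstyle\sum_i v_i}\right),$$

so the $N \times N$ matrix is never formed; cost is $O(NT)$ per
iteration. Convergence is declared when successive unit vectors differ
by less than `tol` (default 1e-6) in the 2-norm; an error (with the
final delta) is raised otherwise. DC is computed blockwise with a
configurable correlation threshold (default `tau = 0`, i.e. negative
weights excluded; `tau = -1` gives the plain row sum), since toolboxes
differ on this convention.

## TFCE and the permutation engine

TFCE integrates cluster extent and height across all thresholds:
$\mathrm{TFCE}(p) = \sum_h e_h(p)^{E}\, h^{H}\, dh$ with $E = 0.5$,
$H = 2$, 100 steps, 26-connectivity. The implementation inserts voxels
in descending order into a union-find, so all thresholds are processed
in one sweep ($O(\text{steps} \times N)$, compiled). Only positive
values are enhanced; the opposite direction is a separate contrast on
the negated map.

Two numerical choices matter:

* **Step size.** Each map is enhanced with its own
  $dh = \max(\text{map})/100$. An earlier variant reused the observed
  map's $dh$ for all permuted maps; measurement on null cohorts showed
  that this truncates permuted maxima and inflates the family-wise
  error rate (0.17, and 0.085 after extending the ladder), while the
  per-draw $dh$ makes the enhancement functional identical across draws
  - a requirement for exact max-statistic control - and yields 0.059
  over 1000 null cohorts.
* **p-value convention.** Schemes carry `n_flips` random sign vectors
  plus a prepended identity; $p_v = (1 + \#\{\text{flips with } \max
  \ge \mathrm{TFCE}_v\})/(1 + n_{\text{flips}})$, so p-values are never
  zero.

Nuisance covariates (age, sex, baseline) are handled by Freedman--Lane:
residuals of the reduced model are sign-flipped and the nuisance fit
re-added before the statistic is recomputed. Sign-flips are drawn
i.i.d. per subject; the group labels act as the variance groups of the
Aspin--Welch statistic (the Behrens--Fisher-safe choice for the 32/16
design), not as flip constraints. For $n \le 20$ the scheme can
enumerate all $2^n$ flips, and the Monte-Carlo path with distinct draws
reproduces the exhaustive p-values exactly.

## The NPC mediation screen

Both partial tests treat the change map as the regression outcome:
(1) group effect on the map (v statistic, age/sex adjusted) and
(2) slope of the behavioral gain regressor on the map (t statistic,
age/sex/group adjusted). The *same* flip vector is applied to both
submodels at every draw, which preserves the dependence between the
partial tests under the global null. Each partial statistic is
converted to a p-value by its rank within that voxel's own permutation
distribution (a parametric conversion is available as an option), the
Fisher combination is TFCE-enhanced, and FWE correction reuses the
max-statistic machinery. Note that TFCE mixes voxels, so the NPC p-map
coincides with the single-test p-map under a one-partial reduction only
when the mask is a single voxel (where enhancement is a monotone
per-map transform); on extended maps the two pipelines agree in rank
but not identically.

## Mediation analysis

Point estimates come from the two OLS stages
$M = a X + \Gamma\,\text{cov}$ and
$Y = c' X + b M + \Gamma'\,\text{cov}$, with HC4 sandwich standard
errors by default (HC3/HC0 selectable). The percentile bootstrap
resamples rows unstratified (the standard macro behavior; a degenerate
resample with constant $X$ is redrawn and counted), recomputes $ab$ per
draw, and reports empirical 2.5/97.5 bounds plus the partially
standardized effect $ab/\mathrm{SD}(Y)$. The robust variant computes
Huber-type case weights from minimum-covariance-determinant Mahalanobis
distances over the continuous variables $(M, Y, \text{cov})$ - the
binary treatment is excluded from the metric - with the cutoff at the
$\chi^2_{p}$ quantile $1 - \kappa$, so an expected $\kappa$ fraction of
clean cases is controlled. Beyond the cutoff the weight decays as
$c/d^2$ (the squared Huber-type weight used for scatter estimation);
the linear $c/d$ decay left a single gross outlier with enough
influence to shift $ab$ by ~20% on the designed breakdown fixture,
while the squared decay keeps the shift under 10% at the same expected
downweighting fraction. The robust configuration is covariate-free by
default for comparability with the reference procedure, though
covariates are supported.

## Fitness indices

PWC120/PWC170 interpolate the workload-heart-rate pairs linearly. The
lactate-workload curve is a least-squares cubic; P3 is its smallest
crossing of 3 mmol/L within the observed workload range (bisection to
< 0.01 W, restricted to the observed range to avoid spurious cubic
roots). The IAT "1.5 mmol method" is anchored at the minimum of the
fitted curve over the observed range (the lactate equivalent) - the
anchor is configurable because published descriptions differ on whether
it is the curve minimum or a resting sample. Body-weight adjustment
(W/kg) is applied after threshold finding. The training-lactate index
averages within then across sessions, normalizes to the subject's IAT
lactate, and tests the cohort mean against 100% with a one-sample t
(effect size $d = t/\sqrt{n}$).

## Johnson-Neyman ANCOVA

Separate least-squares lines per group (no homogeneity-of-slopes
assumption), compared at the 25th and 75th percentile of the pooled
baseline score (type-7 percentiles, the common default) and 8 evenly
spaced points between. Standard errors come from a case-resampling
bootstrap within each group (B = 5000), preserving the group sizes.
Simultaneous significance uses the Studentized-maximum-modulus critical
value with infinite degrees of freedom,
$c = \Phi^{-1}\!\big((1 + (1-\alpha)^{1/K})/2\big)$ (1.96 at $K = 1$,
2.80 at $K = 10$), and per-point two-sided p-values use the standard
normal - the infinite-df reference reproduces the internal consistency
of published design-point tables ($-1.95 \mapsto p = 0.051$).

## Scoring conventions

The d2-R concentration performance follows the published wording
literally: processed targets minus the sum of commission and
overlooking errors. This differs from the test manual's usual CP
definition (processed targets minus commissions only), which is
available as `rule = "manual"`. The ZVT score is the mean completion
time of the four forms; digit span is the count of correct trials.

## Problem sizes and calibration checks

The package's own calibration studies, rerun by the test suite and the
acceptance script, use sizes chosen to make the Monte-Carlo error small
relative to the property being checked:

* **Type-I error.** 200 replicate null cohorts (change-map level, 48
  subjects, $12^3$ grid) x 500 sign-flips; the family-wise
  false-positive rate must sit in the binomial band around 0.05. Null
  cohorts are generated directly at the change-map level: with all
  planted effects at zero the change maps are exchangeable noise, and
  the property under test belongs to the inference engine, not the
  generator.
* **Power/recovery.** 25 planted-effect cohorts at the default
  configuration ($16^3$ grid, 200 frames); the NPC screen must return a
  significant cluster with Dice > 0.3 against the planted hub, and the
  downstream bootstrap mediation CI (B = 2000) must exclude zero, each
  in at least 80% of seeds.
* **Coverage.** Over 500 simulated mediation cohorts (n = 60, B =
  2000), the 95% percentile CI covers the true $ab$ in 92--97% of
  runs.
* **Parameter recovery.** Mediation paths within ±0.05 at n = 5000;
  tensor eigenvalues to 1e-8 on noise-free signals; GXT thresholds to
  < 0.1 W on noise-free records.

## Known limitations

* The generator's noise is spatially white; TFCE's behavior under
  realistic spatial autocorrelation is not probed by these tests.
* The NPC partial tests use permutation-rank p-values; with few flips
  the discreteness propagates into the Fisher combination.
* The robust mediation variant documents one specific Huber-type
  weighting (MCD distances, $\chi^2$ cutoff, squared decay); published
  robust-mediation implementations differ in metric and iteration
  schedule, so numerical agreement with them is approximate.
* Percentage-change maps require a nonzero baseline; voxels with
  baseline magnitude at or below `eps = 1e-6` (modality units) are
  flagged missing and excluded downstream rather than imputed.
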