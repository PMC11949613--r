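---
title: "Methods: KLS structure-function coupling, its estimation and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: KLS structure-function coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model behind `klscoupling`, the choices made
where the method leaves room, and what the synthetic validation does and
does not demonstrate. Nothing here asserts an empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## The coupling statistic

For one subject and one atlas region, let the region's gray-matter-volume
(GMV) voxel values and ALFF voxel values be two samples. Each is min–max
normalized to $[0,1]$, a Gaussian kernel density estimate is formed for
each with Silverman's rule-of-thumb bandwidth, and both densities are
evaluated on one shared uniform grid of 100 points spanning the pooled
sample range extended by three bandwidths. Cell probabilities (density
times grid spacing) are floored at $\varepsilon = 10^{-12}$ and
renormalized, then compared with the symmetric Kullback–Leibler
divergence
$$
D(P,Q) = \sum_i \left[ P_i \ln\frac{P_i}{Q_i} + Q_i \ln\frac{Q_i}{P_i} \right],
\qquad \mathrm{KLS} = e^{-D} \in (0,1].
$$

Assumptions and consequences:

* **Shape, not scale.** GMV and ALFF live in incommensurable units, so a
  raw-value divergence would be meaningless. Min–max normalization per
  region and modality makes KLS exactly invariant to any positive affine
  rescaling of either map (unit-tested), at the cost of sensitivity to
  single extreme voxels, which set the normalization range.
* **Symmetric divergence.** Similarity of two modalities has no natural
  direction, so the symmetrized sum is the default; the one-directional
  divergence is available via `kls_config(divergence = "asymmetric")`.
* **Shared grid.** Both PDFs must live on an identical support for the
  divergence to be defined; the grid is rebuilt per region from the
  pooled normalized range, using the larger of the two bandwidths for the
  3-bandwidth margin so neither kernel's tails are clipped.
* **Exact KDE.** The kernel sum is evaluated exactly on the grid (no FFT
  binning), because the divergence — the package's core quantity — should
  not inherit a discretization approximation from a convenience
  implementation. Bandwidth selection still uses `stats::bw.nrd0`.
* **Degenerate input.** A zero-variance sample becomes a point mass on
  its nearest grid cell; regions below `min_voxels = 10` yield a missing
  value with a warning rather than an unstable estimate.

Whole-brain coupling — used downstream as a covariate — pools all labeled
voxels by default (`kls_config(whole_brain = "pooled")`); averaging the
regional KLS values is available as `"mean"`. Pooling was chosen because
the covariate is meant to capture a subject's global distributional
correspondence, which an average of region-level similarities does not
represent when regional distributions differ.

## ALFF from BOLD

`compute_alff()` takes each voxel's (preprocessed) time course to the
frequency domain with an FFT, defines power as $|X_k|^2 / T$, and
averages $\sqrt{\text{power}}$ over the DFT bins with frequency in
$[0.01, 0.08)$ Hz. Choices:

* **Normalization of the spectrum.** Any fixed convention rescales every
  subject identically and cancels in the KLS shape comparison; $|X|^2/T$
  is used and tested against a term-by-term $O(T^2)$ DFT oracle.
* **Bin inclusion** is half-open $[f_{low}, f_{high})$: a deterministic,
  documented tie-break at the band edges.
* **Ideal rectangular DFT filter** for `bandpass()` rather than an IIR
  design: it matches common resting-state toolchains and is exactly
  testable (an on-bin passband sinusoid passes unchanged; Parseval
  accounting of retained bins holds to $10^{-8}$). A linear trend is not
  band-limited, so detrending and spectral masking do not commute
  exactly; `bandpass(detrend = FALSE)` exposes the pure mask.
* **Pipeline order** is nuisance regression → detrend/filter → ALFF. For
  confounds confined to stopband frequencies, regression and filtering
  commute (unit-tested); for in-band confounds the order matters and the
  chosen order removes them before spectral averaging.
* **Raw ALFF** is reported; division by the global mean (mALFF) is
  off-by-default (`malff = TRUE`) because a global rescaling is
  irrelevant to the shape-based coupling statistic.
* Head-motion thresholds (translation/rotation > 2.5 mm/°, mean framewise
  displacement > 0.5) are a screening *report* (`screen_motion()`), never
  silent row dropping.

## Group inference

Per region, `ancova_region()` fits
`kls ~ group + age + gender + education + mFD + TIV + whole_brain` by
least squares and tests the 2-df group factor by the full-vs-reduced F
test. With a main-effects-only design this equals the Type III group
test, so no contrast-coding machinery is needed; partial
$\eta^2 = SS_{group}/(SS_{group}+SS_{res})$. Gender is coded
0 = female / 1 = male. The FDR family is all regions of the atlas
(Benjamini–Hochberg, step-up, via `stats::p.adjust`). Post-hoc pairwise
contrasts use covariate-adjusted (estimated marginal) means with
Bonferroni adjustment over the 3 contrasts within a region — chosen as
the conservative, unambiguous reading of an unspecified
"multiple comparisons" procedure. Partial correlations are
residualize-then-correlate with $t$-based p-values on $n-k-2$ df, with
BH-FDR over the (regions × clinical variables) family. All tests are
two-sided. The summary-statistic utilities (`t_from_summary`,
`anova_from_summary`, `chi2_from_counts`) assume pooled variances, which
reproduces published cohort-table statistics better than Welch for the
rows checked in the acceptance suite.

## Diagnostic evaluation

* `roc_analysis()`: empirical rank AUC; DeLong variance and 95% CI; p
  versus AUC = 0.5 by normal approximation (the exact small-sample method
  of point-and-click tools is unspecified, so the standard approximation
  is used and documented). Features are oriented so the positive class
  has the higher mean — reported in `orientation` — because published
  regional AUCs are conventionally all above 0.5; `orient = FALSE`
  disables this for antisymmetry checks. The Youden threshold maximizes
  sensitivity + specificity over the observed scores, ties broken toward
  the smallest threshold.
* `combined_pre()`: maximum-likelihood logistic regression over the
  selected regions' KLS values on all subjects (in-sample, as in the
  published procedure), with the fitted probability as the combined
  score. Quasi-separation — likely with strong regional effects — is
  flagged and refit with a small ridge penalty ($\lambda = 10^{-4}$,
  Newton iterations, slopes only) so probabilities stay finite; the
  ROC of the combined score is then well defined.
* `svm_crossval()`: stratified 80/20 split by seed; stratified 5-fold CV
  *within the training portion* (reported as `cv_accuracy`); final
  linear-kernel SVM (C = 1, the common tool default) refit on the full
  training portion and evaluated on the held-out 20%, whose six metrics
  (accuracy, precision, recall, F1, AUC from decision values, MCC) are
  the headline numbers. The published account reports both a 5-fold CV
  and an 80/20 split without stating their interaction; this package
  uses CV for model assessment inside the training portion and reports
  test-portion metrics, and emits both so the ambiguity is visible. With
  roughly 12 held-out subjects these metrics are high-variance, which is
  why validation is property-based (chance level under permuted labels,
  perfection under separable truth) rather than value-matching.
  Standardization is fit on training data only, to avoid leakage. MCC is
  defined as 0 when a confusion-matrix marginal is zero.

## The phantom generator

`make_phantom_atlas()` partitions a grid (default $30^3$, 20 regions,
one-voxel background shell) by Voronoi tessellation — contiguous,
nonempty, deterministic regions. `simulate_covariates()` draws
three-group cohorts (default sizes 29/33/30) from group-specific normal
models parameterized on published cohort summaries: ages ~27–31 ± 7
years, education ~14–15 ± 2–3 years, mFD higher in the anhedonia group
(0.15 vs 0.10/0.11), SHAPS separated between patient groups (38.1 ± 4.0
vs 26.9 ± 5.0; controls get a low ~20 ± 4 on the same 14–56 Likert
scale), HAMD ≈ 25 for patients and ≈ 2 for controls, and TIV given a
mild group gradient (1470/1445/1430 ± 110 ml) so that covariate
adjustment is genuinely exercised.

`simulate_cohort()` draws each region's GMV voxels from a truncated
normal (region-specific mean 0.3–0.7 and SD 0.08–0.15, subject-level
mean jitter), and **derives ALFF voxel-wise from the same region's GMV
values**: at divergence $\delta = 0$, ALFF is an affine map of GMV plus
small measurement noise (SD 0.1 in standardized units), so the two
regional distributions — and their whole-brain pools — coincide and KLS
sits near 1. Growing $\delta$ injects a skew term
($\frac{\delta}{4}(z^2-1)$) and a bimodal component (mass
$0.15(1-e^{-\delta/2})$ offset by $+1.5$ SD), because after min–max
normalization a pure location or scale shift is invisible by
construction — the knob must distort *shape*. Expected KLS is strictly
decreasing in $\delta$ over $[0,3]$ (verified by seeded sweep), and
subjects get jitter $\delta_s = \max(0, \delta + N(0, 0.05))$. The
default affected pattern $\delta = (0, 0.8, 1.6)$ for HC / patients /
anhedonia patients emulates a deficit present in patients and
accentuated in the anhedonia subgroup, giving group-mean KLS ordering
HC > patients > anhedonia patients.

What the phantom does *not* emulate: anatomy, spatial smoothness and
autocorrelation, partial-volume effects, scanner artifacts, or realistic
effect sizes — its defaults produce strong, clean effects so that
recovery failures indicate implementation defects, not power problems.
Passing tests therefore demonstrate correctness of the machinery, not
expected performance on patient data.

`simulate_bold()` builds sinusoid-plus-noise time courses (default
T = 180 volumes at TR = 2 s, the dimensioning of the emulated
acquisition) with closed-form ALFF for the noiseless part; for
white-noise voxels the expected per-bin $\sqrt{\text{power}}$ is
$\sigma\sqrt{\pi}/2$, which the tests verify on average. The mean of a
sinusoid-plus-noise bin follows a Rice distribution and is not asserted.

## Problem sizes and calibration checks

The test suite (all sizes chosen as a balance of statistical resolution
and quick iteration) uses: a $30^3$/20-region phantom with the full
92-subject cohort for ground-truth recovery (sensitivity ≥ 0.8 at FDR
0.05 with at most one false positive, plus the group-ordering check); a
$20^3$/10-region cohort for the end-to-end pipeline test; 500
seeded replicates of group-independent coupling values with realistic
covariates for ANCOVA null calibration (Kolmogorov–Smirnov uniformity,
empirical size within 3 points of 5%); 100 permuted-label replicates for
the SVM chance-level check; and 200 replicates for BH-FDR
false-discovery-proportion control. Oracle equivalences (hand-summed
divergence, brute-force pair-counting AUC, residualize-then-correlate,
step-up FDR, O(T²) DFT) are exact to $10^{-8}$–$10^{-12}$.

## Known limitations

* KLS depends on the KDE settings; with very small regions the Silverman
  bandwidth is noisy, hence the `min_voxels` guard instead of a value.
* Min–max normalization ties the support to sample extremes; a single
  outlier voxel compresses the rest of the distribution. Robust
  normalization (e.g. quantile-based) is a possible extension.
* The ANCOVA assumes homogeneous covariate slopes across groups
  (no interactions) and normal-ish residuals; with n ≈ 30 per group this
  is conventional but unverified per region.
* In-sample logistic AUCs (the combined predictor) are optimistically
  biased by construction; the null-phantom test quantifies, not removes,
  that bias. Cross-validated alternatives exist only for the SVM path.
* Static coupling only: time-varying (dynamic) structure–function
  coupling is out of scope.
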