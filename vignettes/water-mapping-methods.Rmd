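---
title: "Quantitative brain water content mapping: models, corrections and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative brain water content mapping: models, corrections and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydromap)
```

## The measurement problem

The MR-visible proton density (PD) of brain tissue is, after calibration, a
direct measure of its free water content. A single spoiled gradient-echo
(GRE) magnitude image is, however, far from proportional to PD: it is
modulated by the transmit field (B1+, which perturbs the effective flip
angle), the receive coil sensitivity (B1-), T2\* decay at the acquired echo
time, and T1-dependent saturation at finite TR. `hydromap` simulates a
five-scan 3T protocol that measures each confound, inverts it through the
corresponding correction, and calibrates the result against ventricular
cerebrospinal fluid (CSF), whose water content defines 100 %. The package
targets the study design in which this mapping is used to compare
hemodialysis (HD) patients against matched controls at two timepoints, so it
also carries the group-level statistical layer (Wilcoxon rank-sum tests,
linear mixed models with group x time interaction, correlations with
clinical covariates, Cohen's d, Bonferroni correction).

Because no raw MRI from such a study is publicly deposited, the package is
organized around *digital phantoms*: synthetic brains with exactly known
water content, relaxation times and field inhomogeneities. Every correction
step can therefore be validated against ground truth, and the statistical
layer against generating parameters.

## Forward model

The signal model is the perfectly spoiled GRE steady state,

$$ S = g\, b_{1r}\, W\, \frac{\sin(b_{1t}\alpha)\,\bigl(1 - E_1\bigr)}
   {1 - \cos(b_{1t}\alpha)\, E_1}\; e^{-TE/T_2^*},
   \qquad E_1 = e^{-TR/T_1}, $$

with $W$ the water content, $g$ a global scanner gain, $\alpha$ the nominal
flip angle and $b_{1t}, b_{1r}$ the transmit/receive field multipliers. The
simulated protocol comprises

| scan          | TR (ms) | TE (ms)            | FA (deg)        | purpose |
|---------------|---------|--------------------|-----------------|---------|
| PD scan       | 1800    | 5.2                | 40              | proton density estimate |
| T1 scan       | 500     | 5.2                | 90              | T1 via the scan ratio |
| B1+ series    | (sat.-free EPI) | 11         | 30, 60, 90, 120 | transmit field |
| receive pair  | 500     | 5.2                | 40              | receive field (body vs array coil) |
| multi-echo    | 35      | 2.3 + k·2.27, 8 echoes | 12          | T2\* decay |

The forward model deliberately contains *only* the physics the correction
chain addresses: perfect spoiling is assumed, and off-resonance, motion,
flow, slice-profile and k-space effects are out of scope. The EPI series
used for B1+ mapping has no published TR in the protocol being emulated; it
is simulated saturation-free (TR >> T1), so that the series isolates
$\sin(b_{1t}\alpha)$ — this is an assumption, recorded here. The receive
pair is modeled as a body-coil reference with homogeneous sensitivity and
an array scan differing only in $b_{1r}$. Noise is zero-mean Gaussian on
the magnitude, clipped at zero, with SD equal to `noise_sd` times the mean
brain signal of the scan's first echo and held constant across echoes
(thermal noise does not decay with the signal); a Rician option exists for
completeness, but at the default SNR of 50 the low-SNR magnitude bias is
negligible, and low-SNR bias correction is out of scope.

## Digital phantoms and study conditions

`make_phantom()` builds nested ellipsoids — a white matter (WM) core, a
gray matter (GM) shell, a CSF rim, and two interior ellipsoidal ventricles
— rather than folded anatomy: the geometry is deterministic, every tissue
volume is analytic, and ground truth is exact. Default ground-truth water
content is WM 71.46 %, GM 82.93 %, CSF exactly 100 % (the healthy-control
values the recovery experiments aim at); T1 (900/1400/4000 ms) and T2\*
(50/60/200 ms) are typical 3T values, not study-reported quantities, and
are config-overridable. Probability maps are one-hot by default so that
partial-volume suppression and recovery tests have exact references;
within-class Gaussian texture is available behind a flag.

`make_cohort()` emulates the two-group, two-timepoint design: 10 HD and 10
control subjects by default, HD carrying additive water offsets of +1.43
(WM) and +1.49 (GM) percentage points, between-subject SDs of 1.06 (WM) and
1.00 (GM) points, and a small within-subject timepoint fluctuation (SD 0.2
points) so repeated measures have non-degenerate residuals. Dialysis
vintage (months, mean 44.5) and intradialytic weight change (kg, mean -1.5)
are drawn correlated with the subject's WM water offset (r = 0.69 and
-0.74). These defaults *are* the study conditions; tests and the acceptance
experiment never move them. What the phantom deliberately does not emulate:
cortical folding, atrophy or brain-volume differences, lesions, partial
volume (by default), registration error. Passing tests therefore
demonstrate correctness of the estimators under the modeled physics, not
robustness to anatomical variability.

B1 fields are smooth Gaussian random fields (FWHM 40 mm, amplitude 20 %,
exact unit mean over the brain) — representative of 3T transmit/receive
inhomogeneity scales.

## The correction chain

`map_water()` runs five steps in fixed order; each estimator is validated
against the forward model (self-consistency), which is the strongest
verification available for a chain whose published description names the
steps but not the formulas.

1. **Transmit field.** Per voxel, $S(\alpha) = A \sin(b\alpha)$ is fitted
   over $b \in (0.3, 1.7)$ with $A$ profiled out analytically; a coarse
   grid (step 0.005) plus two parabolic refinements reaches the $10^{-6}$
   scale on noiseless data. The raw map is smoothed at FWHM 4 mm within the
   brain. The kernel is deliberately small relative to the 40 mm field
   scale: masked smoothing is biased near the brain boundary by one-sided
   windows, and wider kernels (12 mm and above) distort the field there by
   several percent, more than the per-voxel fit noise they remove.
2. **Receive field.** The array/body ratio, smoothed at FWHM 3 mm in-mask
   and mean-normalized to 1 over the brain (same kernel reasoning).
3. **T2\*.** Log-linear regression of the echoes, parameterized on
   $\log(S_e/S_1)$, which makes the fit exactly invariant under any global
   gain. Voxels with a non-positive echo are fitted on their positive
   prefix (at least 3 echoes) or flagged; non-negative slopes (no
   measurable decay) are capped at 2000 ms.
4. **T1.** Both the PD and T1 scans share TE, gain and receive field, so
   their ratio depends only on T1 and the effective flip angles. The ratio
   equation is solved per voxel by bisection on [100, 6000] ms to 0.1 ms;
   monotonicity of the ratio in T1 is asserted at runtime, and
   out-of-range ratios are clamped to the bracket end and flagged.
5. **PD correction, residual bias, CSF normalization.** The PD scan is
   divided by the modeled saturation/decay/field factors; residual
   nonuniformity is removed (below); the map is scaled so the mean over the
   1-voxel-eroded ventricular mask is exactly 100.

**Median filtering of the relaxation maps.** The T1 and T2\* maps pass
through one 6-neighbour median filter before the PD correction (default
on). Rationale: relaxation times are piecewise-constant tissue properties,
and the corrections are *nonlinear* in them, so voxel noise is rectified
into a systematic offset — most visibly in the ventricular reference,
where the T1-scan signal is weakest. The median is edge-preserving (across
a locally planar interface at most three of the seven values come from the
far side) and commutes with the monotone ratio-to-T1 inversion, so it is
essentially unbiased within tissue. At SNR 50 this reduces the tissue-mean
bias from about -0.5 to below -0.15 percentage points while leaving
noiseless recovery untouched.

**Residual bias removal.** A brain-sized smoothing kernel cannot by itself
separate smooth bias from large-scale anatomy (tissue classes occupy
coherent regions, so the log map has structure at the brain scale). The
estimator therefore first removes the piecewise-constant intensity levels —
a deterministic 1-D k-means (3 levels, quantile starts) on the log
intensities — and smooths only the residual (FWHM 60 mm), alternating
level fit and bias fit three times so that fields larger than half the
inter-level gap are still resolved. On a bias-free piecewise-constant map
the step is an exact identity; a 10 %-amplitude smooth multiplicative
field is suppressed to below 1 % mean residual.

**Flagged voxels** from any step are pooled into an exclusion mask and
excluded from all downstream statistics; nothing is imputed.

### Numerical contracts

The chain preserves two exact invariants that the tests assert bitwise:
the mean of the water map over the eroded ventricular mask is exactly 100,
and the map is invariant under a global scanner gain applied to all scans
(for power-of-two gains, bit-for-bit; this drove the $\log(S_e/S_1)$ and
$\log(\mathrm{map}/\overline{\mathrm{map}})$ parameterizations, since
rounding commutes with scaling by powers of two).

## Classification and ROI statistics

Partial volume is suppressed by the strict probability-one rule: any voxel
whose GM, WM and CSF probabilities are all below one is discarded. On the
retained voxels (CSF excluded — it is the normalization reference), a
2-component full-covariance Gaussian mixture over the bivariate
(water, T1) values assigns WM and GM by model-based discrimination;
components are relabeled by ascending mean water so class 1 is always WM.
The mixture is fitted per subject (group histogram curves are averages of
subject fits, not pooled fits). The EM engine is `mclust`, initialized by
model-based hierarchical clustering on a seeded 1000-point subsample and
fitted on a seeded subsample of at most 20 000 voxels — the Gaussian
parameters are estimated far below the reporting precision at that size,
the full voxel set is then classified under the fitted model, and the
hierarchical initialization cost grows quadratically beyond it.

ROI analysis mirrors probabilistic-atlas practice: a region mask keeps
voxels with probability at or above 0.75 (inclusive, so a 0.75 voxel is in
and 0.74 is out), is intersected with the subject's WM and GM masks, and a
per-tissue row is emitted only when that tissue exceeds 7 % of the ROI
voxels. Real atlases are not shipped; `make_synthetic_atlas()` provides
geometric stand-ins (lobe-like octants, a callosal slab, a periventricular
region) with the same file contract (probability NIfTI per region + TSV
index), so real atlas directories drop in unchanged.

## Statistical layer

* `wilcoxon_ranksum()`: exact enumeration for combined n <= 12 without
  ties, otherwise the tie-corrected normal approximation; two-sided.
* `mixed_model()`: `outcome ~ group * time + covariates + (1 | subject)`
  by REML (lme4), Satterthwaite p-values (lmerTest), missing visits simply
  omitted; singular fits are flagged, never silently dropped; a residual
  normality diagnostic is attached. REML is a choice — the emulated
  analysis does not state ML vs REML.
* `cohens_d()`: pooled SD with n-1 weights, no small-sample correction;
  bands 0.3 / 0.5 / 0.9 with boundaries inclusive upward.
* `summary_ttest()` / `fisher_exact()`: the demographic-table tests,
  computable from printed summaries; the exact test is used for the
  categorical rows because the printed counts are small.
* `bonferroni()`: `min(1, p * m)` with the comparison count `m` exposed —
  the emulated analysis does not state its m.

Calibration is tested by simulation: the interaction-test type-I error is
checked at 0.05 +/- 0.02 over 200 seeded null datasets (200 rather than
1000 keeps the suite inside a sensible runtime; the binomial SE at 200 is
0.015, which the +/- 0.02 band accommodates).

## Problem sizes and reproducibility

Recovery experiments run on 64^3 phantoms with 1 mm voxels (the
acceptance-scale experiment: 10 control subjects, SNR 50, about half a
minute per cohort on one CPU); unit tests use 48^3 and 40^3 phantoms.
A master seed drives every stochastic stage through a fixed affine hash
(`spawn_seed`), with per-subject and per-scan substreams, so adding a
subject never perturbs another subject's noise, and identical
configurations yield byte-identical summaries.

## Known limitations

* The phantom's concentric geometry makes large-scale anatomy unusually
  coherent; the level-removal step of the bias corrector was designed with
  this in mind and also applies to real anatomy, but its 3-level model
  assumes a brain-masked, three-tissue image.
* The B1- estimator assumes a body-coil reference with homogeneous
  sensitivity; scanner implementations differ, and the published protocol
  does not describe the exact two-scan estimator.
* The chain assumes the spoiled-GRE steady state exactly; stimulated-echo,
  slice-profile and off-resonance deviations present in real data are not
  modeled, so real-data accuracy will be poorer than phantom recovery.
* The ventricular reference mask comes from phantom ground truth (eroded
  by one voxel); on real data it would be drawn manually or from an atlas.
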