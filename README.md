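# hydromap

Quantitative brain water content mapping at 3T, implemented end to end on
digital phantoms.

## The problem

The MR-visible proton density of brain tissue measures its free water
content — a clinically meaningful quantity: chronic hemodialysis, hepatic
encephalopathy and other conditions shift cerebral water homeostasis by a
percentage point or two, mostly in white matter. A raw spoiled
gradient-echo (GRE) image is far from proportional to proton density,
though: it is confounded by the transmit field (B1+), the receive coil
sensitivity (B1-), T2\* decay and T1 saturation. The established
water-mapping approach acquires a small protocol of auxiliary scans, undoes
each confound, and calibrates the corrected image against ventricular
cerebrospinal fluid (CSF), whose water content defines 100 %:

```
S = g · b1r · W · sin(b1t·α) (1 − E1) / (1 − cos(b1t·α) E1) · exp(−TE/T2*),   E1 = exp(−TR/T1)
```

`hydromap` provides, in one tested R package:

* **digital phantoms** with exactly known water content (WM 71.46 %,
  GM 82.93 %, CSF 100 % of pure water by default), relaxation times and
  smooth B1 fields, plus a two-group (hemodialysis vs control),
  two-timepoint cohort generator with clinical covariates;
* a **forward simulator** of the five-scan protocol (PD scan TR 1800 /
  TE 5.2 / FA 40°; T1 scan TR 500 / FA 90°; a four-flip-angle B1+ series;
  a low-resolution body/array receive pair; an 8-echo T2\* scan);
* the **five-step correction chain** — B1+/B1- compensation, T2\* decay
  compensation, T1-saturation correction, residual bias removal, CSF
  normalization — turning an acquisition into a voxelwise water map in
  percent of pure water;
* **bivariate (water, T1) Gaussian-mixture tissue classification** with
  strict partial-volume suppression, probabilistic-atlas **ROI
  statistics** (75 % probability threshold, 7 % mixed-tissue rule), and
  the **group-level statistical layer** (Wilcoxon rank-sum, linear mixed
  models with group × time interaction, Pearson/Spearman correlations,
  Cohen's d, Bonferroni).

## Worked example

Simulate one control subject at SNR 50, run the correction chain, and
classify:

```r
library(hydromap)

phantom <- make_phantom(c(64, 64, 64))          # WM 71.46, GM 82.93, CSF 100
fields  <- make_fields(c(64, 64, 64), amplitude = 0.2, smoothness_mm = 40,
                       seed = 7, mask = phantom$brain_mask)
acq   <- simulate_protocol(phantom, fields, default_protocol(noise_sd = 0.02),
                           seed = 3)
chain <- map_water(acq, phantom$ventricle_mask)
chain
#> water_chain: steps [ b1_transmit, t2star, t1_saturation, residual_bias, csf_normalization ]
#>   brain voxels: 93656  CSF reference voxels: 976
#>   flagged: b1t=0 b1r=0 t2star=0 t1=0 pd=0 bias=0

mean(chain$water_map[chain$csf_mask])           # exactly 100 by construction
#> [1] 100

cls <- global_tissue_water(chain$water_map, chain$t1_hat,
                           phantom$prob_maps, seed = 4,
                           exclude_mask = chain$exclude_mask)
as.data.frame(cls)[, c("tissue", "mean_water", "sd_water", "mean_t1")]
#>   tissue mean_water sd_water   mean_t1
#> 1     WM   71.54733 1.613933  903.6202
#> 2     GM   83.04849 1.691570 1402.8707
```

The recovered class means sit within ~0.2 percentage points of the phantom
ground truth; the residual spread (~1.5 points) is the SNR-50 voxel noise
propagated through the corrections. A full study — cohort, ROI tables,
mixed models, correlations — runs from one seeded config:

```r
res <- run_full_study(default_run_config(seed = 1))
head(res$effects)      # group / time / interaction rows per ROI × tissue
```

A thin command-line front end over the same functions lives at
`inst/cli/hydromap.R` (subcommands `run`, `simulate-phantom`,
`simulate-acq`, `map-water`, `segment`, `roi-stats`, `group-stats`).

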