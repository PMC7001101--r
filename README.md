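# cervitex

Texture radiomics of cervical tumours on endovaginal MRI: masked
grey-level co-occurrence matrix (GLCM) feature extraction from T2-weighted
volumes and apparent diffusion coefficient (ADC) maps, feature
de-correlation, volume-threshold group comparison, and recurrence
prediction with internally validated logistic models.

## Who this is for

Imaging scientists analysing small cervical tumours around the
fertility-sparing surgery (trachelectomy) eligibility threshold — the
volume of a 2 cm diameter sphere,
(4/3)·π·(1 cm)³ = **4.19 cm³** — who want a tested, reproducible
implementation of the full analysis chain rather than a one-off script.
Because studies of this kind rarely deposit imaging data, the package
ships a synthetic phantom and cohort generator with the statistical
structure the analysis assumes, so every stage can be exercised, tested
and benchmarked without any download.

## What it computes

* **Texture**: intensities inside a volume-of-interest (VOI) are quantized
  to `Ng` equal-width levels over the in-mask range; the symmetric GLCM
  `p(i, j)` is accumulated per displacement (4 in-plane unit directions by
  default, pooled over slices) and summarized by the second-order
  statistics Dissimilarity, Contrast, Energy = Σp², Entropy = −Σp ln p,
  ClusterProminence, ClusterShade, InverseVariance, Correlation,
  Autocorrelation and IMC2. VOIs under 100 voxels are ineligible and
  itemized, never silently dropped.
* **ADC maps**: per-voxel mono-exponential fit, ADC = −slope of ln S on b
  by ordinary least squares over all b-values (0–800 s/mm²), with
  non-positive signals excluded voxel-wise and counted.
* **De-correlation**: complete-linkage clustering on d = 1 − |Spearman r|
  cut at k = 10; per cluster the feature with the greatest dynamic range
  survives; residual pairs with |r| > 0.9 are pruned greedily.
* **Group comparison**: Mann-Whitney U (exact when nA+nB ≤ 12 without
  ties) between tumours above and below 4.19 cm³, Bonferroni-adjusted per
  modality.
* **Recurrence models**: stepwise-AIC logistic models per feature category
  (ADC-radiomic, T2W-radiomic, clinico-pathological) in the low-volume
  surgical group; combined models tested against the clinical model by
  likelihood-ratio χ²; ROC with DeLong CIs and Youden thresholds; and
  bootstrap optimism correction (B = 1000) through Somers' D, with
  corrected AUC = (1 + D_apparent − mean optimism)/2.

## Worked example

```r
library(cervitex)

# a 2.5 cm^3 textured phantom tumour on an anisotropic T2-W grid
params  <- texture_class_params(mean_intensity = 100, sd_intensity = 20,
                                correlation_length_mm = c(0.5, 0.5, 1))
phantom <- generate_textured_voi(params, target_volume_cm3 = 2.5,
                                 spacing_mm = c(0.35, 0.35, 2), seed = 7)
extract_voi_features(phantom$volume, phantom$mask)
#> <voi_features> T2W  10231 voxels (2.51 cm^3)  Ng=32
#>                    Dissimilarity                         Contrast
#>                           1.9671                           8.4048
#>                           Energy                          Entropy
#>                           0.0327                           3.7976
#>                ClusterProminence                     ClusterShade
#>                      103516.3070                        -344.7779
#>                  InverseVariance                      Correlation
#>                           0.2699                           0.9232
#>                  Autocorrelation InformationalMeasureCorrelation2
#>                         249.5405                           0.9837
```

The feature vector is the mean over the four in-plane directions; 10231
voxels × 0.245 mm³ gives the printed 2.51 cm³, within rasterization error
of the 2.5 cm³ target.

```r
# a full synthetic cohort: 125 patients, ~46 high-volume
spec <- cohort_generator_spec(seed = 42)
gen  <- generate_cohort(spec)

cmp <- compare_volume_groups(gen$features, gen$cohort)
head(cmp[order(cmp$p_adj),
         c("feature", "modality", "median_low", "median_high", "p_adj")], 4)
#>              feature modality median_low median_high    p_adj
#> 17   InverseVariance      T2W      0.381       0.234 3.11e-11
#> 7    InverseVariance      ADC      0.414       0.296 5.90e-10
#> 15 ClusterProminence      T2W     28.636       8.515 1.04e-09
#> 5  ClusterProminence      ADC     32.906      10.676 4.45e-09
```

Low- and high-volume tumours differ strongly in texture (the generator
plants the per-arm feature distributions), and the Bonferroni-adjusted
p-values land in the same range as a real cohort of this size would show.

```r
sc <- run_scenario(gen$cohort, gen$features, scenario = "all",
                   B = 1000, seed = 17)
sc
#> <scenario_result> scenario 'all', n = 76 (B = 1000)
#>                                model   auc corrected_auc  aic p_value
#>                         ADC-Radiomic 0.764         0.738 72.7      NA
#>                         T2W-Radiomic 0.635         0.626 78.2      NA
#>                 Clinico-pathological 0.752         0.703 74.4      NA
#>  ADC-Radiomic + Clinico-pathological 0.843         0.778 68.3 0.00639
#>  T2W-Radiomic + Clinico-pathological 0.761         0.699 74.6 0.17589
```

Recurrence is modelled in the 76 low-volume surgically-treated patients
with follow-up. Adding the stepwise-selected ADC texture terms to the
clinico-pathological model lowers AIC (74.4 → 68.3) and the nested-model
χ² rejects (p = 0.006); the T2W combination does not. `corrected_auc` is
the bootstrap optimism-corrected discrimination — note how much of the
apparent combined AUC survives correction.

The whole chain (synthesize → extract/sample → select → compare → model →
validate), with per-stage logs, exclusion accounting and an echoed
configuration, runs from one call:

```r
cfg <- default_config()
run_pipeline(cfg, output_dir = "run1")   # writes CSV/JSON reports + log
```

or from the shell via `inst/cli/cervitex.R run --config config.yaml --out run1`.

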