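---
title: "Texture radiomics of cervical tumours: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture radiomics of cervical tumours: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cervitex)
```

## The analysis this package implements

Cervical tumours at or below the volume of a 2 cm diameter sphere —
$\tfrac{4}{3}\pi(1\,\mathrm{cm})^3 = 4.19\ \mathrm{cm^3}$ — are candidates
for fertility-sparing surgery (trachelectomy), and identifying which of
these low-volume tumours will recur is the clinically interesting problem.
The pipeline quantifies tumour texture on high-SNR endovaginal MRI with
second-order (grey-level co-occurrence) statistics on two modalities — the
T2-weighted volume and the apparent diffusion coefficient (ADC) map — then:

1. de-correlates the texture features by hierarchical clustering and keeps
   one representative per cluster;
2. compares features between high- and low-volume tumours with Mann-Whitney
   tests under Bonferroni control;
3. models recurrence in the low-volume surgical group with stepwise
   logistic regression per feature category (ADC-radiomic, T2W-radiomic,
   clinico-pathological), compares combined against clinical-only models by
   likelihood-ratio chi-square and AIC, and corrects apparent
   discrimination for over-fitting by bootstrap optimism estimated through
   Somers' D.

No imaging cohort ships with the package. A synthetic generator produces
phantoms and cohorts with the statistical structure the analysis assumes,
which is what the test-suite and the acceptance script run on.

## Texture model

For a masked volume, intensities inside the VOI are quantized to
$N_g$ equal-width bins over the in-mask min–max range (in-mask value $v$
maps to $\lfloor (v-\min)/(\max-\min)\,N_g\rfloor + 1$, the maximum to
$N_g$). Because the bins are set per VOI, any increasing affine intensity
transform leaves the levels — and hence every feature — unchanged.

The GLCM for displacement $d$ counts ordered in-mask voxel pairs $(a, a+d)$,
symmetrized by also counting the reverse pair, and normalizes to joint
probabilities $p(i,j)$. Features are the classical second-order statistics
(Contrast, Dissimilarity, Energy $=\sum p^2$, Entropy $=-\sum p\ln p$,
InverseVariance, Correlation, Autocorrelation, ClusterShade,
ClusterProminence, and the second informational measure of correlation
IMC2 $=\sqrt{1-e^{-2(H_{XY2}-H_{XY})}}$).

Conventions the literature leaves open, fixed here and reported in output
metadata:

* **$N_g = 32$** equal-width bins by default (configurable). A fixed bin
  count keeps matrices populated at the smallest eligible VOIs
  (about 100 voxels) while retaining texture contrast.
* **Offsets**: the 4 unique in-plane unit directions pooled over all
  slices. The acquisitions this emulates reconstruct ~0.35–0.45 mm
  in-plane voxels on 2 mm slices, so a through-plane step is a ~6× larger
  physical distance; mixing it with in-plane steps would average texture at
  two different scales. A 13-direction full-3D mode exists for isotropic
  data.
* **Aggregation**: features are computed per direction and averaged
  (rotational averaging); pooling counts into one merged matrix first is
  available as an option.
* **Energy** is the angular second moment $\sum p^2$ (bounded by 1, equal
  to 1 only for a single-cell matrix), not its square root.
* **Natural logarithm** in all entropy-type quantities.
* **InverseVariance** sums over $i \neq j$ only (the diagonal term is
  undefined).
* A constant VOI has $\sigma_x\sigma_y = 0$; Correlation is then reported
  as `NA` rather than a substituted value.

VOIs under 100 voxels (configurable) are ineligible, mirroring the
eligibility rule of the study design this emulates; extraction returns an
explicit ineligibility record that the pipeline itemizes, never a silent
drop. Note the eligibility pair ">100 voxels / >0.07 cm^3" quoted in that
design is not self-consistent for any single voxel size, so voxel-count and
volume thresholds are exposed independently.

## ADC fitting

Per voxel, ADC is minus the ordinary least-squares slope of
$\ln S$ on $b$ across all acquired b-values (0, 100, 300, 500, 800 s/mm²
by default) — the conventional scanner computation, using the whole
acquisition rather than a two-point estimate. The log is undefined for
non-positive signals, so these are excluded voxel-wise and counted; a voxel
with fewer than two usable b-values is invalid (`NA`), and negative fitted
values are clamped to zero (and counted) when `floor_at_zero = TRUE`.
Silent substitution is avoided throughout because downstream texture is
sensitive to systematic map artefacts. The b-value subset is configurable
since the scanner's own choice is generally not documented.

## Feature de-correlation

Redundancy is measured by Spearman correlation by default — the features
are strongly non-normal (the Shapiro–Wilk gate in the comparison stage
confirms this on every run) — with Pearson as an option. Clustering is
agglomerative with complete linkage on the distance $d = 1 - |r|$:
anticorrelated features are just as redundant as correlated ones. The tree
is cut at $k = 10$ clusters by default. Within each cluster the feature
with the greatest dynamic range ($\max - \min$, raw scale by default, with
a rank-normalized option) is kept; ties break alphabetically. Residual
pairs with $|r|$ above 0.9 are then pruned greedily — worst pair first,
dropping the smaller-range member — which guarantees the survivors'
maximum pairwise $|r| \le 0.9$. Linkage, the dynamic-range scale and $k$
are declared defaults, not inferred facts: the published analysis did not
state them.

## Group comparison

Patients are dichotomized at 4.19 cm³ (boundary inclusive to the
low-volume group, matching the "less than" phrasing of the eligibility
rule). Each feature × modality cell gets group medians and IQRs, a
Mann-Whitney U (exact permutation p-value when $n_A + n_B \le 12$ without
ties; otherwise the normal approximation with tie and continuity
corrections) and a Bonferroni-adjusted p-value. The family is the number
of features per modality (10), adjusted separately per modality, because
the published table reports per-modality adjusted values; a pooled family
is a configuration switch since the original family size is ambiguous.

## Recurrence modelling

Recurrence is modelled in surgically-treated low-volume patients with
known follow-up, in two scenarios: all such patients with adjuvant therapy
as a candidate covariate, or excluding adjuvant-treated patients.
Selection is forward–backward stepwise from the intercept-only model,
applying at each step the single add/drop that lowers AIC most (the
direction, entry and stay rules were not published; this is the
conventional AIC procedure and is deterministic given the data). Fits are
maximum-likelihood logistic regressions; complete separation is detected
(fitted probabilities pinned at 0/1, diverging coefficients) and flagged
rather than silently reported.

Multi-feature models are scored by their fitted linear predictor. ROC
analysis reports the concordance AUC (ties credited ½), a DeLong 95% CI
clipped to [0, 1], and the Youden-optimal threshold (ties going to the
lower threshold) with sensitivity and specificity in percent. Whether the
original CIs were DeLong or bootstrap is unstated; DeLong is the declared
default.

Validation uses bootstrap optimism correction with $B = 1000$ resamples by
default: the *fixed* selected term set is refit on each resample, optimism
is the refit's Somers' D on its own resample minus its D on the original
data, and the corrected AUC is $(1 + D_{app} - \overline{\mathrm{opt}})/2$
— equivalently the apparent AUC minus mean optimism on the AUC scale,
using $\mathrm{AUC} = (1+D)/2$. Repeating selection inside the loop is
available (`reselect =`) but is not the default, matching the common
validate-the-final-model convention. Resamples with a single-class outcome
or non-convergent fits are redrawn and counted; more than 50% unusable
draws aborts. All bootstrap seeds are mandatory inputs recorded in the
outputs.

Combined models take the union of the clinical model's terms and a
radiomic model's terms and are compared with the clinical model by a
likelihood-ratio chi-square on the deviance difference, alongside AIC.

## The synthetic generator

What it emulates, with the defaults frozen to the published cohort
structure:

* **Cohort**: 125 patients, 46/125 high-volume; low-arm volumes
  log-normal with mean 1.3 and SD 1.2 cm³ truncated at 4.19 cm³ (no
  low-arm phantom ever crosses the threshold, by construction), high-arm
  mean 15.3 / SD 11.7 cm³ truncated above it; covariate prevalences from
  the published demographics (LVSI 27%, grade 3 43%, adenocarcinoma 38%,
  nodal disease 31%, parametrial invasion 33%, adjuvant therapy 23% of
  surgical patients, surgery in 88.6% of the low arm and 15.2% of the
  high arm, follow-up available in 68/70).
* **Texture features**: sampled per arm from distributions centred on the
  published per-arm medians with spread IQR/1.349, truncated to each
  feature's valid range; Contrast and Entropy are generated as tightly
  coupled companions of Dissimilarity and Energy so the de-correlation
  stage has the redundancy it exists to remove. With
  `with_phantoms = TRUE` the features are instead produced by running the
  actual extraction pipeline on generated phantom volumes (two texture
  classes differing in correlation length between the arms).
* **Outcome**: Bernoulli on a logistic linear predictor. Continuous terms
  enter standardized (z-scored within the cohort) so coefficients read as
  standardized log-odds; binary terms enter 0/1. The default intercept is
  $\mathrm{logit}(0.10)$ — roughly one recurrence in ten, as in the
  low-volume arm being emulated — with modest planted effects on ADC
  Dissimilarity (+1.0), ADC Energy (−0.8), volume (+0.8), depth of
  invasion (+0.5) and LVSI (+0.7). The true effect sizes are unknowable
  from published medians alone, so these are free parameters chosen once
  to make texture, size and histology all informative without making any
  single model trivially perfect.
* **Phantoms**: ellipsoids (axis ratio 1 : 1 : 0.7 — realistic
  non-spherical tumours with analytic volume targeting, refined so the
  rasterized voxel count lands within 5% of the target) filled with a
  stationary correlated Gaussian field: white noise convolved circularly
  with a per-axis Gaussian kernel whose width in voxels is the correlation
  length in mm divided by the voxel spacing, then rescaled in-mask to the
  requested mean/SD. Circular convolution of stationary white noise is
  stationary with the same kernel, so no padding is needed. An optional
  additive sinusoid raises textural uniformity (Energy) in one class.
* **DWI**: $S(b) = S_0 e^{-b\,\mathrm{ADC}}$ plus Gaussian noise (the
  default; adequate at the moderate SNRs simulated), with Rician magnitude
  noise as a flag.

What it deliberately does **not** emulate: the joint dependence structure
of the clinical covariates (only prevalences are published; covariates are
sampled independently by default), endovaginal-coil signal-intensity
inhomogeneity across the image, partial-volume effects at mask borders,
and scanner-specific noise spectra. Green tests on synthetic cohorts
therefore demonstrate that the *procedures* are correct and calibrated —
not that the published effect sizes would replicate on real patients.

## Numerical and interface choices

* Grids are R arrays, so voxel and slice indices are 1-based; the slice
  axis is the third axis. Masks must share their volume's exact grid — no
  implicit resampling, ever (T2-W and ADC VOIs are delineated separately
  on their own grids).
* NIfTI is the volume format (via RNifti). The NIfTI-1 header stores
  voxel spacing in single precision; spacing is rounded to 6 significant
  digits on read so that 0.35 mm survives a round-trip as 0.35.
* Feature and cohort tables are UTF-8 CSV with fixed, documented column
  order and "." decimal; duplicate (patient, modality) rows are refused on
  write, unknown columns are an error on read, incomplete rows are flagged.
* Logistic fits use IRLS with a tight tolerance (1e-10, max 100
  iterations); AIC satisfies deviance + 2(terms+1) exactly.
* Every stochastic stage takes an explicit seed and the pipeline echoes
  its fully resolved configuration, per-stage logs, and an exclusion
  accounting (cohort = analyzed + itemized exclusions) into an immutable
  run directory.

## Problem sizes used by the test-suite and acceptance script

Statistical behaviour is checked at sizes chosen to make the Monte-Carlo
error small relative to each assertion: GLCM oracle equivalence on 50
random small volumes; ADC error on 10⁴ voxels; null calibration of the
comparison stage over 100 cohorts of 40+40; bootstrap optimism at the
emulated study scale (n = 68, 7 events) with B = 200 over 50 seeds;
planted-effect recovery (standardized log-odds 1.5 on ADC Dissimilarity)
over 50 generated cohorts of 125. Stepwise null behaviour is asserted
against its closed-form benchmark (a noise term enters when its deviance
drop exceeds 2, probability $P(\chi^2_1 > 2) \approx 0.157$), with
3-binomial-SE slack.

## Known limitations

* Quantization is fixed-bin-count over the in-mask range; fixed-bin-width
  quantization (preferable when absolute intensities are comparable across
  patients, as for ADC in physical units) is not implemented.
* The optimism correction validates the final term set; when selection
  itself is unstable, the default under-estimates optimism — use
  `reselect` to validate the whole selection procedure.
* Polygon/RT-STRUCT contours are out of scope; masks must arrive as
  binary volumes (or per-slice binary masks to stack).
* The multiplicative coil bias-field option for phantoms is not
  implemented; phantom fields are stationary.
* No IVIM/kurtosis diffusion models, no motion or eddy-current
  correction, and no survival (time-to-event) modelling — recurrence is a
  binary endpoint here.
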