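---
title: "Methods: automated PWI-DWI mismatch estimation and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated PWI-DWI mismatch estimation and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokemismatch)
```

## Scope and model

`strokemismatch` estimates the perfusion-diffusion mismatch in acute
ischemic stroke MRI and renders the standard imaging-based thrombolysis
eligibility decision. The pipeline assumes its inputs — a diffusion pair
(b = 0 and b = 1000 s/mm²), a 4D dynamic susceptibility contrast (DSC)
series, and optional follow-up or rater masks — are already co-registered
on a common grid; it checks shape and spacing agreement and refuses
mismatched grids rather than registering. Registration, DICOM ingestion,
bias-field and motion correction are out of scope.

The biophysical model is deliberately minimal and standard:

* **ADC.** Monoexponential diffusion decay, `S_b = S_0 exp(-b·ADC)`, so
  `ADC = ln(S_b0/S_b1000)/b` in mm²/s. Non-positive signals make the voxel
  undefined (`NaN`), never ±Inf: background and noise-floor voxels carry
  no diffusion information.
* **Tissue concentration.** The DSC signal drop is converted by the usual
  transverse-relaxivity relation `C(t) = -ln(S(t)/S0)/TE` (1/s), with `S0`
  the per-voxel mean of the pre-bolus baseline samples. TR and TE are
  taken from arguments, not headers, because exported DSC headers are
  unreliable for timing.
* **TTP.** The time-to-peak is the grid time of the concentration maximum,
  `argmax_t C(t) · TR`, with plateau ties resolved to the earliest sample
  (deterministic, and conservative in that it reports the shortest delay).
  TTP is referenced to the series start; only contralateral *differences*
  enter segmentation, so the global offset cancels. No deconvolution is
  performed — TTP is the perfusion statistic of this pipeline, not MTT or
  Tmax — and no temporal smoothing is applied by default (`ttp_smooth`
  exposes an optional centered moving average).

## Laterality detection

Lesion laterality decides which hemisphere provides the "normal tissue"
reference, so it must be reliable for small lesions. Hemisphere-level
location statistics (for example the hemisphere median of TTP) are
insensitive here: a focal lesion occupying a few percent of a hemisphere
leaves the hemisphere median untouched, so a median-contrast score
degenerates to noise for exactly the lesions that matter. The package
instead scores *mirrored voxel differences*:

1. The midline is the mid-plane of the brain-mask bounding box along the
   left-right axis (phantoms and re-sliced clinical data are approximately
   centered; no anatomical midsagittal fit is attempted).
2. For each map, every brain voxel is paired with its mirror voxel and
   the lesion-signed difference is formed (TTP minus mirror for delay,
   mirror minus ADC for diffusion restriction).
3. Differences are converted to robust z-scores by the brain-wide
   IQR/1.349 scale, and the fraction of voxels per hemisphere exceeding
   `z_cut` (default 2) is computed.
4. The score is the high-minus-low hemisphere contrast of these tail
   fractions, normalized by their sum floored at `f_floor` (default 1% of
   hemisphere voxels, so symmetric noise cannot saturate the contrast),
   averaged over the TTP and ADC channels. Its magnitude lies in [0, 1].

Scores below `laterality_min_score` (default 0.1) produce an explicit
`"undetermined"` state; the pipeline then refuses to auto-segment and
requires an explicit side, surfacing as exit code 3 on the command line.
`z_cut = 2` was chosen because the per-voxel mirrored-difference noise
scale of TTP on the reference phantom is roughly 2 s, so two robust SDs
correspond to the 4 s clinical delay threshold; the default minimum score
keeps deterministic symmetric phantoms (score 0) and noisy symmetric
phantoms (observed scores well below 0.1 across seeds in the test suite)
in the undetermined state while small lesions (5 mL core, 20 mL
hypoperfusion) score several times the minimum.

## Lesion delineation against a mirrored reference

For each candidate voxel the healthy-tissue reference is the mean and
sample SD (n − 1) of the map over a cubic neighborhood (default 5³
voxels) centered on the voxel's mirror position, restricted to brain
voxels with defined values; voxels whose mirror falls outside the brain
have an undefined reference and never enter a lesion. The criteria are:

* **DWI core:** `b1000 > ref_mean + k·ref_SD` (default `k = 2`) **and**
  `ADC < adc_max` (default 620e-6 mm²/s, a common clinical cutoff for
  acute infarction). The conjunction guards against T2 shine-through,
  which elevates the diffusion-weighted signal without restricting ADC.
* **TTP lesion:** `TTP − ref_mean > ttp_delay_threshold` (default 4 s).

Cleanup is identical for both modalities and applied in a fixed order:
threshold → optional 3D opening → removal of clusters below
`min_cluster_mL` (default 0.2 mL) → hole filling. Masks are clipped to
the affected hemisphere unless `allow_midline = TRUE` (bilateral
pathology). The opening radius defaults to 0: on anisotropic clinical
grids (5 mm slices) a radius-1 voxel ball erodes an entire slice from
thin lesions and biases small-core volumes substantially, while the dual
DWI criterion and the minimum-cluster filter already remove speckle — on
lesion-free phantoms the residual false-positive volume is essentially
zero. The opening remains available for noisier data.

All thresholds have physical units (signal SDs, mm²/s, seconds, mL), are
carried in a single flat configuration (`default_config()`), and are
persisted with an MD5 hash into every report for auditability.

## Mismatch, eligibility and contraindications

The mismatch is the set difference `TTP lesion AND NOT DWI lesion`;
volumes are voxel counts times the voxel volume, so
`V(mismatch) + V(TTP ∩ DWI) = V(TTP)` holds exactly and is asserted in
the tests. Two ratio conventions exist in the stroke literature: the
trials behind the standard 1.2 cutoff used the PWI/DWI volume ratio,
while the verbal definition of the mismatch ratio is mismatch/core. Both
are implemented; `pwi_over_dwi` is the default because the 1.2 threshold
travels with that convention, and the convention in force is recorded in
every result and report rather than silently assumed. A zero core with a
nonzero numerator yields an infinite ratio, serialized as the JSON string
`"inf"`.

Eligibility is `mismatch volume > 10 mL` AND `ratio > 1.2`, both strict,
matching the wording of the thresholds. The contraindication screen (SBP
> 185 mmHg, DBP > 110 mmHg, intracranial hemorrhage, anticoagulant use,
INR > 1.7, onset-to-treatment > 4.5 h; all strict) is reported as a list
of named flags *alongside* the imaging decision, never fused into a
single verdict: clinicians weigh the two hierarchically, and an unknown
field yields an `unassessable:<field>` flag rather than a silent pass.

## Consensus masks

Multi-rater masks are combined by voxelwise summation of ratings
(1 = lesion) and thresholding at a summative cutoff, default 3 of 4
raters. The comparison is `>=`: a "cutoff of 3" admits voxels rated by
exactly three raters. Cutoff 1 is the union, cutoff n the intersection,
and the consensus is monotone non-increasing in the cutoff — all
asserted exhaustively on random rater stacks in the tests.

## Evaluation statistics

* **Confusion matrices** compare automated eligibility (rows) against a
  reference decision (columns; actual treatment or a consensus-derived
  decision). Sensitivity, specificity, PPV and NPV are reported in
  percent; a zero denominator yields an explicit `NA`, never 0.
* **Volumetric agreement**: Spearman rank correlation (average ranks on
  ties) plus Bland-Altman mean difference, SD, and mean ± 2 SD limits of
  the differences `a − b`.
* **Mismatch salvage**: `V(acute mismatch AND NOT follow-up infarct)`;
  `salvage + V(mismatch ∩ infarct) = V(mismatch)` exactly.
* **Rank-sum test**: Wilcoxon-Mann-Whitney, two-sided, average ranks on
  ties. The exact distribution is used when both samples have ≤ 20
  observations and no ties; with ties, exact enumeration over group
  assignments is used while `choose(n+m, n) ≤ 2e5` (full enumeration at
  20 + 20 would require ~1.4e11 arrangements and is not attempted);
  otherwise the normal approximation with continuity correction. The test
  suite checks both the small-fixture agreement with brute-force
  enumeration and the null calibration (rejection rate at the 5% level
  within [0.03, 0.07] over 2000 seeded replicates).
* **Group summaries**: medians and IQRs per confusion cell with type-7
  (linear interpolation) percentiles — stated explicitly because reported
  IQRs depend on the percentile convention. The NIHSS improvement
  `ΔNIHSS = NIHSS_acute − NIHSS_24h` is positive for improvement.
* **CART**: greedy binary partitioning maximizing the decrease of the
  Gini diversity index `1 − Σ p_c²`, candidate thresholds at midpoints
  between consecutive distinct values, deterministic tie-breaking by
  feature order then lowest threshold (Gini ties are common on small
  cohorts), stopping on purity, `min_leaf` (default 5), or `max_depth`
  (default 4). No pruning or cross-validation: the tree is descriptive.
  Chosen splits are verified against exhaustive search on small fixtures
  and against an independent implementation (`rpart`) on a synthetic
  cohort; trees recover a known hierarchical generating rule
  (contraindication → mismatch volume → NIHSS) in ≥ 90% of seeded
  replicates.

## The phantom: what it emulates and what it does not

The generator emulates a routine acute stroke protocol: 24 cm FOV on a
64×64 matrix (3.75 mm in-plane), 5 mm slices, DSC with TR 1.5 s and
TE 50 ms, 40 time points with 8 pre-bolus samples, diffusion at b = 0 and
1000 s/mm². Tissue values are normal ADC 0.9e-3 mm²/s, core ADC
0.5e-3 mm²/s, a 1.6× T2 elevation of the core baseline signal (applied to
both diffusion images so the injected ADC is preserved), a gamma-variate
bolus (shape α = 3, β = 1.5 s) whose only hypoperfusion effect is an
arrival delay (default 6 s), and additive Gaussian signal noise at 5% of
the tissue baseline. Lesions are ellipsoidal and sized by selecting the
requested number of voxels nearest an off-lattice center, so constructed
truth volumes match requests to within one voxel and the core is nested
in the hypoperfused region by construction. The seed fully determines
every output.

Deliberate simplifications, and hence what passing tests do **not**
demonstrate about clinical data: no anatomy (ellipsoids, no atlas, no
CSF), sharp lesion boundaries (no partial-volume gradient), Gaussian
rather than Rician noise, a single global bolus shape with no
dispersion, no benign oligemia surrounding the lesion, no motion or
susceptibility artifacts, and perfectly centered geometry. The phantom
validates the *machinery* — map computation, reference mirroring,
thresholds, set arithmetic, decision logic — not clinical segmentation
accuracy.

A cohort generator complements the imaging phantom for the evaluation
layer: it draws per-patient volumes, ratios, NIHSS scores and
contraindication profiles consistent with requested confusion-matrix
cells (TP/FP imaging-eligible, TP/FN treated), with cell-wise
contraindication prevalences defaulting to 24/83/73/23% (TP/TN/FP/FN)
and location parameters shaped like a thrombolysis cohort. Generated
salvage volumes respect the definitional bound salvage ≤ mismatch even
where published cell summaries are mutually inconsistent on this point.

## Numerical choices and degenerate inputs

* Volumes are `count × dx·dy·dz / 1000` mL; no slice-gap correction is
  applied (spacing-product volume).
* Masks are uint8 on disk, float maps float64, so round-trips are exact.
* The left-right axis is resolved from NIfTI qform/sform orientation;
  files without orientation require an explicit `lr_axis` rather than a
  guess. `flip_lr()` updates the direction metadata, so a flipped volume
  still reports the same patient side; a raw array flip (metadata kept)
  flips the reported side, and both behaviors are tested.
* Otsu thresholding uses a 256-bin histogram; constant volumes are an
  error, not an empty mask.
* Undefined map values are `NaN` in memory and are excluded from every
  statistic; voxels outside the brain mask are never interpreted.
* TTP delays within about one TR of the delay threshold are not reliably
  recoverable: the per-voxel peak shift quantizes to the TR grid (1.5 s),
  so an injected 4 s delay oscillates between 3.0 and 4.5 s against the
  4 s threshold. The phantom recovery suite therefore exercises delays of
  6-10 s, comfortably above the threshold, and the default phantom delay
  is 6 s; sub-TR delay resolution is a physical limit of TTP-grid
  segmentation, not a tunable.

## Known limitations

Inputs must be co-registered and roughly midline-centered; the geometric
midline assumption fails for grossly tilted acquisitions. PWI without
deconvolution cannot separate critically hypoperfused tissue from benign
oligemia, so the TTP lesion — and with it the mismatch — tends to
overestimate tissue at risk; the delay threshold is config-exposed for
this reason. DWI lesion reversal after reperfusion is not modeled. The
contraindication screen covers the six database-available criteria only
and is decision *support*: the package never outputs a treat/no-treat
verdict.
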