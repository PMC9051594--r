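---
title: "Methods: whole-body PSMA PET tumor volumetry and its test-retest repeatability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-body PSMA PET tumor volumetry and its test-retest repeatability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psmarepeat)
```

## The problem

Whole-body molecular tumor volume (MTV_total) on PSMA PET is a candidate
biomarker for monitoring advanced prostate cancer: it summarizes total
disease burden in a single number. Before a change in MTV_total can be read
as disease progression or response, one has to know how much the number
moves when nothing has changed — the test–retest repeatability of the whole
measurement chain, segmentation included. This package implements that
chain: semiautomatic whole-body lesion segmentation on SUV volumes,
per-lesion and per-patient burden metrics, and the repeatability statistics
that turn paired scans into a repeatability coefficient (RC), the smallest
relative change exceeding measurement noise with 95% probability.

Because no image data are distributed with studies of this kind, the
package also contains a first-class synthetic-data module: paired PET
phantoms with known ground truth, and tabular paired cohorts with a known
true within-subject CV, so every stage of the pipeline is testable without
any download.

## Segmentation model

A scan is a non-negative SUV volume on an axis-aligned grid (mm spacing;
the physical center of voxel `(i, j, k)`, 1-based, is
`origin + (index - 1) * spacing`). Segmentation proceeds in four steps.

**Liver-referenced threshold.** Candidate tumor foci are voxels whose
SUVpeak reaches

```
threshold = constant / liver_mean * (liver_mean + liver_sd)
```

with `constant = 4.3` (a nominal normal-liver SUVmean, configurable) and
`liver_mean`, `liver_sd` measured in a liver reference VOI supplied as a
mask (sample, n−1, standard deviation by default; a population variant is
available). The leading factor corrects for the tumor sink effect: a large
tumor burden sequesters tracer and lowers liver uptake, which would
otherwise drag the threshold down with it. The formula's typography is
ambiguous in print; we adopt the reading consistent with its stated intent
— a corrective coefficient (`constant / liver_mean`) times the uncorrected
liver threshold (`liver_mean + liver_sd`) — so the threshold is strictly
decreasing in the observed liver mean at fixed sd, and equals
`liver_mean + liver_sd` when the liver is nominal.

**SUVpeak.** Undefined in most clinical reports; we adopt the common
EANM-style convention: the mean SUV over all voxels whose centers lie in a
1.0 mL sphere (radius ≈ 6.2 mm, volume configurable) centered on the voxel.
A sphere smaller than one voxel degenerates to the voxel's own value; at
grid edges only in-grid centers contribute. Candidate detection evaluates
SUVpeak only inside the sphere-dilation of the set of voxels at or above
the threshold — an exact restriction, since the sphere mean can only reach
the threshold within sphere reach of a voxel that does.

**Candidate foci.** Connected components (26-connectivity by default;
6/18/26 configurable) of the SUVpeak-qualified set, one seed per component
at the component's SUVmax voxel. Components seeded inside the liver
reference VOI are dropped automatically — the reference organ is
definitionally not tumor; all other physiologic uptake (bladder, salivary
glands, ...) is removed by the explicit manual-edit step below, mirroring
how such segmentations are actually cleaned up.

**50% isocontour delineation.** From each seed the algorithm ascends to the
connected regional SUV maximum (strict hill climb; plateaus terminate the
ascent, and ties anywhere are broken by the smallest column-major index so
results are deterministic), then grows the connected set of voxels at or
above half that local maximum. If growth reaches a higher voxel — two peaks
joined above the half-max level — the threshold is re-anchored at the
higher maximum and the region regrown; the iteration terminates because the
threshold strictly increases. Climbing first makes the contour independent
of which component voxel happened to be flagged. Candidates are processed
in descending SUVmax; voxels already claimed are never re-claimed, a
delineation whose local maximum is already claimed is dropped, and a
partially overlapping delineation keeps the connected piece containing its
maximum. Every emitted lesion therefore satisfies
`min(SUV) >= 0.5 * max(SUV)` within its mask, masks are pairwise disjoint
and connected, and on noiseless phantoms with separated lesions the output
equals ground truth voxel-for-voxel (asserted in the tests).

**Manual edits.** Whole-lesion granularity only: a lesion can be excluded
(by id or by a contained point) or a missed lesion added by delineating
from a supplied seed. Contours are never partially edited. Applying the
same edit list twice is a no-op the second time, so edits are idempotent.

**Cross-scan matching.** Per-lesion analyses need the same lesion on both
scans. Lesions are paired by mutual nearest centroids within a 15 mm cap
(configurable). One-to-many constellations — a metastasis segmented as one
focus on one scan and several on the other — are reported as conflicts and
excluded from the pair list rather than silently merged; resolving a split
is a human decision.

## Burden metrics

Per lesion: MTV (voxel count × voxel volume, mL), SUVmax, SUVpeak (on a
plateau of tied maxima, the sphere position maximizing the sphere mean),
SUVmean, PSMA-TL = MTV × SUVmean (the PSMA analogue of total lesion
glycolysis) and PSMA-TLQ = MTV / SUVmean. The exact identity
`PSMA-TL * PSMA-TLQ = MTV^2` is asserted on randomized inputs. Subgroup
aggregates (a random sample of up to 10 lesions per patient, deterministic
under a seed; optionally stratified over region tags) take sums of MTV,
PSMA-TL, PSMA-TLQ, the mean lesion MTV, and unweighted means of the SUV
statistics. Patient totals do the same over all lesions; a patient with no
detected disease yields all-zero totals with `n_lesions = 0`.

## Repeatability statistics

For paired measurements `(a_i, b_i)` over `n` subjects the within-subject
coefficient of variation is

```
wCV = sqrt( mean_i [ (a_i - b_i)^2 / (2 * ((a_i + b_i)/2)^2) ] )
RC  = 1.96 * sqrt(2) * wCV
```

Subjects with `a = b = 0` (no disease on either scan) contribute an
undefined 0/0 term; they are excluded by default and counted in the output
(`zero_policy = "error"` refuses instead). A single-sided zero is a finite
term (value 2) and is retained. Confidence intervals are percentile
bootstrap over subjects (lesions, for the per-lesion analysis, which treats
lesions as independent observations), 1000 replicates by default,
bit-reproducible under a seed. Bland–Altman agreement uses absolute
differences, `d = scan2 - scan1` by default (configurable sign), bias ±
1.96·sd limits of agreement and a normal-approximation bias CI. The ICC is
the single-measure two-way coefficient computed from ANOVA mean squares;
the default variant is absolute agreement, ICC(A,1), and the variant label
is always carried with the value because consistency and agreement answer
different questions (a constant reader offset gives consistency 1 but
agreement < 1). Pearson correlations use the two-sided t transform, with an
optional log10–log10 mode that drops non-positive pairs (zero-burden
patients) first. An exploratory profile stratifies per-lesion
repeatability by SUVmax with thresholds `1, 6, 11, ...`; both directions
("below": lesions under the threshold, as published; "above": discarding
low-avidity lesions) are implemented because the accompanying prose
describes both, and strata under 3 lesions are flagged rather than hidden.

Reader-swap designs (scan 1 read by reader 1 paired with scan 2 read by
reader 2, and conversely) are expressed purely as reader tags on the pairs
table; there is no special code path. The study driver
`run_repeatability_study()` composes all of the above and its report
contains the pairs table it used, so every reported statistic can be
recomputed directly from the report (asserted in the tests).

## Synthetic data: what it emulates, and what it does not

A phantom is a background of 0.5 SUV, a liver ellipsoid with Gaussian
texture (mean 5.0, sd 0.5 — placing the threshold near 4.7, above
background and below lesion peaks), uniform-sphere or Gaussian lesions,
and optional physiologic hot spots (rendered, but absent from ground
truth). The default grid is 128 × 128 × 256 at 2 mm isotropic: large
enough for a liver plus ~13 well-separated lesions, seconds-scale to
render. The retest model draws, independently per scan, per-lesion
amplitude multipliers (`1 + N(0, cv)`, clamped at 2.5 cv) and mean-one
log-normal lesion-volume multipliers; the parameters are per-scan CVs, so
the measured between-scan wCV of the corresponding metric targets the
parameter. The second scan additionally takes a global uptake scale (to
which the liver-referenced threshold is invariant by construction), voxel
noise, and a subvoxel shift. Everything is a deterministic function of the
spec seed.

Tabular cohorts draw log-normal true burdens (median 30 mL, log-sd 1.5 —
spanning roughly 2–650 mL, the realistic range for advanced disease) and
apply multiplicative retest errors, normal (`T(1+e)`, negatives resampled)
or mean-one log-normal. `true_wcv` is defined as the population value of
the quantity the wCV estimator targets, and the error-law scale is
calibrated to it by numeric integration and root finding: at large CVs the
nominal scale and the estimand diverge at second order (at 27.7%, the
naive log-normal parametrization would bias the estimate several points
low and the naive normal one several points high), and without calibration
"estimator recovery" would conflate generator parametrization with
estimator behavior.

The 18-patient study fixture mirrors a real cohort's shape: 2 disease-free
patients, 96 lesions spread over the rest (1–13 per patient), per-patient
target volumes taken from the bundled example cohort, a bladder hot spot
removed by both readers' edit lists, and an injected between-scan
lesion-volume CV of 12.7%. Two choices deserve justification:

* **Coherent volume perturbation.** The injected volume deviations are
  shared by all lesions of a patient (scan-level effects — uptake time,
  calibration, threshold shift — move a patient's lesions together), so the
  lesion-level CV carries through to MTV_total unattenuated; with
  independent per-lesion deviations the per-patient CV would shrink by
  roughly the root of the effective lesion count and the end-to-end check
  would be testing the lesion-size distribution, not the pipeline.
* **Exact injection.** The drawn per-patient deviations are standardized
  to the target second moment, making the injected within-subject CV exact
  in the finite 16-patient cohort (as in a calibrated physical phantom
  study). The end-to-end run then isolates segmentation and voxelization
  error from cohort sampling error; with free sampling, the n = 16
  estimator noise (SE ≈ 2.2 percentage points on the wCV) would dominate
  the comparison.

What the phantoms deliberately omit: scanner point-spread blurring and
partial-volume effects (the segmentation oracle stays exact; real 50%
isocontours on blurred data run systematically larger), scatter/randoms
noise structure, anatomy (organs other than one liver ellipsoid and one
bladder sphere), and lesion shapes other than spheres and Gaussians.
Passing the phantom tests therefore demonstrates correctness of the
algorithms, not clinical accuracy of the segmentation on real scans.

## Numerical and degenerate-input choices

Ties in maxima are broken by the smallest column-major linear index.
Volumes are kept at full float precision throughout and rounded only at
table export (percents to 1 decimal, volumes to 2). NIfTI volumes are
written float32, label masks uint16; masks must share the volume's exact
grid (no resampling). Zero-lesion patients propagate as all-zero totals
and are handled by the wCV zero policy. The liver VOI must have positive
mean SUV; an absent mask label, a non-positive delineation seed, an empty
lesion aggregate, constant-columns ICC, and sub-minimum pair counts all
raise errors rather than returning numbers.

On a 1 mm grid, a σ = 4 mm Gaussian lesion's 50% isocontour contains
437–480 voxels depending on how the center sits relative to the lattice
(analytic ball: 437.6 mm³); lattice-aligned centers are the worst case.
Voxelization error of this order (a few percent for small lesions) is the
irreducible floor for voxel-counted MTV.

## Known limitations

* Percentile bootstrap CIs for wCV undercover at small n: at n = 16 and
  true wCV 12%, empirical coverage is ~85% (the per-subject squared
  relative differences are χ²(1)-skewed, and percentile intervals are
  monotone-transformation-invariant, so no rescaling helps; coverage
  approaches the nominal 95% by n ≈ 250). CIs from small cohorts should be
  read as optimistic. `analysis/01_simulate_cohorts.R` measures this.
* The wCV estimator is evaluated verbatim per pair; pooled-variance
  conventions found in some reports give different numbers from the same
  table, so cross-study wCV comparisons should check the convention.
* Lesion matching is geometric (centroids); gross anatomical
  rearrangement between scans would need manual pairing, and conflicts are
  surfaced, never auto-resolved.
* Only axis-aligned grids are supported; images must be resampled to a
  common grid upstream if needed.

## Problem sizes used by the shipped analyses

The numbered scripts under `analysis/` run: estimator recovery at
n = 5000 subjects per condition (Monte-Carlo SE ≈ 0.1–0.3 percentage
points on the wCV), bootstrap coverage at 200 replicate cohorts of n = 16,
and the full 18-patient phantom study on the default 2 mm whole-body grid
(about 90 seconds end to end). The test suite uses the same fixture plus
smaller grids for the unit-level oracles.
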