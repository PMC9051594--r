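# psmarepeat

Test–retest repeatability of whole-body tumor volumetry on PSMA PET, for
imaging scientists and biostatisticians who need to know how large a change
in PET-derived tumor burden must be before it means anything.

Whole-body molecular tumor volume (MTV_total) on ⁶⁸Ga-PSMA PET summarizes a
prostate-cancer patient's total disease burden in one number, and related
metrics fold avidity in: PSMA-TL = MTV × SUVmean (the PSMA analogue of
total lesion glycolysis) and PSMA-TLQ = MTV / SUVmean. Using such numbers
to call progression or response requires their test–retest repeatability —
segmentation included, because the segmentation is part of the measurement.

The package implements the full chain:

* **Segmentation** — liver-referenced candidate detection: voxels whose
  SUVpeak (1 mL sphere mean) reaches
  `4.3 / liver_SUVmean × (liver_SUVmean + liver_SUVsd)`, a threshold whose
  leading factor corrects for the tumor sink effect; per-candidate
  delineation by the 50% isocontour of the local SUVmax; whole-lesion
  manual edits; mutual-nearest-centroid lesion matching across scans.
* **Metrics** — per-lesion MTV / SUVmax / SUVpeak / SUVmean / PSMA-TL /
  PSMA-TLQ; random subgroups of up to 10 lesions per patient; per-patient
  totals.
* **Statistics** — within-subject coefficient of variation
  `wCV = √( meanᵢ (aᵢ−bᵢ)² ⁄ [2 ((aᵢ+bᵢ)/2)²] )` and repeatability
  coefficient `RC = 1.96 √2 wCV`, percentile-bootstrap CIs, Bland–Altman
  agreement, two-way ICC, Pearson/R², reader-swap designs, and an
  RC-vs-SUVmax stratification.
* **Synthetic data** — paired whole-body PET phantoms with exact ground
  truth and tabular paired cohorts with a calibrated true wCV, so the
  whole pipeline is verifiable without any image download. An 18-patient
  example test–retest cohort (two readers × two scans, plus PSA) is
  bundled.

## Worked example

Repeatability of MTV_total in the bundled cohort, reader 1 against himself
across the two scans:

```r
library(psmarepeat)
ch <- testretest_cohort()
repeatability(cohort_pairs(ch, "R1"), n_boot = 1000, seed = 17)
#> wCV 8.5% | RC 23.6% (95% CI 12.2-33.1%) | n = 16 (2 zero pair(s) excluded)
```

Reader 1's MTV_total must change by more than ~24% before the change
exceeds measurement variability; the two patients with no detectable
disease on either scan carry no repeatability information and are excluded
(and counted). Agreement between scans and readers:

```r
bland_altman(cohort_pairs(ch, "mean"))
#> Bland-Altman (b_minus_a): bias -1.965 (95% CI -7.764 to 3.834), LoA -26.568 to 22.638, n = 18
icc(cbind(ch$r1_scan1, ch$r1_scan2))
#> ICC 0.9934 [two-way, absolute agreement, single measure (ICC(A,1))], n = 18 x 2, p = 4.78e-18
```

The mean bias of −2.0 mL is small against limits of agreement of ±25 mL,
and the same reader ranks patients almost identically across scans.

Segmenting a synthetic paired phantom with known ground truth:

```r
sp <- phantom_spec(
  lesions = list(lesion_spec(c(60, 196, 54), "uniform_sphere", 12, 20),
                 lesion_spec(c(196, 60, 54), "uniform_sphere",  8, 25)),
  retest  = list(lesion_amp_cv = 0.1, vol_cv = 0.127, vol_mode = "patient"),
  seed = 42)
pair <- generate_phantom_pair(sp)
seg1 <- segment_whole_body(pair$scan1, pair$liver_mask)
seg1
#> <patient_segmentation> phantom / scan1: 2 lesion(s), liver threshold 4.734 SUV, 0 edit(s)
lesion_table(pair$scan1, seg1)[, c("lesion_id", "mtv_ml", "suv_max", "suv_mean")]
#>    lesion_id mtv_ml  suv_max suv_mean
#> i          1  2.240 24.05985 24.05985
#> i1         2  7.744 17.19783 17.19783
```

Both inserted lesions are recovered; on noiseless uniform phantoms the
recovered voxel sets equal ground truth exactly (this is asserted in the
test suite).

## The analysis workflow

The numbered scripts under `analysis/` run the study end to end and write
their tables under `results/analysis/`:

1. `01_simulate_cohorts.R` — estimator recovery on simulated cohorts
   (n = 5000) across the CV range seen in PET volumetry, and the
   small-sample coverage of the bootstrap CIs.
2. `02_phantom_study.R` — the full 18-patient synthetic study: 96 lesions,
   two readers, bladder hot spots removed by reader edits, injected
   lesion-volume CV of 12.7%; produces per-lesion / subgroup / total /
   reader-swap repeatability tables, Bland–Altman and ICC.
3. `03_cohort_reanalysis.R` — the tabular statistics on the bundled
   18-patient cohort: per-reader and reader-swap wCV/RC with bootstrap
   CIs, reader-averaged Bland–Altman, ICCs, and the log–log correlation of
   burden with PSA.

The methods vignette (`vignettes/repeatability-methods.Rmd`) documents the
segmentation model, the statistics, the phantom design and its
limitations.

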