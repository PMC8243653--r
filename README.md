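# pacdetect

Delineation-free detection of premature atrial complexes (PACs) and
ventricular beats in long-term two-lead ambulatory ECG.

## The problem

PACs are early heartbeats of atrial origin: an early R peak, an
altered or seemingly absent P wave, a near-normal QRS and a
non-compensatory pause. They are increasingly linked to atrial
fibrillation onset and stroke risk, but annotating them in 24-hour
Holter recordings by hand is impractical, and classical beat
classifiers reach poor PAC sensitivity. Ventricular ectopic beats (wide
abnormal QRS, no preceding P wave, full compensatory pause) disturb the
rhythm in a similar way and must be told apart from PACs by morphology.

`pacdetect` implements a beat classifier that needs **no ECG
delineation** — only R-peak beat annotations, which are robust to
obtain. Each beat is described by:

* **HRV features (42)** — RR and dRR (`dRR_n = RR_{n+1} - RR_n`) of the
  beat and both neighbors, plus mean RR, sd RR, sd dRR, pNN10..pNN50
  and RMSSD over four windows: 1 and 5 min preceding the beat, 2 and
  10 min centered on it.
* **Morphology features (72 per signal version)** — fixed windows
  around the R peak (`t = 0`): whole beat [-300, 250] ms, P wave
  [-300, 40] ms, PR interval [-288, 0] ms, QRS [-70, 60] ms. For each
  segment, intra-patient templates are built from 80, 20 and 4
  neighboring beats (cross-correlation aligned, outliers excluded,
  averaged); the beat's maximum normalized cross-correlation against
  each template, the corresponding lag, and the template's median
  per-sample standard deviation are the features, per lead.
* The morphology block is computed twice: on the preprocessed ECG and
  on **W4**, the scale-4 detail of the undecimated quadratic-spline
  wavelet transform (a trous scheme), which band-limits the signal to
  where P/QRS energy concentrates.

Preprocessing: resample to 250 Hz, subtract a baseline-wander estimate
from two cascaded median filters (200 and 600 ms), then a linear-phase
35 Hz FIR low-pass with group-delay compensation. A random forest
(500 trees, min split 10, min leaf 2, max depth 20, no bootstrap
resampling) classifies beats as N / S / V (or S vs Other in binary
mode) under **patient-wise** k-fold cross-validation: folds balance the
S proportion, no patient contributes beats to both train and test, and
each class is capped at 10,000 training beats. Feature conditioning per
fold: physiological clipping (RR into [250, 3428.6] ms), imputation,
variance pruning (< 0.05), Pearson dependence pruning (|r| > 0.95),
z-scoring — all fitted on the training folds only.

PhysioNet beat symbols map to simplified classes as `A,a,S -> S`;
`V,F,E -> V`; `N,B,e -> N`; `J,j,Q` and anything else are excluded
(they keep their R peak for RR timing but get no feature vector).

## Worked example

```r
library(pacdetect)

g  <- generate_record(synth_config(seed = 42), patient_id = "demo01")
pp <- preprocess_record(g$record, g$annotations)
pp$record
#> <ecg_record> patient=demo01  2 leads x 59019 samples @ 250 Hz (236.1 s)

features <- assemble_features(pp$record, pp$annotations)
nrow(features); table(features$label)
#> [1] 220
#>   N   S   V
#> 170  21  29
```

300 annotated beats yield 220 feature vectors (the first and last 40
beats are trimmed). The class contrasts the classifier exploits are
directly visible:

```r
round(tapply(features$morph_raw_qrs_t80_L1_xcorr, features$label, median), 3)
#>     N     S     V
#> 1.000 0.999 0.601     # ventricular beats break the QRS template match
round(tapply(features$hrv_drr_i, features$label, median), 1)
#>   N   S   V
#> -60 304 360            # premature beats disrupt the dRR sequence
```

End to end (synthesize a 20-patient cohort, extract, cross-validate
patient-wise, write a report directory):

```r
res <- run_all("run1", n_patients = 20, k = 2, mode = "multiclass", seed = 1)
```

or from the shell via the CLI wrapper:

```sh
Rscript inst/cli/pacdetect.R all --out run1 --k 2 --seed 1
```

The report directory contains `metrics.json` (beat-wise and
patient-wise median/IQR metrics), per-beat and per-fold predictions,
the row-normalized confusion matrix, top-10 feature importances per
fold, and an `audit.jsonl` log proving train/test patient
disjointness. `Rscript inst/cli/pacdetect.R replicate-physionet`
prints the recipe for running the same pipeline on the PhysioNet
LTSTDB/SVDB databases (multi-GB downloads; not part of the tests).

## Notes

* The synthetic generator uses transparent sum-of-Gaussians beat
  kernels with exaggerated class contrasts; green tests establish that
  the pipeline recovers planted physiology, not clinical performance.
  See the methods vignette (`vignettes/pacdetect-methods.Rmd`).
* Feature names follow `hrv_*` and
  `morph_{raw|w4}_{beat|p|pr|qrs}_{t80|t20|t4}_L{1|2}_{xcorr|lag|medsd}`.
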