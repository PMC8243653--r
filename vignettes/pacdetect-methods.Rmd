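---
title: "Methods: delineation-free PAC and ventricular beat detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: delineation-free PAC and ventricular beat detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

A PAC shows up in the ECG as two things: a disruption of the RR
sequence (an early R peak followed by a non-compensatory pause) and a
distortion of the P wave. Ventricular ectopy disrupts the rhythm
similarly but deforms the QRS and usually lacks a preceding P wave.
`pacdetect` encodes exactly these two information channels as features
of each annotated beat and lets a random forest combine them; crucially
it never delineates wave boundaries, because delineation is the
fragile, patient-dependent step in classical beat classifiers.

**HRV block (42 values).** With `RR_i` the interval ending at beat
`i`'s R peak and `dRR_n = RR_{n+1} - RR_n`: the six beat-local values
`(RR_i, RR_{i-1}, RR_{i+1}, dRR_i, dRR_{i-1}, dRR_{i+1})` in
milliseconds, plus nine statistics (mean RR, sd RR, sd dRR,
pNN10..pNN50 as percentages with a strict `>` threshold, RMSSD) over
four windows: 1 and 5 minutes *preceding* the beat (RR entries whose
ending R peak lies in `[t_i - d, t_i)`) and 2 and 10 minutes *centered*
(`[t_i - d/2, t_i + d/2]`). Windows with fewer than 3 RR entries are
flagged missing and imputed with training-fold column means at model
time. Standard deviations use the n-1 denominator. Every annotated R
peak contributes to RR timing regardless of class — an R peak exists
physically even for beats excluded from classification.

*A counting note:* the literal enumeration (6 beat-local + 4 windows x
9 statistics) gives 42 values; the published description of this
feature family totals them as 41 without saying which one is dropped.
We emit all 42 under stable names and treat the discrepancy as
unresolved rather than silently reconciling it; feature totals are not
acceptance-relevant.

**Morphology block (72 values per signal version).** Fixed windows
around the R peak at `t = 0`: whole beat [-300, 250] ms, "P wave"
[-300, 40] ms, "PR interval" [-288, 0] ms, "QRS" [-70, 60] ms
(sample offsets are `round(ms * fs/1000)` with ties away from zero).
The quotes matter: without delineation these windows only approximate
the named ECG regions — the P window deliberately contains the R
upstroke. What the features measure is *intra-patient variability*:
for each segment, templates are built from the 80, 20 and 4 beats
surrounding the beat of study (symmetric, always excluding the beat
itself to prevent self-match leakage; neighbors of any class are
eligible). Template construction: provisional reference = element-wise
median of the neighbor segments; each segment aligned to it by maximum
normalized cross-correlation (NCC) over lags within ±10 samples
(±40 ms); segments with alignment NCC below 0.8 are excluded as
outliers (if that leaves fewer than two, the two best are kept); the
retained aligned segments are averaged. Per (segment, template size,
lead): the beat's maximum NCC against the template, the lag attaining
it (positive = beat lags template; ties resolve to the smallest |lag|,
then the negative one), and the template's median per-sample standard
deviation. NCC uses zero-mean, unit-energy normalization of the
overlapping parts, so it is scale- and offset-invariant;
zero-variance segments score 0.

**W4.** The morphology block is computed a second time on the scale-4
detail of the undecimated dyadic wavelet transform with a quadratic
spline prototype — the classic pair with low-pass taps proportional to
[1,3,3,1]/8 and high-pass [2,-2], cascaded in the a trous scheme
(translation kept at the input rate, so the transform is
shift-equivariant and windows can be cut exactly as on the raw ECG).
At 250 Hz the scale-4 band peaks below 16 Hz, where P/QRS energy
concentrates. The cascade group delay is 14.5 samples; we compensate
the integer part (14) — the residual half sample is irrelevant to
NCC-based features. Published variants of this filter bank differ by
per-scale gain factors; any positive gain cancels in the NCC
normalization, so the taps are used with unit gain.

**Preprocessing.** Resample to 250 Hz (cubic-spline interpolation;
anti-alias low-pass first when downsampling — the supported databases
only ever need upsampling from 128 Hz); subtract the baseline estimate
from two cascaded median filters of 200 and 600 ms (51 and 151 samples
at 250 Hz; edges use shrinking symmetric windows); apply a 35 Hz
linear-phase FIR low-pass. Every stage is length-preserving and
delay-compensated, so R-peak sample indices stay valid; annotation
samples are remapped across resampling with round-half-away-from-zero.

**Classifier and protocol.** Random forest: 500 trees, minimum 10
samples to split, minimum 2 per leaf, maximum depth 20, *no* bootstrap
resampling (each tree sees all training rows; randomness enters only
through per-node feature subsampling with mtry = floor(sqrt(p))).
Prediction averages leaf class-proportion vectors; importance is the
node-weighted gini decrease, normalized per tree. Cross-validation is
patient-wise: patients are assigned to folds by a greedy
longest-processing-time heuristic on their S counts (ties shuffled by
seed, then fewest-patients, then lowest fold id), so fold S proportions
stay similar without ever splitting a patient. Per fold, training
beats are capped at 10,000 per class (uniform subsample, seeded), and
the full feature conditioning — clip, impute, variance prune,
dependence prune, z-score — is fitted on the training folds only.
Metrics are reported beat-wise (pooled over folds, each beat one
sample) and patient-wise (median and IQR across patients; a patient
with no true beats of a class is excluded from that class's summary).

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `target_fs` | 250 | Hz | common rate of the supported databases; all window/sample calibrations assume it |
| `median_ms` | 200, 600 | ms | short window flattens QRS, long one smooths the remainder into a wander estimate |
| `lp_cutoff` / `lp_stop` / `lp_atten_db` | 35 / 45 / 40 | Hz, dB | removes powerline and high-frequency noise while keeping QRS energy |
| neighborhoods | 80, 20, 4 | beats | long-, mid- and short-term context; the short template catches isolated PACs, the long ones catch bigeminy/trigeminy/runs |
| `max_lag` | 10 | samples | ±40 ms: above fiducial jitter, below inter-beat spacing |
| `ncc_min` | 0.8 | — | outlier exclusion for template construction; only the floor rule (keep best 2) guards tiny neighborhoods |
| clip bounds | 250 / 3428.6 | ms | cardiac refractory period; twice the RR of an extreme 35 bpm bradycardia (the longest post-ectopic pause). dRR bounds ±(RR_max − RR_min), derived symmetrically |
| `var_min` | 0.05 | — | variance pruning threshold, applied before z-scoring (afterwards every variance is 1 and the rule would be vacuous) |
| `corr_max` | 0.95 | — | Pearson dependence pruning; the later feature in canonical order is dropped, deterministically |
| `cap` | 10000 | beats/class | the only class-imbalance handling; no class weights |
| forest | 500 / 10 / 2 / 20 / no bootstrap | — | taken as given from the published hyper-parameter search |

The pipeline order clip → impute → variance prune → dependence prune →
z-score is part of the contract: permuting the pruning steps can change
the kept set.

## Design choices where the design was open

* **FIR design.** Only "35 Hz, equal ripple" is specified upstream. We
  close the band spec as passband edge 35 Hz, stopband edge 45 Hz,
  ≥40 dB attenuation, and realize it as a Kaiser-window linear-phase
  FIR with an even order (integer group delay) and unit DC gain. A
  Parks–McClellan equiripple design would match the textbook wording
  more literally, but no such design routine exists in the offline
  dependency set, and the filter's acceptance-relevant behavior (DC
  within 1%, 5 Hz preserved, 60 Hz attenuated ≥40 dB, zero net delay)
  is met identically; the band spec stays configurable.
* **Resampling** by cubic-spline interpolation rather than a
  rational-factor polyphase bank: the pipeline only upsamples
  (128 → 250 Hz), where spline interpolation reproduces a 5 Hz test
  tone to well under 1%.
* **Binary "multi-labels" reading.** The three-class mode is a single
  multi-class forest (mutually exclusive labels), consistent with
  reporting a 3×3 confusion matrix.
* **Beat-wise pooling.** Beat-wise metrics pool all folds' predictions
  (each beat one sample) rather than averaging per-fold values.
* **Fold balancing** is stated upstream only as an objective ("similar
  S proportion per fold"); the greedy LPT heuristic is our closure and
  is deterministic given the seed.
* **Template context** uses beats of any class, matching "neighboring
  beats" literally; rebuilt per beat (the beat itself never enters its
  own template).
* **Unknown beat symbols** (outside the 12-symbol simplified scheme)
  map to EXCLUDED with a warning instead of erroring, so foreign
  databases degrade gracefully; non-beat annotations are dropped.
* **Seeding.** One master seed is fanned out to every stochastic stage
  (fold tie shuffles, per-class caps, each tree, each synthetic
  patient) through a documented string-hash derivation
  (`derive_seed`), so no stage consumes RNG state meant for another
  and every run is reproducible from the config echo.

## The synthetic world — and what a green test does not establish

The generator (`synth_config`, `generate_record`, `generate_cohort`)
emulates: 2-lead ECG at 250 Hz; normal sinus rhythm with Gaussian RR
noise (default mean 800 ms, sd 40 ms) and respiratory modulation
(30 ms at 0.25 Hz); PACs at rate 0.10 — 25% premature, P wave at half
amplitude, shifted −40 ms and inverted (an ectopic atrial focus),
non-compensatory pause (half the stolen time is returned); ventricular
beats at rate 0.10 — no P wave, main deflection inverted and 2.5×
wide at 1.4× amplitude, inverted T, full compensatory pause (the
couplet spans exactly 2 × mean RR); bigeminy, trigeminy and atrial-run
patterns; additive Gaussian noise (0.02 mV) and sinusoidal baseline
wander (0.1 mV at 0.3 Hz). Beats are sum-of-Gaussians P-QRS-T kernels:
transparent ground truth for every morphology knob, with per-patient
randomization of amplitudes, rates and lead-2 gain in the cohort
generator (plus fixed pattern patients: 14 isolated, 2 bigeminy, 2
trigeminy, 2 atrial-run in the 20-patient cohort).

What it does **not** model: realistic T/QT dynamics, atrial
fibrillation, muscle/electrode artifact, lead dropout, or the
continuum of borderline morphologies found in real Holter data. The
class contrasts are deliberately exaggerated. Consequently the
parameter-recovery criterion (multiclass S and V sensitivity ≥ 0.90
under 2-fold patient-wise CV on 20 synthetic patients) establishes
that the pipeline — features, conditioning, patient-wise protocol,
forest — recovers physiology that is planted in the data; it does not
establish clinical performance on PhysioNet databases, which requires
the (documented, non-tested) replication path.

One derived expectation was corrected during development: because the
"P wave" window [-300, 40] ms contains the shared R upstroke, the NCC
between a PAC kernel's P segment and a normal kernel's P segment stays
high (~0.97) even with a fully inverted P wave — a naive "< 0.8" bound
would require unphysiologically large P amplitudes. The tested
invariant is the meaningful one: generated S beats score systematically
lower P-window NCC than N beats, and V beats lower QRS NCC than both.

## Numerical choices

* NCC tie-breaking visits lags in the order 0, −1, +1, −2, +2, … and
  accepts only improvements beyond 1e−12, so exact ties resolve to the
  smallest |lag|, negative first, independent of float noise.
* Aligned-template samples shifted beyond the overlap are filled with
  the reference value (affects at most `max_lag` edge samples).
* Median-filter edges use shrinking symmetric windows; the wavelet
  cascade uses mirror extension — both affect only samples inside the
  40-beat trim.
* Split thresholds are midpoints between consecutive distinct feature
  values; `x <= threshold` goes left; gini gains must exceed 1e−15 to
  be accepted, keeping tree growth deterministic across platforms (the
  feature subsampler uses raw Mersenne-Twister draws, not
  implementation-defined distributions).
* Degenerate inputs: zero-variance segments get NCC 0; a constant
  feature column that survives to the z-score stage is an error (it
  cannot, by construction — variance pruning runs first); records with
  ≤ 80 beats produce an empty feature matrix with a warning and are
  skipped by the extraction driver.

## Known limitations

* WFDB support covers headers, signal formats 16 and 212 and the MIT
  annotation codec — enough for the targeted databases; multi-file
  records and other formats are not read.
* The 41-vs-42 HRV count ambiguity is left visible (42 emitted).
* Binary-mode patient-wise PPV is noisy on small synthetic cohorts
  (few S beats per patient); beat-wise metrics are the stable summary
  at desk scale.
* Paced beats and lead-quality assessment are out of scope; R-peak
  detection is an input, not a capability.
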