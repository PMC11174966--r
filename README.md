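# ecgph — neonatal ECG morphology and blood pH group analysis

Birth asphyxia leaves a biochemical fingerprint — metabolic acidosis, a
blood pH below 7.20 — that today is monitored by drawing blood for gas
analysis: invasive, painful, and intermittent. Ventricular repolarization
is sensitive to hypoxia, so the ECG's T wave offers a continuous,
noninvasive window on the same physiology. `ecgph` is for researchers in
physiological signal processing and neonatal monitoring who want a tested,
reproducible pipeline from raw bedside ECG plus a table of blood-gas
sampling events to a statistical answer: *which morphological ECG features
differ across pH groups?*

The pipeline extracts 10 s ECG segments adjacent to each blood-gas event,
filters them (0.5 Hz high-pass, 100 Hz low-pass, 50 Hz notch,
Savitzky–Golay), detects QRS complexes with a Pan–Tompkins style detector,
gates out segments with missing cycles, reduces each segment's beats to one
representative cycle by PCA, delineates the T wave (tangent-method T end),
and computes ten features per segment:

> T/QRS, T Amplitude, Tslope, Tslope/T, Tslope/|T|, Tslope/√|T|,
> HR, QT, QTc = QT/√RRAvg (Bazett), RRAvg

Features are compared across **acidosis** (pH < 7.20), **normal**
(7.20–7.45) and **alkalosis** (pH > 7.45) groups with the tie-corrected
Kruskal–Wallis test,

H = [12 / (N(N+1)) · Σᵢ nᵢ (r̄ᵢ − (N+1)/2)²] / [1 − Σ(t³−t)/(N³−N)],

referred to χ²(k−1), followed — when the omnibus test is significant — by
Dunn–Šidák pairwise comparisons with simultaneous intervals
(estimate ± z₁₋α*/2·SE, α* = 1 − (1−α)^(1/m)), whose disjointness is the
significance display.

Clinical neonatal datasets of this kind are private, so the package ships a
synthetic cohort generator (`generate_cohort()`): Gaussian-sum beats with
closed-form T amplitude, T slope and QT ground truth, three pH groups with
configurable sizes (default 9/83/16) and effect multipliers, and the three
classic artifact types (baseline wander, 50 Hz interference, EMG noise).
Every processing stage is validated by parameter recovery against that
ground truth.

## Worked example

```r
library(ecgph)

# a cohort in which acidotic neonates have half the T amplitude
effects <- list(t_amp = c(0.5, 1, 1), tslope = c(0.5, 1, 1), qt = c(1, 1, 1))
cfg <- pipeline_config(cohort = cohort_config(effects = effects), seed = 42)
res <- run_pipeline(cfg)
print(res)
```

```
<ecg_ph_analysis: 108 records, 108 segments (108 accepted, 0 rejected)>
ECG feature group comparison (n = 108; acidosis = 9, normal = 83, alkalosis = 16; alpha = 0.05)

Kruskal-Wallis omnibus tests:
  T/QRS           chi-square =  25.01  p = 0.0000 *
  T Amplitude     chi-square =  24.86  p = 0.0000 *
  Tslope          chi-square =  23.61  p = 0.0000 *
  Tslope/T        chi-square =   0.46  p = 0.7931
  Tslope/|T|      chi-square =   0.46  p = 0.7931
  Tslope/sqrt|T|  chi-square =  18.27  p = 0.0001 *
  HR              chi-square =   4.79  p = 0.0911
  QT              chi-square =   0.71  p = 0.7013
  QTc             chi-square =   2.34  p = 0.3108
  RRAvg           chi-square =   4.79  p = 0.0911

Significant Dunn-Sidak pairs (simultaneous intervals):
  T/QRS           acidosis vs normal:  -52.182 [ -78.428,  -25.937]  p_adj = 0.0000
  T/QRS           acidosis vs alkalosis:  -60.431 [ -91.591,  -29.270]  p_adj = 0.0000
  T Amplitude     acidosis vs normal:  -52.730 [ -78.975,  -26.484]  p_adj = 0.0000
  T Amplitude     acidosis vs alkalosis:  -59.090 [ -90.251,  -27.929]  p_adj = 0.0000
  Tslope          acidosis vs normal:   52.202 [  25.957,   78.448]  p_adj = 0.0000
  Tslope          acidosis vs alkalosis:   55.826 [  24.665,   86.987]  p_adj = 0.0001
  Tslope/sqrt|T|  acidosis vs normal:   46.560 [  20.314,   72.805]  p_adj = 0.0001
  Tslope/sqrt|T|  acidosis vs alkalosis:   46.847 [  15.686,   78.008]  p_adj = 0.0010
```

Reading the output: the halved T amplitude in the acidosis group is picked
up by T Amplitude itself and by every feature that scales with it (T/QRS,
Tslope, Tslope/√|T|) — the acidosis mean rank sits 45–60 rank positions
away from the other groups and each simultaneous interval excludes 0.
Pure shape and timing features (Tslope/T, QT, QTc, HR) stay correctly
non-significant, because the simulated effect did not touch T width, QT or
heart rate. With all multipliers at 1 (a null cohort) no feature is
expected to be flagged beyond the 5% false-positive rate.

Per-segment measurements are in `res$features` (one row per accepted
segment, TSV written by `write_features()`), the statistics in
`res$comparison` (JSON via `write_report()`), and the segment accounting in
`res$manifest`.

A thin command-line interface over the same functions is installed at
`inst/cli/ecgph.R` (subcommands `simulate`, `extract-features`, `analyze`,
`run-all`, `version`).

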