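# crmaneuver

Analysis of combined cardiorespiratory recordings acquired during a
**paced-breathing maneuver**: three consecutive 2-minute epochs — spontaneous
breathing (SR), controlled breathing at 6 min⁻¹ (0.1 Hz; 5 s in / 5 s out,
"CR6") and at 15 min⁻¹ (0.25 Hz; 2 s in / 2 s out, "CR15") — with
simultaneous beat annotations (RR interval, beat-to-beat finger pressure by
the Penáz volume-clamp method, optional QT/ST and stroke-volume fields) and a
respiratory airflow channel.

The maneuver probes cardiorespiratory regulation from both ends: breathing at
0.1 Hz drives the system at the resonance of the arterial baroreflex loop and
maximizes respiratory sinus arrhythmia (RSA), while 15 min⁻¹ breathing is a
mild hyperventilation stimulus. How strongly each index moves between epochs
(its **increment** δ = CR − SR), compared against reference quartile limits,
classifies a subject's reactivity as *reduced*, *expected* or *increased* —
of interest in sports medicine for detecting overreaching and dysregulation
without exercise testing.

## What it computes

Per epoch, the full index bundle of the field's standard tables:

* **Breathing pattern** — T_I, T_E, V_T, V_T/T_I, V_T/T_E, T_I/T_TOT,
  breathing rate, minute ventilation V, and oxygen uptake as a fixed fraction
  of V (default 0.046).
* **Spectra** (one engine for all series) — Welch band powers TP/VLF/LF/HF
  with the 0.04 / 0.15 / 0.4 Hz edges, normalized units
  LFn = LF/(TP−VLF)×100, HFn, LF/HF, and the centralization index
  IC = (LF+VLF)/HF, applied to RR (ms²), SBP and DBP (mmHg²), and a
  ventilation waveform whose per-breath mean is V_T/T_E ((L·min⁻¹)²).
* **Baroreflex α** — BR_LF = √(LF_RR/LF_SBP), BR_HF = √(HF_RR/HF_SBP), in
  ms·mmHg⁻¹.
* **Time-domain & geometric HRV** — SDANN (SD of all NN in the epoch), RMSSD,
  pNN50; Baevsky histogram indices Mo, AMo, MxDMn and the derived SI
  (= AMo/(2·Mo·MxDMn)), ABI, SRAI, ARI.
* **ECG summary** — HR, Bazett-corrected QTc (per beat, then averaged), ST.
* **Hemodynamics** — EDV/ESV/SV annotations summarized; CO = SV·HR/1000,
  CI = CO/BSA, stroke index, MAP = DBP + PP/3, GPVR = 80·MAP/CO; BSA by
  DuBois (default) or Mosteller.
* **Synchronization** — Hildebrandt index HI = HR/breathing rate and the
  volume synchronization index VSI = CO/V.
* **Increments and classification** — δ(SR→CR6), δ(SR→CR15) for every scalar
  index, classified against shipped reference Q1/Q3 limits (from a cohort of
  183 healthy male athletes); cohort summaries as median (Q1; Q3) with an
  exact Wilcoxon matched-pairs signed-rank test.

Records with extrasystoles (11-beat running-median rule, 20% deviation) or
non-sinus rhythm are excluded before cohort analysis, mirroring the
maneuver's study design.

A **synthetic cohort generator** (integral pulse frequency modulation with
respiratory, Mayer-wave and beat-lagged baroreflex coupling, half-sine
airflow lobes, ectopic injection, between-subject dispersion) provides ground
truth for every stage, so the whole pipeline is testable with no recording
hardware.

## Worked example

```r
library(crmaneuver)
out <- generate_subject(sim_config(seed = 42), subject_id = "athlete-042")
res <- analyze_subject(out$record)
round(t(res$flat[, c("HR", "RR", "V", "VO2", "LF_Rn", "HF_Rn", "HI")]), 3)
```

```
          SR    CR6   CR15
HR    68.131 71.997 77.988
RR    14.042  6.000 15.000
V      8.061 10.206 13.137
VO2    0.371  0.469  0.604
LF_Rn  1.752 99.978  0.473
HF_Rn 98.248  0.022 99.527
HI     4.852 11.999  5.199
```

Reading this: breathing locks onto the paced rates (14.0 → 6.0 → 15.0
min⁻¹); minute ventilation and uptake rise across the maneuver; the
ventilation spectrum is resonant with the paced rate — almost all normalized
power sits in LF at 0.1 Hz breathing and in HF at 0.25 Hz; heart rate rises
and the Hildebrandt index roughly doubles at CR6 (≈12 heartbeats per breath).

```r
inc <- res$increments
inc[inc$index %in% c("HR", "HI"), ]
#>  index delta_cr6 delta_cr15 class_cr6 class_cr15
#>     HR  3.866015  9.8566417  expected   expected
#>     HI  7.147590  0.3472762  expected   expected
```

Both increments fall inside the reference Q1–Q3 bands: an *expected*
reactivity. Values below Q1 classify *reduced*, above Q3 *increased*.

## Command line

```sh
Rscript inst/exec/crmaneuver simulate --n 20 --seed 1 --out cohort/
Rscript inst/exec/crmaneuver cohort cohort/ --out cohort/summary
Rscript inst/exec/crmaneuver analyze cohort/sim-001
Rscript inst/exec/crmaneuver limits export-default
```

`cohort` writes per-epoch median (Q1; Q3) tables, Wilcoxon tests for the
three epoch contrasts, the exclusion report, and the cohort's own empirical
increment limits in the same format as the shipped reference table
(`inst/extdata/reference_limits.csv`).

## Record format

One directory per subject: `beats.csv`
(`time_s,rr_ms,sbp_mmHg,dbp_mmHg,qt_s,st_nu` + optional
`sv_cm3,edv_cm3,esv_cm3`; empty cell = absent), `flow.txt` (one airflow
sample per line, L·s⁻¹, inhalation positive), `flow.json` (`{"fs_hz": ...}`),
`meta.json` (id, anthropometrics, sinus-rhythm flag, segment windows).
`write_record()` / `read_record()` round-trip this byte-identically.

See `vignettes/maneuver-methods.Rmd` for the model assumptions, parameter
choices, numerical decisions and known limitations.
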