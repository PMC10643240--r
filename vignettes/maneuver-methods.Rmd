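---
title: "Methods: breathing-maneuver analysis and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: breathing-maneuver analysis and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crmaneuver)
```

## The maneuver and its epochs

A record covers three consecutive 2-minute epochs on a common time base:
spontaneous breathing (SR), paced breathing at 6 min⁻¹ (0.1 Hz, 5 s
inhalation / 5 s exhalation; CR6) and at 15 min⁻¹ (0.25 Hz, 2 s / 2 s; CR15).
Epoch windows are half-open `[start, end)` so no beat is counted twice at the
120-s boundaries. An RR interval belongs to an epoch only when **both** of
its bounding beats lie inside the window; the device literature is silent on
boundary beats, and full containment keeps epoch spectra free of
boundary-crossing intervals. This is a convention, not a measurement claim:
at most one interval per boundary is affected.

## Spectral engine

All variability indices come from one engine. Beat-stamped series (RR, SBP,
DBP) are interpolated with a natural cubic spline onto a uniform 4 Hz grid
over `[first, last]` event time — standard beat-series practice; the source
methodology does not state its estimator — then mean- and linear-trend
removed. Power spectral density uses Welch's method: Hann taper, 64-s
segments, 50% overlap, so a 120-s epoch yields two segments (a deliberate
variance/resolution trade-off that still separates the 0.04 and 0.15 Hz band
edges; `crm_config()` exposes segment length, overlap and resampling rate,
and setting the segment to the epoch length gives a plain periodogram).

Band powers integrate the density over half-open bands VLF `(0, 0.04]`,
LF `(0.04, 0.15]`, HF `(0.15, 0.4]` Hz by the rectangle rule (bin sum × Δf).
The rectangle rule, not the trapezoid, is used deliberately: it makes band
additivity exact (VLF + LF + HF = TP for band-limited input) and preserves
Parseval's identity, which the test suite asserts. Derived quantities follow
the conventional definitions: LFn = LF/(TP−VLF)×100, HFn likewise (so
LFn + HFn = 100), LF/HF, and the centralization index IC = (LF+VLF)/HF.

Two caveats are inherited from 2-min epochs and documented rather than
hidden. First, VLF on a 2-min record is unreliable (the lowest resolvable
frequency is ≈ 0.008 Hz and only two or three bins fall below 0.04 Hz); we
integrate from the first positive bin and report it anyway, as the reference
tables do. Second, the baroreflex α is reported as
BR = √(band_RR/band_SBP) in ms·mmHg⁻¹ — the square-root form is the only one
dimensionally consistent with the printed unit; the squareless ratio that
sometimes appears in running text is treated as a typographical shorthand.

## Ventilation variability (VRV)

The ventilation series is nominally the per-breath expiratory mean flow
V_T/T_E (in L·min⁻¹, hence band powers in (L·min⁻¹)²). A subtlety forced a
design decision: a per-breath series is sampled at the breathing rate, so its
Nyquist frequency is *half* the breathing rate — 0.05 Hz at CR6, 0.125 Hz at
CR15 — and no interpolation of it can carry power at the breathing frequency
itself. Yet reference ventilation spectra are dominated by exactly that line
(LF-dominant at 0.1 Hz pacing, HF-dominant at 0.25 Hz pacing and at typical
spontaneous rates ≈ 0.24 Hz). The pipeline therefore analyses a **ventilation
waveform**: within breath *k* of period *T_k* the waveform is
`level_k · (1 − cos(2π(t − t_k)/T_k))`, whose mean over the breath equals
that breath's V_T/T_E. The per-breath V_T/T_E level is the waveform's
envelope — preserving the "dispersion of V_T/T_E" semantics — while the
waveform carries the breathing-frequency line that makes the spectrum
resonant with the paced rate. `ventilation_series()` still returns the plain
per-breath event series for users who want it.

Tidal volume is reported from the inspiratory lobe; the expiratory lobe feeds
the VRV series. Oxygen uptake is modelled as a fixed fraction of minute
ventilation (default 0.046, configurable): a flow-only sensor cannot measure
gas concentrations, and the constant uptake/ventilation ratio across all
three epochs of the reference tables implies exactly this model.

## Breath segmentation

Breath onsets are negative-to-positive zero crossings of the 2 Hz low-pass
filtered flow (zero-phase windowed-sinc FIR), debounced by a ±0.02 L·s⁻¹
hysteresis band. Hysteresis exits are then refined back to the adjacent zero
crossing so phase durations are unbiased; every refinement walk is capped at
0.2 s so that slightly-negative noise in quiescent stretches is never
absorbed into a breath (uncapped walks inflated the final expiration by
whole seconds in noisy records). A record starting mid-inspiration counts
that onset as a breath start; the final breath is closed at the end of the
expiratory run that follows the last inspiration. Candidate breaths shorter
than 0.5 s per phase or below 0.05 L inspired volume are merged into their
predecessor. All thresholds sit in `crm_config()`; the source methodology
never describes its detector, so these are stated package conventions.

## Ectopic exclusion

Beat *i* is flagged when its RR deviates from the median of the 11-beat
window centred on it by more than 20% of that median; flagged beats and the
immediately following interval are excluded from all index computations, and
a record with any flagged beat in any epoch — or annotated non-sinus
rhythm — is excluded from cohort analysis with a structured reason naming the
epoch. The threshold and window are configurable; the defaults are the
package's convention (no algorithm is given in the source methodology).

## Geometric (Baevsky) indices

RR histograms use fixed 50-ms bins anchored at 0 ms; Mo is the centre of the
tallest bin (ties broken toward shorter RR — stated so results are
reproducible), AMo its percentage share, MxDMn the RR range. Derived:
SI = AMo/(2·Mo·MxDMn), ABI = AMo/MxDMn, SRAI = AMo/Mo, ARI = 1/(Mo·MxDMn).
Absolute conventional-unit scaling of device implementations is not
reproducible from published material; interpretation should rest on
increments and monotone behaviour (SI rises as dispersion narrows — a tested
property), not absolute c.u. agreement. "SDANN" follows the source's own
definition text — the SD of all NN intervals in the 2-min epoch (true
5-min-sub-mean SDANN is impossible here); `sdnn` is returned as an alias.

## Hemodynamics and synchronization

SV/EDV/ESV enter as per-beat record annotations (from the simulator or any
external estimator — reconstructing a device's proprietary two-phase PQRST
method is out of scope). CO = SV·HR/1000, CI = CO/BSA, stroke index SV/BSA,
MAP = DBP + PP/3 (the conventional formula; none is stated in the source),
GPVR = 80·MAP/CO with 80 ≈ 79.92 as the mmHg·min·dm⁻³ → dyn·s·cm⁻⁵
conversion. BSA defaults to DuBois (0.007184·W^0.425·H^0.725), with
Mosteller as the config alternative. Synchronization: Hildebrandt index
HI = HR/breathing rate; VSI = CO/V. Pulse pressure is averaged per beat;
under the mean summarizer this equals the difference of means (linearity),
but the per-beat definition matters for any non-linear summary and is kept.

## Increments, limits, classification

For every scalar index, δ(CR6) = CR6 − SR and δ(CR15) = CR15 − SR. The
shipped `reference_limits.csv` carries the reference cohort's Q1/Q3 for both
contrasts (183 healthy male athletes; classifying other populations emits a
provenance warning). Classification: δ < Q1 → the low-tail class, δ > Q3 →
high-tail, boundary values inclusive → *expected* (the narrative phrasing is
strict — "less than", "more than" — so the closed interval is the consistent
complement). In the shipped table every low tail is *reduced* and every high
tail *increased*, matching all unambiguous narrative entries; where the
narrative and the printed quartiles disagree numerically, the quartiles win.
Only the Q1/Q3 tier ships: a 1st/99th-percentile "pathology" tier is
mentioned in the source narrative but its values are not printed, so the
config slot exists and ships empty.

Cohort statistics report median (Q1; Q3) per epoch (type-7 quantiles — no
percentile rule is stated in the source) and a Wilcoxon matched-pairs
signed-rank test per contrast: zeros dropped, ties mid-ranked, exact
permutation null up to n = 25 via a rank-polynomial recursion on doubled
ranks (exact even with mid-ranks; verified against full 2^n enumeration),
normal approximation with tie and continuity correction above. A cohort's
empirical increment quartiles are exported in the limits-file format so any
cohort can define its own reference bands.

## The synthetic cohort: what it emulates, and what a green test establishes

Beats come from integral pulse frequency modulation: beats fire when
∫m(t)dt crosses successive integers, with

m(t) = (1/RR₀(t)) · [1 + a_resp·flow_norm(t) + a_lf·sin(2π·0.1t + φ)],

where `flow_norm` is the flow normalized per epoch by its maximum (so
`rsa_gain` and pressure amplitudes read directly in ms and mmHg),
`a_resp = rsa_gain/RR₀`, `a_lf = lf_amp_rr/RR₀`, and RR₀(t) carries a
per-epoch chronotropic scale (defaults 1 / 0.946 / 0.874: heart rate rises
under paced breathing, most under mild hyperventilation, matching the
direction and magnitude of the reference epochs). IPFM is used instead of
phenomenological RR sinusoids so that derived-series spectra contain
realistic harmonics and spectral-recovery tests are honest. SBP/DBP carry a
respiratory oscillation plus an intrinsic 0.1 Hz Mayer wave; the baroreflex
is a beat-lagged linear coupling RRᵢ += G·(pressure-wave deviation at the
previous beat). Two modelling points deserve emphasis:

* the baroreflex input is the modelled pressure **wave**, not the noisy
  measurement — baroreceptors low-pass their input and never see Penáz
  measurement noise; coupling to the noisy channel would add G·σ of white RR
  noise and (at realistic gains) trip the 20% ectopy rule on clean records;
* the independent RR Mayer term (`lf_amp_rr`, 15 ms) is deliberately small:
  most LF RR power is baroreflex-mediated from the pressure Mayer wave, and
  double-counting it would bias α-recovery upward.

Gain recovery by the α-method is therefore approximate by construction
(lagged coupling, intrinsic LF residual, estimator variance); acceptance uses
a ±30% band, and the default world recovers an injected 15 ms·mmHg⁻¹ within
a few percent at cohort-median level.

Flow is built from half-sine lobes with per-phase areas ±V_T; paced programs
have exact timing and log-normal tidal-volume jitter (CV 0.07 — paced
subjects control rate, not volume), spontaneous breathing jitters the breath
*period* log-normally (CV 0.10 around 14.2 min⁻¹; drawing the period rather
than the rate keeps the detected rate 60/mean(T) unbiased). Per-beat QT is
qtc·√(RR s) plus jitter; SV oscillates with respiration around its mean;
EDV = SV + ESV. Ectopics replace a beat's RR with 0.6× its value followed by
a 1.4× compensatory pause (timing-preserving), injected away from record
edges and epoch boundaries; the generator guarantees the flagged set equals
the ground-truth affected set, a coupling contract the tests assert.

Cohorts draw per-subject parameter multipliers once (log-normal, CV 0.08;
Gaussian anthropometrics 73 ± 8 kg, 178 ± 6 cm) and are fully deterministic
given a seed; zero dispersion is defined as a fully homogeneous cohort
(identical records), which is what makes the dispersion-0 identity test
meaningful.

What the generator does **not** emulate: real RSA's frequency-dependent gain
(resonant amplification near 0.1 Hz is only partly captured through the
baroreflex loop), chemoreflex dynamics and hyperventilation gas chemistry,
non-stationarity within epochs, measurement dropouts, and realistic Penáz
drift. At spontaneous rates the effective RSA modulation is attenuated below
the nominal `rsa_gain` (asymmetric lobes, per-epoch normalization,
IPFM integration), so the synthetic SR band balance is more LF-weighted than
typical cohort medians. A green suite therefore establishes that each
operation recovers what the generator injected under the stated world — it
does not establish device-level agreement on absolute index magnitudes for
real athletes.

## Numerical choices and degenerate inputs

Zero-power bands propagate `NA` ("absent") rather than 0 through ratios and
α; missing optional annotations (QT, ST, SV) yield absent outputs, never 0.
The IPFM integral is interpolated on the right-edge time grid (the cumulative
sum over sample *i* covers `(0, i/fs]`), which makes the unmodulated limit
exact: constant m emits RR ≡ RR₀ to machine precision. Welch segments are
mean-removed per segment; series shorter than the segment fall back to a
single full-length segment. Histogram ties break toward shorter RR. The
record serializer formats numbers with `%.10g` so write → read → write is
byte-identical. All randomness flows from explicit seeds; analysis is fully
deterministic.

## Known limitations

Two-minute epochs make VLF indicative at best; absolute Baevsky c.u. scaling
is device-specific; the shipped limits describe young male athletes only;
the ectopy rule is a single running-median filter, not an arrhythmia
classifier; SV/EDV/ESV are taken on trust from the record. The CLI and
readers handle the package's own directory format only — no EDF/WFDB import.
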