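---
title: "Methods: beat-to-beat BPV metrics and their test-retest reliability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: beat-to-beat BPV metrics and their test-retest reliability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beatvar)
```

## Scope and model

`beatvar` quantifies very short-term (beat-to-beat) blood pressure
variability from continuous noninvasive arterial pressure waveforms
sampled at 100 Hz, and assesses the intrasession test-retest reliability
of each metric across two sequential recordings per participant. The
pipeline assumes: a calibrated pressure trace in mmHg; two sessions per
participant, paired by identity; and that within-session beats are
exchangeable draws from a participant-session distribution except for the
temporal structure that the sequence metric (ARV) is designed to capture.

Three stages:

1. **Delineation.** Systolic peaks are local maxima of the trace; the
   diastolic trough is the lowest sample strictly between consecutive
   peaks (earliest index on ties). Automated artifact rules replace manual
   visual screening.
2. **Per-session metrics.** Dispersion (SD, CV, VIM), sequence (ARV) and
   instability (ΔSBP = max − min) metrics on the systolic and diastolic
   beat-amplitude series, plus mean SBP/DBP and interval-based heart rate.
3. **Reliability.** Per metric: paired t-test, ICC(2,1) with F-based 95%
   CI and Munro grading, SEM/SEM%, SRD/SRD%, Pearson r, and Bland–Altman
   bias with 95% limits of agreement; optionally stratified by
   antihypertensive use.

## Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `min_height` | 80 | mmHg | systolic peaks in adults exceed this; rejects diastolic-level maxima |
| `refractory` | 400 | ms | see below |
| `artifact_bounds` | (20, 250) | mmHg | physiologically plausible pressure range |
| `max_abs_slope` | 25 | mmHg/sample | 2500 mmHg/s at 100 Hz: above peak systolic upstroke dP/dt (roughly 1200–2000 mmHg/s, and up to ~10 mmHg/sample for a 65 mmHg pulse pressure rising over ~0.1 s) yet far below spike or step discontinuities |
| `max_excluded_fraction` | 0.10 | — | a session is rejected when more than 10% of samples are artifact-masked |
| `window` | 420 | s | the 7-minute analysis window; longer recordings are truncated to the first window, shorter ones analysed whole with a warning |

**The refractory period and the dicrotic notch.** Published
parameterisations of finger-cuff peak pickers sometimes quote a minimum
peak separation of "40 milliseconds". At 100 Hz that is 4 samples, which
cannot suppress the dicrotic notch — a secondary maximum arriving roughly
300 ms after the systolic peak — and indeed a 40 ms refractory detects
notches as spurious peaks (roughly doubling the count on notched
waveforms), while 400 ms (= 40 *samples* at 100 Hz) yields exactly one
peak per beat. We therefore express the parameter in milliseconds with a
400 ms default and note the printed-unit ambiguity here; both behaviours
are reproducible by setting `refractory = 40` vs `400`, and both are
exercised in the test suite.

**Peak retention.** Candidate maxima are retained greedily in descending
amplitude order subject to the pairwise refractory constraint, with
amplitude ties broken by the earlier index. On arterial pulse shapes this
coincides with prominence ordering (the systolic peak always dominates its
notch) and matches the distance-filter semantics of common peak pickers;
it is fully deterministic.

**Artifact masking.** A sample is flagged when outside `artifact_bounds`
or when its first difference exceeds `max_abs_slope`. Flagged runs are
dilated outward to the nearest flanking local minima of the raw trace
(provisional diastolic troughs, searched in a 0.25 s neighbourhood), so
whole beats are removed and no metric ever mixes partial pulses. Beats on
opposite sides of a masked span are marked as non-consecutive; ARV and
heart-rate intervals never bridge a gap (a bridged pair is not a true
consecutive beat pair). These deterministic rules are a documented
surrogate for interactive visual inspection; the exact criteria a human
rater applies are not recoverable, which is precisely why we prefer
testable rules.

## The VIM fit

VIM removes the correlation between dispersion and mean pressure by
rescaling each unit's SD with a fitted power of its mean:
`VIM_i = SD_i / mean_i^x · M^x`, where `x` minimises
`Σ (SD_i − a·mean_i^x)²` across units and `M` is the grand mean of the
unit means. Numerical choices: Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`, which converges cleanly even on exact zero-residual
data where Gauss–Newton step-halving fails), starting values
`a = median(SD)/median(mean)`, `x = 1`, bounds `x ∈ [−5, 5]`, tolerance
1e-10 on the objective. Non-convergence is a flagged result
(`converged = FALSE`), not an exception; an all-equal-means cohort is
degenerate and errors. With `x = 0` VIM reduces to SD; with `x = 1` it
equals `CV · M / 100`; on a cohort whose SDs follow the power law exactly,
every VIM value equals `a·M^x` and the covariance between VIM and mean is
zero — the defining property.

The exponent is fitted **per session** by default (each session is a
sample in its own right); a pooled fit across both sessions is available
(`add_vim_metrics(scope = "pooled")`). Published work is typically silent
on this choice, so both are supported and the scope is recorded in the
fit object. The `M^x` multiplier is the only rescaling applied.

## Reliability statistics

With paired vectors \(x_1, x_2\) over \(n\) participants and differences
\(d = x_1 - x_2\):

- **Paired t**: `t = mean(d)/(sd(d)/√n)`, two-sided p on `n − 1` df. If
  every difference is zero the test is degenerate and `t = 0, p = 1` by
  convention; zero variance with nonzero mean yields a flagged infinite t.
- **ICC(2,1)**: two-way random effects, absolute agreement, single
  measures, `(MS_R − MS_E)/(MS_R + MS_E + (2/n)(MS_C − MS_E))` from the
  two-way ANOVA of the n×2 table, with the F-based (McGraw–Wong) 95% CI.
  This is the standard form for test-retest with a fixed device: session
  is a random effect and systematic session shifts count against
  agreement. Consistency ICC(3,1) and one-way ICC(1,1) are available via
  `icc_absolute(form = ...)` and the form is recorded in output metadata.
  Zero total variance gives an `undefined` flagged result.
- **Munro bands**: ≥ .90 excellent, .70–.89 good, .50–.69 moderate,
  < .50 low (left-closed at each boundary, so .90 grades excellent).
- **SEM** is the SD of the paired differences divided by `√n`; **SRD** is
  `√2 · SEM` by default. The conventional 95% smallest real difference
  `1.96·√2·SEM` is available via `srd_factor = "conventional"`; the `√2`
  default matches the arithmetic used in the published reference table
  bundled under `inst/extdata/` (e.g. SEM .19 → SRD .27), and the choice
  is recorded in the output. SEM% and SRD% divide by the grand mean of
  both session means, computed from unrounded intermediates.
- **Bland–Altman**: bias `mean(x2 − x1)` and limits `bias ± 1.96·sd(d)`.

Report tables round to 2 decimals (round-half-even) at serialization only;
all internal values are unrounded. Reliability rows appear in a fixed
canonical order (HR, mean SBP, SBP SD/CV/VIM/ARV, ΔSBP, mean DBP, DBP
SD/CV/VIM/ARV). Strata with fewer than 3 complete pairs yield a flagged
row rather than an error; participants missing a session are dropped
pairwise per metric.

## The synthetic-data generator

The generator is first-class, tested code: it defines the conditions under
which the pipeline is validated. Per-beat systolic amplitude is

\[ SBP_k = \mu + o + A_{lf}\sin(2\pi f_{lf} t_k)
        + A_{r}\sin(2\pi f_{r} t_k) + e_k, \]

with subject offset \(o\), a 0.1 Hz low-frequency (Mayer-wave) and a
0.25 Hz respiratory oscillation, and AR(1) innovations \(e_k\)
(`innovation_sd`, `ar_coefficient`; white noise at 0, stationary start).
Diastolic amplitudes follow the same model around `dbp_mean` with an
independent innovation stream and shared oscillations. The long-run SBP
standard deviation has the closed form
\(\sqrt{\sigma^2/(1-\phi^2) + A_{lf}^2/2 + A_r^2/2}\), and the ARV of an
i.i.d. Gaussian series with SD σ converges to \(2\sigma/\sqrt{\pi}\); both
are asserted in the tests. The AR(1)-plus-oscillation decomposition lets
tests separate slow dispersion-driving variance from the successive-
difference variance that ARV isolates.

Each beat is rendered as a stylized four-segment pulse (cosine systolic
decay, dicrotic bump of relative height `notch_depth` centred 30% of the
beat interval after the peak, diastolic runoff reaching the trough at 90%
of the interval, rapid upstroke), sampled at 100 Hz. The rendered maximum
of each beat matches its true SBP, and the inter-peak minimum its true
DBP, within 0.5 mmHg. Motion artifacts are Poisson-placed trapezoidal
excursions (0.5–3 s, 5% ramps) with ground-truth extents returned for
mask validation; their spectral content is schematic, as no published
artifact model is available for these devices.

Cohorts exist at two levels. **Metric-level** cohorts realise the
two-session variance model directly (subject effect with SD
`between_sd`, session noise with SD `within_sd`, so the true ICC is
`between²/(between² + within²)`, with optional per-stratum overrides) and
drive the estimator-recovery tests. **Waveform-level** cohorts run the
full render → detect → metrics path and drive the round-trip tests. All
draws flow from explicit integer seeds; the same seed gives bit-identical
output, and the caller's RNG state is never disturbed.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: finger-cuff calibration drift,
baroreflex feedback and other closed-loop dynamics, heteroscedastic or
non-Gaussian beat distributions, realistic artifact spectra, and
waveform-morphology pathology. Validation here shows the *estimators and
pipeline* are correct under the stated statistical model, not that the
model captures every property of clinical recordings.

## Problem sizes

The validation suite uses sizes chosen to make Monte-Carlo error small
relative to the tolerances asserted: ICC recovery uses 200 replicates of
n = 111 paired cohorts over true ICCs {.5, .7, .87, .95}; paired-t
calibration uses 1000 null replicates at n = 30; closed-form ARV uses
10⁵ beats; round-trip delineation uses full 420 s (7-minute) waveforms;
the quality-control accounting fixture uses a 121-session batch with 60 s
windows and 10 sessions corrupted beyond the 10% rule.

## Known limitations

- Heart rate is derived from inter-peak intervals; device-channel HR, if
  available, may differ.
- The ICC model actually used in any given published table is rarely
  stated; ICC(2,1) is our default and alternatives are one flag away, but
  printed coefficients from other software may not be exactly
  reproducible without the raw data.
- Frequency-domain, time-weighted and circadian (dipping/surge) BPV
  indices are out of scope, as are pulse-wave-analysis features
  (augmentation index, dP/dt) and device calibration.
- `accepted = FALSE` is a QC verdict, not an error; downstream cohort
  functions drop rejected sessions and report the accounting, and a run
  aborts only when the rejected fraction exceeds `max_reject_fraction`.
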