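---
title: "Automatic quantification of REM sleep without atonia: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic quantification of REM sleep without atonia: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rwascore)
```

## The problem

REM sleep behavior disorder (RBD) is a parasomnia in which the muscle atonia
that normally accompanies REM sleep is lost, so patients enact their dreams.
Because isolated RBD is a prodromal stage of the α-synucleinopathies,
documenting *REM sleep without atonia* (RWA) on polysomnography matters well
beyond sleep medicine. The reference method is visual scoring of the
submentalis (chin) EMG, which is slow and requires trained scorers; automatic
quantification makes RWA screening fast and reproducible at the cost of some
accuracy.

`rwascore` implements an automatic RWA quantifier of the adaptive-baseline,
threshold-detector family, a rule-based emulation of visual tonic/phasic/any
scoring to compare it against, the statistics used to validate such methods
(ROC with DeLong intervals and paired curve comparison, ANOVA with
Bonferroni post-hoc tests, Fisher's exact test, correlation, simple
regression), and a synthetic chin-EMG/cohort generator so the entire pipeline
is testable without patient data.

## The automatic RWA algorithm

The detector runs on the chin EMG in five steps.

1. **Conditioning.** The signal is resampled to a canonical 256 Hz and
   band-pass filtered 10–100 Hz (4th-order Butterworth, zero-phase) with a
   50 Hz notch — standard chin-EMG practice. At 256 Hz the 51-sample window
   below spans ≈ 0.2 s, a physiologically sensible envelope scale.
2. **Amplitude curve (AC).** The envelope is the peak-to-peak range
   (max − min) of the filtered EMG in a sliding, centered 51-sample window,
   truncated at the signal edges. The range is parameter-free and tracks
   burst envelopes faithfully; an RMS variant can be substituted via the
   module's internal machinery if a smoother envelope is preferred.
3. **Adaptive baseline.** The baseline is the 5th percentile of the AC over
   a centered 30-s moving window, clamped from below at 0.5 µV and from
   above at twice the whole-recording 5th percentile of the AC. A low
   percentile over a moving window tracks the atonia floor while ignoring
   bursts and lets the baseline adapt to slow drift across the night (for
   example medication wearing off); the floor prevents zero thresholds on
   idealized noise-free signals.
4. **Motor activity events (MAE).** A sample is supra-threshold when the AC
   strictly exceeds the motor activity detection threshold (MADT) of 4 ×
   baseline. Maximal supra-threshold runs are merged when separated by less
   than the inter-event interval (IEI) of 0.5 s, and merged events shorter
   than 0.3 s are dropped. No artifact/arousal exclusions are applied; the
   configuration retains an `exclusions` hook. Merging precedes the duration
   filter, so two 0.2-s bursts 0.3 s apart survive as one 0.7-s event — the
   IEI is what defines event unity.
5. **Mini-epoch scoring.** Each 30-s staging epoch is tiled by ten 3-s
   mini-epochs inheriting its stage. A mini-epoch is positive when events
   occupy *strictly more than* 50% of it. The **Automatic RWA score** is the
   positive fraction of REM mini-epochs: 0 is complete atonia, 1 complete
   absence of atonia. Per-stage metrics (REM, S1, S2, S3, NREM = S1+S2+S3)
   report the percentage of positive mini-epochs, the summed event time
   within the stage, and that time as a percentage of stage time.

### Why the baseline is capped

A purely local moving-window percentile has a failure mode that matters
clinically: when sustained muscle activity fills the whole 30-s window (a
fully tonic REM period), the 5th percentile rises to the activity's own
level, the threshold of 4 × baseline climbs above the activity, and the
detector goes blind exactly where atonia loss is most severe. The package
therefore clamps the moving baseline at `baseline_cap_ratio` (default 2)
times the whole-recording 5th percentile of the AC — a global atonia
reference in the spirit of atonia-index methods. Local adaptation survives up
to a doubling of the floor, which is ample for overnight drift, while
sustained activity can no longer drag the threshold up to itself. Setting
`baseline_cap_ratio = Inf` recovers the purely local estimator.

### Numerical choices

- Intervals are half-open `[start, end)` seconds from recording start;
  epoch *k* (1-based) covers `[30(k−1), 30k)`. Sample *i* (0-based) covers
  `[i/rate, (i+1)/rate)`.
- The moving percentile is evaluated every 0.25 s (`baseline_stride_s`) and
  linearly interpolated between evaluation points; the percentile is R's
  type-7 sample quantile. Setting the stride to one sample period gives the
  exact per-sample estimator (the tests compare that case against a
  brute-force oracle).
- AC edge handling truncates the window rather than padding; this affects
  less than 0.1 s at each signal edge.
- Occupancy is compared with a strict `>`, so an event covering exactly half
  a mini-epoch does not make it positive.
- Youden-cut ties are broken toward higher specificity.

## Visual scoring emulation

Human RWA scoring distinguishes *tonic* activity (sustained elevated tone
over more than half of a 30-s REM epoch), *phasic* bursts (0.1–5 s
excursions above twice the background) and *any* (their union), in the
SINBAR tradition. The package emulates these rules, not any individual human
scorer: phasic and any are scored on 3-s mini-epochs and tonic on 30-s
epochs, following the scoring standard even though validation reports often
quote all three per 30-s epoch.

The emulation compares a rolling-RMS envelope of the conditioned EMG against
`amp_ratio` (default 2) times a background level, where the background is the
5th percentile of that envelope over a 30-s window with the same global cap
as the detector baseline. RMS rather than peak-to-peak is deliberate: the
rolling range of Gaussian atonia noise has a heavy upper tail and brushes a
2× threshold often enough to fabricate phasic bursts out of noise ripple,
which a human would never score; the RMS envelope of quiet atonia
essentially never crosses 2× its own background, so an atonia-only recording
scores 0 on all three parameters, as it must. Supra-threshold runs of
0.1–5 s qualify as phasic; runs of at least 0.1 s of any length qualify for
"any" (so a 6-s elevation counts toward any and tonic but not phasic), and a
REM 30-s epoch is tonic when runs cover more than half of it.

## The synthetic generator

`generate_signal()` emulates a night of chin EMG: a band-limited (10–100 Hz)
Gaussian atonia floor at a configurable RMS (default 2 µV), with phasic
bursts and tonic segments that *multiply* the local envelope (motor activity
scales the interference pattern; this keeps the ratio-based detector in its
design regime), with 20-ms raised-cosine ramps. The default hypnogram layout
is W(10) → S1(5) → S2(30) → S3(20) → REM(20) minutes, repeated; tests use a
REM-dense W(2)/S2(8)/REM(20) layout to keep recordings short.

When `target_occupancy` is set, the generator plants bursts that fully cover
exactly `round(target × #REM minis)` REM mini-epochs and no others, giving
an exact ground truth for the Automatic RWA score. Planting is stratified
across REM epochs so that every 30-s epoch keeps at least one uncovered
mini-epoch whenever the target allows — this keeps the moving-window
baseline anchored on atonia even at 90% occupancy. Planted bursts span whole
mini-epochs, so the "more than 50%" rule is unambiguous; envelope smearing
by the 0.2-s AC window adds at most ≈ 0.1 s at each event edge, an occupancy
of ≈ 0.03 on neighbouring mini-epochs — far from the 0.5 decision boundary.

`generate_cohort()` draws subject records from per-group truncated-normal
marginals (RWA percentages truncated to [0, 100], the automatic score to
[0, 1], indices to non-negative values), by default at the group means, SDs
and sizes of the published validation cohort (11 healthy controls, 24 PD
without RBD, 45 iRBD, 46 PD with RBD). Variables are independent unless a
Gaussian-copula correlation between the automatic score and imaging values
is requested. Reported checks compare empirical means against the analytic
truncated-normal mean, since truncation shifts strongly skewed variables.

What the generator does *not* emulate: ECG and snore artifacts, respiratory
event coupling, arousals, scorer disagreement, or realistic stage
transitions. Passing closure tests on synthetic data therefore demonstrates
the algorithm's internal correctness (detection, merging, scoring,
statistics), not clinical performance on real, artifact-laden recordings.

## Statistics layer

The AUC is computed from midranks (the normalized Mann–Whitney statistic,
ties counted ½), so it agrees exactly with pair counting; standard error and
95% CI use DeLong's method, and paired curve comparisons use DeLong's test
for correlated ROC curves (via pROC). Identical score vectors are a
degenerate comparison (zero variance of the AUC difference) and return
z = 0, p = 1. Two cut points are reported per curve: the Youden-optimal one
and the maximum sensitivity at specificity 1, since visual RWA cut-offs are
usually quoted at perfect specificity. Group pooling into RBD vs non-RBD
reproduces the published workflow: it is accepted when Bonferroni post-hoc
tests find no within-pair differences (α = 0.05) and logged on the returned
object. Confidence intervals of published tables may differ slightly from
DeLong CIs when the original method is unstated; this is documented, not
reconciled. Correlation families are Bonferroni-corrected over all
correlations computed in one call.

## Problem sizes used in the test suite

Closure and recovery tests run on 15–30-minute REM-dense recordings
(100–400 REM mini-epochs); the occupancy sweep covers targets 0.1–0.9 with
20 seeds each; detector-oracle equivalence uses 100 random 60-s signals on a
64 Hz grid; cohort checks run 100 replicates at the published group sizes
(91 RBD vs 35 non-RBD) and large-sample marginal checks at n = 4000 per
group. These sizes were chosen so the full suite exercises every code path
at tight tolerances while remaining quick to run on a laptop.

## Known limitations

- The EDF layer is a minimal reader/writer (16-bit EDF/EDF+C, one-second
  records for signals, TAL parsing for annotations); it does not handle
  discontinuous (EDF+D) files or non-EDF montages.
- The detector's constants beyond the published factor set (window length,
  baseline percentile, floor, cap, stride) are design choices exposed in
  `detection_config()`; on real data they may warrant tuning.
- The visual emulation approximates scoring *rules*; agreement with human
  scorers on real recordings is out of scope here.
- Cohort synthesis draws marginals per variable; apart from the optional
  copula between the automatic score and imaging, the joint structure of
  real cohorts (e.g. correlated visual and automatic scores within subject)
  is not reproduced, which is why cohort-level checks are directional rather
  than numerical reproductions.
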