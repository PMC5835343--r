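---
title: "Simulating and analysing ERPs from a probabilistic gambling task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing ERPs from a probabilistic gambling task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gamblerp)
```

## The task and its behavioral endpoints

`gamblerp` simulates and analyses a two-group study built around a modified
Gneezy–Potters probabilistic gambling task (PGT). On every trial the player
is endowed with 20 points and stakes one of {0, 4, 8, 12, 16, 20}. With
probability 1/3 the stake is multiplied by 4 and added to the unstaked
remainder; with probability 2/3 the stake is lost. Staking 8 therefore
leaves 12 points on a loss and 44 on a win, and the expected points held
after staking $x$ are $20 + x(4 \cdot \tfrac13 - 1) = 20 + x/3$ — the
lottery has a positive edge, so the behavioral interest is in *how much*
risk a player takes, not whether gambling pays.

A session is 10 alternating blocks of 16 trials. In high-frequency feedback
(HF) blocks the outcome is displayed 4 s after the choice; in low-frequency
(LF) blocks it is withheld (the running total still appears every four
trials). Two events delimit each trial: the self-paced trial onset `S`
(spacebar press) and the gamble selection `I` (mouse click); their lag is
the response time (RT).

Behavioral endpoints (`behavior_metrics` functions):

* **Total gains** `TotG`, and per-condition `TG(HF)`, `TG(LF)`: the sum of
  points held after each trial. Gains are computed over all trials by
  default — points are earned whether or not a trial's RT survives
  screening; RT-based endpoints use the screened set. (Whether the original
  analysis excluded screened trials from the gain sums is not stated; this
  default is configurable via `gains_on`.)
* **Risk index** `RI = (HR - LR)/(HR + LR)`, where `HR` is the fraction of
  trials staking 12/16/20 and `LR` the fraction staking 0/4/8; `RI` ranges
  from −1 (risk-averse) to +1 (risk-seeking), with per-condition variants
  `RI(HF)`, `RI(LF)`.
* **RT screening**: trials with RT < 250 ms or > 10 s are discarded by
  rule; surviving trials are then scored by a Local Outlier Factor on
  log(RT) (`k = min(20, n-1)`, threshold 1.5) and high-scoring trials are
  discarded as outliers. LOF parameters are conventional defaults: the
  method is cited without parameters in the source analysis, so both are
  configurable. LOF is implemented in-package (one-dimensional case);
  no installed package provides it.

## The synthetic participant

`agent_profile()` draws stakes from a per-condition categorical
distribution and RTs from a per-condition log-normal truncated to
(0, 20 s]. The log-normal is the natural minimal RT model: strictly
positive and right-skewed. Its median (`rt_location_ms`) is set to the
group/condition medians reported for the study populations (controls
1083/1032 ms, ADHD 1544/1274 ms for HF/LF); only medians and
across-participant means were reported, so a single within-session
dispersion (`sdlog = 0.45`, a typical RT coefficient of variation) is used
for every cell. Stake preferences default to near-uniform, with the ADHD
profile tilted mildly toward high stakes — matching the *sign* of the
reported group difference in risk indices, which was itself not
significant.

Randomness is organized as one stream per participant, seeded by
`participant_seed(master_seed, participant_id)`, so any participant can be
re-simulated independently of simulation order. Block order (HF first) is
configurable; the original counterbalancing is not stated.

## The synthetic EEG

Each of the eight planted waves is a Gaussian bump
(`component_template()`): `width_ms` is its full width at half maximum,
amplitude is a per-electrode magnitude (µV) signed by polarity, and the
per-trial latency adds Gaussian jitter shared across electrodes (one
underlying source per component). Latencies of the trial-onset and
post-choice N2/P3a/P3b are calibrated, per group × condition × ROI, to the
study's reported medians; C1 (70 ms, posterior), N500 (490 ms after `S`,
frontal), the N400-like wave (490 ms after `I`, central), the LPP (850 ms
after `I`, centroparietal) and the premotor build-up (−150 ms before `I`)
use the approximate latencies and topographies described for them. No
amplitudes were reported anywhere, so all amplitudes are free generator
parameters with conventional defaults (3–10 µV) and a linear
posterior–frontal taper; consequently only *latency* recovery — never
amplitude — is treated as a validation surface.

Two generator choices deserve emphasis:

* **Kernel widths and jitter.** The calibrated latencies are *peak
  positions*: the generator must plant kernels whose superposition actually
  peaks there. Wide kernels pull each other's peaks together (the N2–P3a
  separation is only ~75 ms), and trial-to-trial jitter widens the average
  by convolution. With FWHM 50/70/100 ms and 20 ms jitter the detected
  medians are biased by up to ~20 ms; the defaults are therefore
  N2 40 / P3a 60 / P3b 80 ms with 10 ms jitter, for which the measured
  superposition bias is below ~2.5 ms and full-pipeline recovery error
  3–8 ms. All are configurable.
* **Noise realism.** The background is 1/f ("pink") Gaussian noise, flat
  below 0.5 Hz (bounding drift) and rolled off above 60 Hz by a 2-pole
  low-pass standing in for the acquisition chain's anti-aliasing filter —
  without that roll-off, the sample-to-sample gradient of pink noise at
  1024 Hz is dominated by near-Nyquist power that no recorded EEG contains.
  Defaults (10 µV RMS background, 8 µV posterior-weighted 10 Hz alpha,
  10 blinks/min at 150 µV frontally weighted, 2 muscle bursts/min, 2 µV
  sensor noise) give clean raw epochs of ~60–90 µV peak-to-peak and an
  epoch retention near 70% under the default rejection rules, matching the
  usable-epoch fractions reported for the real recordings (means 211 and
  239 of 320).

Epoch stacks can be synthesized directly (`synthesize_epochs()`, the fast
path used in validation) or via a continuous recording with annotated
events (`synthesize_recording()`), which round-trips through a plain
matrix + JSON on-disk format (`write_recording()`, little-endian float32,
row = channel). The generator does **not** model volume conduction, a full
64-channel montage, saccade potentials, or any dependence of the EEG on the
gamble actually chosen; passing validation on these data shows the
*pipeline* is correct and calibrated, not that it would be unbiased on any
real recording.

## The ERP pipeline

The preprocessing order is fixed: band-pass filter → epoch → baseline →
reject → average.

* **Filter**: cascade of 2-pole Butterworth high-pass (0.1 Hz) and low-pass
  (30 Hz), applied forward–backward (`signal::filtfilt`) so latencies are
  not shifted; zero-phase application doubles the nominal −12 dB/octave
  slope to −24. The cascade keeps the high-pass numerically
  well-conditioned at 0.1 Hz / 1024 Hz; the channel mean is subtracted
  explicitly because a 0.1 Hz high-pass settles too slowly to cancel DC
  within epoch-length segments.
* **Epochs**: half-open window [−500, +1000) ms around each `S`/`I` marker
  (1536 samples at 1024 Hz), trigger at sample 513 (t = 0); a 160-trial
  session yields 320 epochs per participant.
* **Baseline**: per epoch and channel, the mean over [−500, 0) ms is
  subtracted. (Whether baseline correction preceded artifact screening in
  the original chain is not stated; this order is the default and both
  stages are exposed separately.)
* **Rejection**: automated stand-in for visual screening — an epoch is
  flagged if any channel exceeds 100 µV peak-to-peak or 50 µV/ms
  sample-to-sample gradient, with the violated rule recorded. The original
  interactive ICA-based ocular correction is intentionally not reproduced;
  threshold rejection is parameter-free to audit and errs toward discarding.
* **Average**: pointwise mean per condition; averages from ≤ 20 usable
  epochs are refused (the participant/condition is excluded by rule).

Because filtering and averaging are both linear they commute, so
`erp_from_epochs(..., filter_stage = "average")` filters the per-condition
mean instead of every epoch — tens of times faster and equal to the
per-epoch path up to filter edge effects (equivalence is tested); the only
substantive difference is that rejection then sees unfiltered epochs, which
is also how visual screening of raw data works.

## Component latencies

`detect_peak()` finds, within a component's search window, the extremum of
the polarity-signed waveform among *local* extrema strictly inside the
window — a raw argmax would latch onto slow-slope endpoints (e.g. the CNV
ramp). Ties break to the earliest latency; windows with no interior local
extremum fall back to the flagged window-edge extremum rather than being
dropped. Default windows bracket the nominal latencies with margin: N2
[130, 230] ms (negative), P3a [200, 310] ms (positive), P3b [300, 430] ms
(positive), C1 [50, 110] ms (POz/Pz, trial onset only); the within-waveform
ordering N2 < P3a < P3b is checked and violations flagged. Latencies are
measured on per-participant, per-electrode averages (not ROI-averaged
waveforms; the alternative is one argument away), and ROI pooling
*concatenates* the per-electrode observations of {Fz, FCz, Cz}
(frontocentral) or {CPz, Pz, POz} (centroparietal), summarized by median
and mean ± SEM.

## Differential waveform analysis

For each participant, the feedback-related difference wave is
`HF − LF` pointwise (`difference_wave()`). Per group and electrode,
`group_band()` forms the mean curve with a mean ± SEM envelope
(SEM = sample SD/√n). Group contrast over a time window uses the
integrated band separation

$$s(t) = \max(0, \ell_A(t) - u_B(t)) - \max(0, \ell_B(t) - u_A(t)),$$

the signed gap between the envelopes (zero wherever they overlap),
integrated by the trapezoidal rule — the quantitative version of "do the
shaded areas intersect". The statistic is antisymmetric in the groups and
bounded by the integrated distance between the group means. Significance
comes from a two-sided permutation test that reshuffles group labels across
participants and re-derives both bands per permutation. Note that under a
true null the statistic is only *approximately* zero for finite groups —
two independent SEM bands separate somewhere with positive probability — so
the null behavior is assessed by the permutation p-value, not by exact
zeroness.

The spatial profile (`window_amplitude_profile()`) integrates each
participant's difference curve over a window and reports, per electrode,
the group mean with a seeded percentile-bootstrap 95% CI (default 2000
resamples) and a Wilcoxon signed-rank test against zero. Both readings of
the original analysis (band overlap and signed-rank tests) are provided
because the supplement that would disambiguate them is unavailable; the
per-electrode integrated-amplitude profile is our interpretation of the
"relative density plot". Default integration windows are centered at the
latencies highlighted in the original figures — 80 ms (C1), 260 ms (N2–P3),
490 ms (N500) after `S`; −450 ms, −140 ms, +490 ms (N400-like), +850 ms
(LPP) around `I` — with a ±50 ms half-width (the stripes' widths are not
printed; ±50 ms is comparable to the component widths and configurable per
window). No multiple-testing correction is applied across electrodes ×
windows by default, matching per-site reporting; Holm correction can be
applied downstream on the emitted tables.

## Statistics

`mann_whitney()` and `wilcoxon_signed()` return the U/W statistic, a
tie-corrected normal Z, a two-sided p (exact by enumeration for pooled
n ≤ 12 / n ≤ 10; the enumeration is over group assignments or sign flips
and remains valid under ties), and the effect size `r = |Z|/√N`. In pooled-
electrode comparisons N is the number of pooled observations (the
alternative — participants — is not recoverable from the reported
statistics). `phi_coefficient()`, `cramers_v()` and `cohens_d()` use the
standard definitions; `gaussian_rank_correlation()` is the normal-scores
correlation — the product-moment correlation of `qnorm(rank/(n+1))` — our
reading of the robust index ρ^G. Mixed-effects models are deliberately
*exported, not implemented*: the pipeline writes tidy observation tables
(`build_reports()`) that any standard fitter consumes.

## Validation problem sizes

The shipped checks run, per seed, 14 participants per group (the size of
the smaller usable EEG sample), 160 trials each, at 1024 Hz. The
50-repetition recovery/ordering check uses the frontocentral sites and
trial-onset epochs, where all the calibrated orderings live; a single
full-montage run checks both ROIs. Bootstrap coverage is assessed on 500
synthetic datasets of n = 30 (the percentile bootstrap is a
moderate-to-large-n method). The command-line surface of the package is R
itself plus `scripts/acceptance.R`; the exported functions are the
interface.

## Known limitations

* Latency calibration plants ROI-constant values per component; real
  within-ROI gradients are not modeled.
* Amplitudes, alpha power, artifact rates and RT dispersion are plausible
  conventions, not fitted quantities.
* The permutation and bootstrap procedures treat participants as
  exchangeable units; no hierarchical (trial-level) resampling is provided.
* Questionnaire-based analyses (CAARS/ASRS/HEXACO correlations and the
  associated regressions), ICA ocular correction, CNV quantification,
  source localization and mixed-effects fitting are out of scope by design.
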