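---
title: "Cortical state from widefield calcium imaging: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cortical state from widefield calcium imaging: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortexstate)
```

## The scientific problem

Cortex moves between synchronized states, with strong low-frequency
(roughly <= 10 Hz) fluctuations of population activity, and desynchronized
states in which those fluctuations are suppressed. In head-fixed mice
performing steering-wheel choice tasks, the strength of 3-6 Hz fluctuations
during the enforced pre-stimulus quiescent period predicts whether the
animal will respond at all (Choice versus Miss), more than whether its
response will be accurate. This package implements the analysis machinery
needed to measure that relationship from widefield calcium imaging and
simultaneous electrophysiology, and a synthetic-session generator that makes
every stage of the pipeline testable against known ground truth.

## The compressed representation

A widefield movie reshaped to a pixels-by-time matrix S is stored as a
truncated SVD, S = A Lambda B'. We keep U (the leading spatial components)
and V = Lambda B' (the singular-value-scaled temporal components), so pixel
n's trace is literally f_n(t) = U[n, ] V. Storing V pre-scaled makes the
downstream formulas direct matrix products; the alternative (unit-norm
temporal components) was rejected to keep those expressions literal. The
truncation rank defaults to 500 — sufficient to capture physiological
spatiotemporal dynamics in full-size recordings — and is capped at the
matrix rank. The SVD sign ambiguity is fixed by forcing the
largest-magnitude entry of each spatial component positive. Coordinates are
0-based (row, col) with row-major flattening; all time windows are half-open
`[start, end)` in seconds.

No mean-centering is applied before decomposition (configurable by
subtracting means upstream): band power in the analysis bands excludes DC,
so centering does not change any reported quantity, and leaving the movie
uncentered keeps reconstruction exact.

For wide matrices (frames >> pixels) the truncated decomposition is computed
from the eigendecomposition of the pixels-by-pixels Gram matrix, which is
algebraically identical and much faster; a full SVD is used whenever full
rank is requested so that exactness-oracle comparisons hold to 1e-8.

## Spectral analysis in the compressed domain

The Fourier transform of a pixel trace is fhat_n(w) = sum_i U[n,i]
Vhat_i(w): transforming the k temporal components once gives every pixel's
spectrum. Band power for all pixels is assembled from the k-by-k band
cross-spectral matrix C = sum_w Re(vhat vhat^H), so the per-pixel power is
the quadratic form U C U' — cost O(k^2 bins + pixels k^2), never a per-pixel
FFT, and the pixel-by-time movie is never materialized.

Numerical conventions, each of which matters at the short (0.7-2 s)
quiescent windows this analysis targets:

* **Taper**: rectangular by default, keeping the band sum literal; a Hann
  taper (mean-square normalized) is available by flag.
* **Band edges**: inclusive, `low <= f <= high`. With a 0.7 s window the bin
  spacing is ~1.4 Hz, so edge inclusivity visibly changes which bins count;
  it is fixed and documented rather than left to floating-point accident.
* **No zero padding**: windows too short to place any bin in the band raise
  an error naming the minimum usable window length; quiescent periods are
  too short to analyse below 3 Hz, which is why the state band starts there.
* **Normalization**: one-sided power (not density), `vhat = fft(v)/N` with a
  fold factor of 2 off DC/Nyquist, so the band sum over all bins equals the
  signal's mean square (Parseval). Band sums are therefore comparable across
  equal-length windows; comparisons across unequal windows should use equal
  windows upstream.

Condition maps average per-trial quiescent-window maps; the difference map
is P_diff = 10 log10(P_a / P_b) in dB. Pixels whose time-averaged broadband
power falls below the 20th percentile are masked (in real data this removes
pixels outside the brain); zero-denominator pixels are masked and counted,
never returned infinite.

## Hemodynamic correction

Blood-volume and oxygenation changes contaminate the calcium-dependent
channel, most strongly in the heartbeat band (9-13 Hz). A calcium-
independent channel, acquired on alternate frames, measures the artifact
directly. The correction subtracts a per-pixel multiple of the raw hemo
signal; the multiple is a no-intercept least-squares coefficient estimated
after linear detrending, 0.01 Hz high-pass and 9-13 Hz band-pass filtering
of both channels. Filtering exists only to estimate the multiple; the
subtraction uses the unfiltered hemo signal. Both estimation and subtraction
run in the SVD domain: filters act on V, the per-pixel regressions are
assembled from k-by-k cross-products, and the corrected movie is
refactorized by QR plus a small SVD (rank at most k_cal + k_hemo).

Two open numerical choices were resolved as follows:

* **Filter family**: zero-phase FFT-domain (brick-wall) filters. The band
  edges are specified but no filter family is; an IIR design would need a
  filter-design dependency and phase compensation, while FFT filtering is
  exactly zero-phase, which is what the regression requires.
* **Channel alignment**: the half-frame offset between the interleaved
  channels is compensated by exact bandlimited (FFT phase-ramp)
  interpolation when the grids are uniform, falling back to linear
  interpolation otherwise. Linear interpolation is *not* adequate here even
  though it is the minimal assumption: at 35 Hz per channel it attenuates an
  11 Hz artifact by cos(pi f/fs) ~ 0.55 and would inflate every regression
  gain by ~1.8x. The bandlimited shift is exact for the band the regression
  uses.
* **No intercept** in the per-pixel regression: both signals are detrended
  and high-passed, hence zero-mean by construction.

Pixels whose hemo channel has no heartbeat-band variance get gain 0 and a
degeneracy flag; per-pixel diagnostics report the residual heartbeat-band
power fraction after correction. Sessions recorded without a hemo channel
pass through unchanged, tagged "uncorrected".

## Trials, quiescent windows, and behavioral statistics

Trials are classified as Correct Choice, Incorrect Choice, Miss (stimulus
present), or Correct Reject / False Alarm (zero contrast both sides). With
equal nonzero contrasts reward is random, so correctness follows the
recorded reward. Responses recorded outside the response window are
contradictory: the trial is flagged invalid, excluded, and counted. The
state window is strictly the enforced quiescent period `[quiescent_start,
quiescent_end)`; quiescent periods shorter than 0.7 s are excluded (exactly
0.7 s is included — the exclusion criterion is *less than* 0.7 s).
Post-outcome analyses reuse the same machinery on the following trial's
quiescent window through a trial-lag parameter.

The trial-by-ROI band-power table carries raw power (a.u.^2) for
within-session analyses and power in dB relative to the session mean, which
is the cross-session comparable quantity.

**Percentile curves.** Per session and ROI, the 20/40/60/80% points of the
trial power distribution define five bins (membership `[0,20), [20,40),
[40,60), [60,80), [80,100]`). The bin edges use linear interpolation between
order statistics (R's type-5 quantile, matching the MATLAB `prctile`
convention of the original analysis environment); the alternative literal
reading "percent of maximum power" is a fraction-of-max rule that the
worked arithmetic contradicts, so distribution percentiles are implemented.
Edges are computed on all included trials. Within each bin, %Choice/%Miss
are computed among stimulus trials, %Correct/%Incorrect among
non-equal-contrast Choice trials (equal-contrast trials are rewarded at
random and carry no accuracy information), and %Correct Reject/%False Alarm
among zero-contrast trials. With several sessions, binning is per session
and rates are averaged across sessions.

**Reaction-time residuals.** Reaction time (go cue to response) varies by
stimulus, so the per-contrast-condition mean is subtracted before
correlating with power; zero-variance residuals are signalled as an
undefined correlation, never silently zero.

**Pupil ANCOVA.** Power against a pupil covariate is fit with one shared
slope and per-condition intercepts (parallel lines by construction); the
intercept difference is the condition effect at matched pupil.

**Nested mixed models.** The cross-session condition test fits, by maximum
likelihood, power ~ cond + area with area-specific random effects nested in
genotype, subject within genotype, and session within subject, delegating
the numerics to lme4. The p-value is a likelihood-ratio test (the package
deliberately reports no denominator-df approximation). Random terms whose
grouping factor has a single level are dropped, so a single-session table
collapses exactly to ordinary least squares. Sessions with fewer than 10
trials in a compared condition are excluded. The percentile-response model
is a logistic mixed model, response ~ 1 + percentile + (1 | session);
complete separation is reported with a flag.

## Electrophysiology bridge

MUA is binned at the imaging rate (35 Hz; counts conserve total spikes
exactly) and smoothed with a normalized Gaussian window (SD 25 ms; the
smoothing width is not specified anywhere authoritative, so it is a
configurable default). LFP light artifacts are removed by aligning segments
to the light onsets of one illumination color, subtracting the pre-onset
baseline sample, and subtracting a running median over 500 pulses.

The **Fano factor** is F = var(X)/mean(X) with sample variance (n-1), per
trial. The ensemble over which var and mean are taken per trial is
genuinely ambiguous for a single number per trial; this package tiles each
quiescent window with 1/35 s sub-bins of summed population counts (the same
window used for band power), with a per-trial-count alternative behind a
flag. Zero-mean windows are flagged undefined.

**Coherence** is Welch magnitude-squared coherence (Hann taper, 50%
overlap) — no estimator is specified anywhere authoritative, and this is
the field default. The estimator is bounded in [0,1] and has a bias floor
of ~1/n_segments for independent signals, which the tests verify
analytically. **Cross-frequency power correlation** computes per-window
band powers on 1 Hz bands and Pearson-correlates them across windows for
every frequency pair.

The **spike-prediction filter** regresses MUA on time-lagged compressed
components with an L2 penalty chosen by blocked cross-validation (contiguous
folds: temporally correlated samples must not leak across folds), then
factorizes the coefficient matrix into a pixel-space spatial map and a
temporal kernel.

## Decoding

Stimulus presence is decoded from per-trial population spike-count vectors
in the 50-150 ms post-stimulus window with ridge-penalized logistic
regression (glmnet, as in the original analysis), scored by 5-fold
stratified cross-validation with the penalty chosen by inner CV on a fixed
log-spaced grid. Stratification is not specified anywhere authoritative but
is necessary at the small trial counts the splits produce. Before any
comparison, trial counts are equalized per contrast level by seeded
subsampling of the larger condition; state splits take trials strictly
below/above the median, excluding ties so that "below and above the median"
stays literal. Accuracy is reported (log-loss alongside, since the original
"decoder performance" metric is not pinned down).

## The synthetic world

The generator emulates exactly the structure the analysis assumes, with one
root seed fanned out to named child streams (trials / movie / spikes /
pupil) so components can be regenerated independently and identical seeds
give bit-identical sessions.

* **Task timing** (stated world): 35 Hz per channel, quiescent durations
  uniform 0.5-2 s at the end of a 1-5 s pre-trial baseline, go cue 0.3-0.8 s
  after stimulus onset, response window 1.5-5 s, contrasts {0, 25, 50,
  100}%.
* **Latent state**: a per-trial AR(1) process (lag-1 coefficient 0.7 by
  default — Miss trials cluster in sequences, and per-trial constancy makes
  recovery tests unambiguous), standard normal marginally.
* **State signal**: 3-6 Hz band-limited Gaussian noise (irregular-rhythmic,
  avoiding the spectral-leakage artifacts a pure sinusoid would create),
  filtered through a sharp-rise/slow-decay calcium kernel and then
  amplitude-modulated per trial. Modulating after the kernel filter keeps
  the injected per-trial dB exact instead of smeared across trial
  boundaries by the kernel tail.
* **Outcome coupling and calibration**: Miss probability is logistic in the
  trial state. The per-trial power offset is c * state dB, with c chosen in
  closed form (numerical integration over the state marginal) so that the
  expected Choice - Miss difference equals `band_power_effect_db` exactly.
  When the outcome slope is zero but a nonzero power effect is requested,
  the offset conditions on the outcome directly. The realized per-session
  difference still scatters (~0.6 dB SD at 200 trials) because which trials
  Miss is random; recovery checks therefore average over sessions.
* **Hemodynamics**: a narrowband heartbeat-band (default 11 +- 1 Hz)
  artifact enters the calcium channel through a smooth per-pixel gain map
  and the hemo channel bare (no calcium bleed-through — sufficient to test
  the correction's contract). Channels are sampled on interleaved grids
  offset by half a frame period.
* **Spikes**: an inhomogeneous Poisson population whose rate follows the
  VIS-pixel fluorescence low-passed below 8 Hz (negative rates clipped and
  counted), plus contrast-tuned units firing 50-150 ms post-stimulus whose
  tuning is state-independent — the substrate for the decoder dissociation:
  Fano factor rises with 3-6 Hz power while decodability does not change.
* **Pupil**: latent state plus independent AR(1) noise mixed to a target
  correlation (default 0.6); the derivative is the first difference.
* Defaults chosen where nothing is stated: 16x16 grid and white measurement
  noise with SD 0.1 (about 10% of the signal scale) keep full sessions
  desk-sized; the noise spectrum of real widefield recordings is not
  characterized here, so white noise is an assumption, flagged rather than
  inferred. Stimulus transients are large relative to ongoing fluctuations,
  as GCaMP6 sensory responses are.

What a green test does **not** establish: the generator has no vasculature,
motion, photobleaching, slow drift, multi-area connectivity structure, or
video-derived pupil artifacts; group-level numbers from the real recordings
(absolute coherence values, muscimol effect sizes, regional dB magnitudes)
are not reproducible from it, and the suite instead checks directions,
calibrated recoveries, and estimator identities.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_trials = 120, seed = 1)
session <- generate_session(cfg)

cal  <- compress_movie(session$movie$calcium_frames,
                       session$movie$timestamps_cal, k = 50)
hemo <- compress_movie(session$movie$hemo_frames,
                       session$movie$timestamps_hemo, k = 25,
                       channel = "hemo")
gains     <- estimate_hemo_gains(cal, hemo)
corrected <- apply_hemo_correction(cal, hemo, gains)

trials <- classify_trials(session$trials)
tab <- band_power_table(corrected, trials, default_roi_set(16),
                        pupil = session$pupil)
percentile_rates(tab, "VIS")
```

## Known limitations

* The FFT filters and the bandlimited channel alignment assume effectively
  stationary segments; very short recordings see wrap-around edge effects.
* The likelihood-ratio p-values from the mixed models are asymptotic; at
  very few sessions/subjects they can be mildly anticonservative (the
  false-positive-rate simulation in the acceptance suite tracks this).
* The coherence bias floor (~1/n_segments) is not subtracted from reported
  coherence; comparisons should use matched segment counts.
* `equalize_trial_counts` subsamples once per seed; analyses sensitive to
  the particular subsample should average over seeds.
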