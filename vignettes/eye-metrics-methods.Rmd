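---
title: "Models and methods behind oculaware"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind oculaware}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oculaware)
```

`oculaware` analyses stimulus-evoked eye metrics — pupil size, blinks and
microsaccades — in visual detection experiments, with the design axis that
matters for cerebral blindness: every stimulus is presented in one of two
hemifields, and the question is whether the evoked responses in a *blind*
hemifield carry decodable information about stimulus presence. This
vignette explains the models, the parameters that matter, the numerical
choices, and what the synthetic data can and cannot tell you about real
recordings.

## The task model

A session consists of blocks of trials with three phases: a pre-stimulus
fixation period jittered between 3 and 5 s, a 3-s stimulus presentation,
and a post-stimulus period jittered between 3 and 5 s. Stimuli come in six
classes: two *target* orientations (plus, x) requiring an immediate
keypress and orientation judgement, and four *nontargets* (white, glare,
nonglare, isoluminant) requiring no response. The nontargets form a
luminance/brightness gradient: the white stimulus is physically bright,
the glare stimulus induces *illusory* brightness from a luminance-gradient
arrangement, the nonglare stimulus is the same gradient rotated so the
illusion vanishes, and the isoluminant stimulus adds no net luminance at
all.

Defaults in `synth_config()` mirror this design: 10 blocks of 40 trials,
uniform class proportions (each target orientation 0.1, each nontarget
0.2), and a 50/50 field split. Tests and examples use fewer trials purely
to keep runtimes short; the generator's defaults are the study-scale
conditions.

## The synthetic recording

`generate_session()` builds a 1000-Hz monocular recording:

* **Pupil** = baseline + summed evoked kernels + noise. Targets evoke a
  unimodal dilation, modelled with the standard gamma-family pupil impulse
  response (peak at 930 ms, shape 10.1), amplitude 60 recorder units by
  default. Nontargets evoke a sustained constriction: raised-cosine rise
  over 600 ms, unit plateau for the stimulus duration, exponential
  recovery (τ = 1 s) after offset. Constriction amplitudes default to
  −120 / −80 / −40 / −10 units for white / glare / nonglare / isoluminant —
  a 3:2:1 gradient over the three luminance-test stimuli, plus a small
  stimulus-onset component for the isoluminant control. All kernels are
  scaled by a per-field gain; `c(sighted = 1, blind = 0.4)` emulates an
  aware-like patient with reduced blind-field responses, and
  `blind = 0` an unaware-like patient with none.
* **Noise** is AR(1) with coefficient 0.99 (innovation SD 1.5 units)
  plus white measurement noise at a quarter of that SD. The strong
  autocorrelation matters: i.i.d. noise would average away within an
  epoch and make classification unrealistically easy. The innovation SD
  was set so that sample-to-sample jitter stays an order of magnitude
  below the blink-artifact velocities the detector looks for, as in real
  recorder output where the pupil signal itself is smooth.
* **Blinks** are an inhomogeneous point process: base rate 0.25/s times a
  piecewise-constant modulation (×0.3 in the 500 ms after onset, ×2.0 in
  the 500 ms after offset). Each blink sets the pupil to missing for a
  lognormal duration (median 150 ms) flanked by 30-ms, 600-unit ramps, so
  the velocity criterion of the detector has a realistic signature to
  find. A dead time of one blink duration prevents overlapping events;
  count expectations in the tests use the standard dead-time correction
  λ/(1 + λτ).
* **Microsaccades** are a second point process (base 1.5/s, ×0.2 after
  onset, ×0.5 after offset, 50-ms refractory gap) realised in the gaze
  traces as conjugate raised-cosine step displacements of 0.1–1.0° over
  2–12 ms, on top of slow AR(1) fixation drift and white jitter
  (SD 0.01°). Displacement directions are biased back toward fixation
  once gaze strays beyond 0.3°, giving bounded square-wave-jerk-like
  behaviour.
* **Responses** are emitted for each target with the per-field perception
  probability; latencies are Normal(0.9 s, 0.3 s) truncated at zero, and
  the orientation key is correct with probability 0.9.

One master seed expands into named substreams (events, pupil, blinks,
microsaccades, gaze, responses), so any component can be varied without
disturbing the others and every output is exactly reproducible.

What the generator does *not* emulate: binocular disparity, head motion,
pupil foreshortening with gaze eccentricity, slow arousal drifts
correlated across metrics, saccadic spike artifacts in the pupil signal,
and non-stationary blink rates over a session. Passing tests therefore
demonstrate that the pipeline recovers what it is defined to recover under
controlled conditions — they do not certify performance on any particular
real recording.

## Preprocessing choices

Blink detection combines three independent criteria — missing samples,
absolute sample-to-sample change above 10 units/ms, and deviation from
the session median beyond 8 MADs — padded by 50 ms per side with runs
closer than 100 ms merged. The cited detection literature leaves these
values open; the defaults were chosen once against the generator's
artifact model (ramps of 20 units/ms versus noise jitter of ~2 units/ms)
and are all exposed as `blink_params()`. Cleaning interpolates linearly
across blink intervals (nearest-value fill at the edges) and smooths with
a 50-ms centered moving average whose window shrinks at the recording
edges so no samples are invented. Interpolation rather than excision was
chosen so epochs keep their full sample grid; interpolated samples are
flagged in the output.

Microsaccade detection follows the median-velocity-threshold scheme: a
centered moving-window velocity estimate (5 samples; the classic
`(x[n+2]+x[n+1]−x[n−1]−x[n−2])/6` at 1000 Hz, generalised to any odd
window), per-axis thresholds at λ = 6 median-based SDs, a 6-ms minimum
duration, a 1° amplitude ceiling separating microsaccades from ordinary
saccades, and a 20-ms merge window. Edge samples where the window does
not fit are marked undetectable rather than extrapolated. The detector is
deliberately monocular — the study design records one eye — so no
binocular agreement criterion exists.

## Epoching and exclusion

Epochs span −9000…+9000 ms inclusive (18,001 samples), with the sample at
offset 0 being the event-onset sample. Every stimulus gets one *blank*
epoch drawn uniformly from 4000–7000 ms after its onset, clipped to end
1000 ms before the next onset and before the block end; a stimulus whose
admissible interval is empty simply gets no blank, and is reported. Pupil
epochs are baselined to the mean of the 1000 ms immediately preceding the
event; binary epochs never are.

Exclusion keeps rows and flips a mask rather than deleting, so the
stimulus–blank pairing survives reporting; `harmonise_pairs()` then drops
the partner of any excluded epoch so paired analyses see a bijection.
Pupil epochs are excluded for any value above 1750 recorder units or
strictly more than 50% missing samples within −1000…+6000 ms — both
boundaries strict, so a value of exactly 1750 or exactly half missing is
retained. For binary epochs the exclusion is based on *tracking validity*
(more than 50% of the interval untracked): taken literally, a rule about
"samples that were 0" would discard epochs that merely lack blinks, while
its stated motivation is eye closure and tracking loss. The literal
variant remains available behind `literal = TRUE`.

Fraction timecourses (per-sample proportion of epochs with an event) are
smoothed with a 100-ms centered moving average; the width is a package
choice, exposed as an argument, since only the fact of smoothing is given
by the reference procedure.

## The stacked classifier

Features are the epoch samples in (0, 4000] ms averaged in 20-ms bins
(200 features). Binning is a conditioning choice: at 1000 Hz the raw
window is 4000 highly collinear features, and 20-ms averages preserve the
waveform far below the timescale of any of the three metrics' responses;
`bin_ms = 1` restores raw samples. Folds are assigned to stimulus–blank
*pairs* (a pair always shares a fold), which simultaneously prevents twin
leakage between a stimulus epoch and its temporally adjacent blank and
stratifies every fold perfectly. Whether the original procedure
stratified folds is not stated; this choice is the conservative one.

Level one fits a linear SVM (hinge loss, cost 1, features standardised on
each training fold) per metric per fold and emits signed decision-boundary
distances for held-out epochs only. Level two stacks the three out-of-fold
scores with the same folds. A second-level score of exactly 0 predicts
"blank" — deterministic and conservative toward the null. Accuracy is
correct/total over held-out predictions; chance is the majority-class
proportion (0.5 on balanced sets). The permuted-label null refits the
whole stack with labels shuffled *within fold*, preserving the balanced
fold composition while destroying any label–feature association; the mean
null accuracy sitting on chance is the operational no-leakage check, and
its 95th percentile is the presence criterion for single metrics.

## Behavioural and luminance statistics

Perception scoring credits each keypress to at most one target — the
earliest unmatched press within 5000 ms of onset — making the
press-to-target matching deterministic; the false-positive rate is
unmatched presses over all presses. The binomial test is the exact upper
tail. Reaction-time comparisons trim unequal paired samples to the common
length in trial order and flag that they did.

The signed-rank tests throughout use an exact sign-flip enumeration up to
n = 14, which stays exact under tied absolute values (where the classical
null tables do not apply — eight identical positive differences must give
p = 1/256, not an approximation), with a tie-corrected normal
approximation beyond. The luminance slope test fits least squares through
each participant's minimum constriction in the first 1500 ms, ordered
white (1), glare (2), nonglare (3) — coded so the expected physiological
pattern is a *positive* slope — and tests slopes against zero one-sided
(a two-sided option exists, since the sidedness of the reference test is
not explicit). Zero slopes use Pratt handling, retaining the information
in exact ties instead of discarding them.

## Cluster-based permutation testing

Field-potential traces are zero-phase filtered (2nd-order Butterworth
high-pass at 0.1 Hz, 4th-order low-pass at 115 Hz, 2nd-order ±2-Hz
band-stops at 60 and 120 Hz), epoched at onset + 19 ms (the projector
delay) on a −4000…+4000 ms grid, and baselined per epoch to the 500 ms
before the event — per-epoch rather than per-condition baselining, the
stricter of the two readings. Per-sample pooled-variance t statistics in
(0, 500] ms form clusters where |t| exceeds the two-sided critical value
at α = 0.05 (the cluster-forming threshold is not printed by the
reference method and is exposed as `cluster_alpha`); cluster mass is the
sum of t, and the null is the maximum |mass| over label exchanges, with
the add-one permutation p-value. Identical epochs in both conditions
yield zero pooled variance at every sample; those t values are defined as
0 so the degenerate case reports no clusters rather than an error. The
three study contrasts run as independent families with no cross-contrast
correction, matching per-contrast reporting.

## Problem sizes in the tests

The test suite chooses sizes that keep the full run near three minutes:
sessions of 10–400 trials depending on what the check needs (amplitude
recovery uses 200 trials; suppression-ratio recovery 400 epochs),
600 replicates at 250 permutations for the family-wise error calibration
(on a 250-Hz grid — the test's validity does not depend on sampling
rate), 1000 replicates for the slope-test calibration, and 200 label
permutations for the leakage check. These are the package's validation
conditions; the analysis functions themselves have no built-in scale
limits.

## Known limitations

Accuracy estimates from ten folds on small epoch counts are noisy, and
the chance level is estimated per participant rather than derived from a
null distribution (the permutation null is available when that matters).
The cluster test is one-dimensional — single sensor over time; spatial
adjacency clustering across sensors is out of scope. The generator's
evoked kernels are deterministic per class; trial-to-trial amplitude
variability beyond the noise model is not simulated, so decoding
accuracies on synthetic sessions should be read as upper bounds for
matched real-data conditions.
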