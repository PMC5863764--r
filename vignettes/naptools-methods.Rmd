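---
title: "Methods: cue-evoked spindle analysis, SO-spindle coupling, and category decoding in sleep EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cue-evoked spindle analysis, SO-spindle coupling, and category decoding in sleep EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope

`naptools` implements the analysis chain of a targeted memory reactivation
(TMR) experiment in NREM sleep: auditory memory cues are replayed during
N2/N3, and the pipeline asks (1) whether cues evoke fast sleep spindles,
(2) at which slow-oscillation (SO) phase that spindle activity is
expressed, (3) whether the category of the cued memory (object vs. scene)
can be decoded from the evoked EEG pattern, and (4) whether decoding
fidelity predicts the behavioral benefit of cueing. Because raw
experimental recordings in this field are typically shared only on
request, the package pairs every analysis stage with a synthetic
polysomnography generator whose ground truth makes the stage testable by
parameter recovery.

## Preprocessing model

Continuous 8-channel EEG (F3, F4, C3, C4, P3, P4, O1, O2; 200 Hz;
microvolts) is segmented into cue-locked epochs spanning the half-open
interval [-1, 3) s; the sample at t = 0 is the cue onset and all other
windows in the package are closed intervals in seconds. Artifact
rejection is two-step. Step one flags trials whose amplitude statistic
(maximum absolute value over channels and samples) or gradient statistic
(maximum absolute difference between adjacent samples) falls outside
median +/- 3.5 IQR of the across-trial distribution; the per-trial
maximum over channels makes the criterion whole-epoch, the stricter of
the readings such a rule admits. Step two is an
automated surrogate for interactive summary screening: robust z-scores
((x - median)/(1.4826 MAD)) of per-trial variance and excess kurtosis,
flagging trials above `z_cut` (default 5) on either metric. Flags are
sticky and only ever grow; both steps are invariant to trial and channel
order. ERP analyses high-pass the epochs at 0.5 Hz (zero-phase
Butterworth, order 4 per pass) and subtract the mean of the -200 to 0 ms
baseline.

All zero-phase filters pad the signal by odd (point-reflected) extension
before the forward-backward pass. The `filtfilt` available in R's
`signal` package applies no edge treatment, and without padding the
transient of a 0.5 Hz high-pass corrupts an entire 4-s epoch; with the
padding, a 10 Hz sinusoid passes the 0.5 Hz high-pass with < 0.1%
amplitude error (verified in the test suite by projection onto the 10 Hz
component).

## Time-frequency model

Power is estimated by Hanning-tapered complex demodulation with a
frequency-dependent window of 5 cycles (333 ms at 15 Hz), on a 4-30 Hz
grid in 0.5 Hz steps and a 5 ms time grid (one sample at 200 Hz). The
estimate is scaled so a pure sinusoid of amplitude A yields A^2/2 at its
own frequency. Time points whose window would extend beyond the epoch are
missing values, never zero-padded, so pre-cue baselines cannot be
contaminated by post-stimulus activity leaking through a padded window.
Percent change is computed per channel and frequency as
100 (P - Pbase)/Pbase against the -300 to -100 ms window, with the
baseline taken on the trial-averaged power (average-then-baseline;
configurable ERP and TFR baselines are intentionally distinct defaults).
Power is left untransformed before statistics.

## Event detection

Spindles: per channel, the signal is demeaned, band-passed (13-16 Hz fast
band by default; 10-13 Hz slow band available), and the amplitude
envelope taken as the magnitude of the analytic signal. The threshold is
mean + 1.25 SD of the envelope over all eligible samples -- N2/N3 scored
epochs with automatically detected artifact samples padded by +/- 1 s and
removed -- and events are supra-threshold runs lasting 0.5-3 s.
Supra-threshold runs separated by less than 0.1 s are merged before the
duration gate (merging is not part of the core rule; the gap is
configurable). Demeaning before filtering makes detection exactly
invariant to DC offsets.

Slow oscillations: per channel, 0.5-2 Hz filtering, positive-to-negative
zero-crossing pairs spanning 0.8-2 s form candidates, and candidates
exceeding mean + 1.25 SD of *both* the trough amplitude and the
trough-to-peak amplitude (statistics over all candidates on that channel,
computed after excluding artifact-padded candidates) are kept. When the
candidate metrics are essentially identical -- coefficient of variation
below 0.5%, as for a constant-amplitude oscillation -- no candidate
stands out from the pool and the adaptive threshold is not meaningful, so
nothing is detected; this guard only engages for degenerate inputs, since
real candidate pools vary by far more.

Post-cue spindle counting uses events whose envelope maximum falls in the
closed window 1.5-2.5 s after cue onset on left-hemisphere channels (F3,
C3, P3, O1) by default, mirroring the left-lateralized expression of the
cue-evoked spindle surge; an event peak exactly on the window edge is
counted.

## SO-spindle coupling

For each selected spindle a +/- 1.5 s raw segment around the envelope
maximum (601 samples at 200 Hz) is filtered into an SO view (0.5-2 Hz)
and a spindle view (13-16 Hz). The SO instantaneous phase comes from the
analytic signal; the spindle envelope is demeaned and its phase likewise
extracted; the per-sample circular distance (SO phase minus envelope
phase) is averaged circularly. Two numerical choices matter here and are
the package's own:

* the envelope is demeaned before the analytic transform, because the
  analytic phase of a strictly positive signal is dominated by its DC
  component and carries no modulation timing;
* the circular mean over the 601 distances is weighted by the
  instantaneous spindle envelope, because samples without spindle energy
  have no meaningful envelope phase. For sustained spindle trains the
  weighted and unweighted means coincide; for an isolated burst the
  unweighted mean is pulled tens of degrees off the stated convention
  anchors, while the weighted mean reproduces them within ~2 degrees.

The phase convention is cosine-based: 0 = SO up-state peak, +/-180 = the
down-state trough, and a burst envelope peaking a quarter cycle *after*
the up-state peak reads +90 (the SO phase has advanced by pi/2 at the
envelope maximum). Phases are wrapped to (-180, 180]; display on the
[0, 360) branch is offered where results are conventionally printed that
way. Subject-level preferred phases are circular means of event phases
(resultant length R reported; R ~ 0 is flagged degenerate and excluded
from group histograms). Group-level concentration is tested with the
Rayleigh statistic z = nR^2 (small-sample series approximation for the
p-value) and directionality against the up-state with the V test
(v = nR cos(mean - ref), u = v sqrt(2/n) against the standard normal
upper tail). Both tests are implemented in the package and their size is
verified by Monte-Carlo under uniform phases.

## Representational similarity

From 0.5 Hz high-passed epochs, a 200 ms sliding window in 10 ms steps
(centres -0.2 to 2.5 s) yields one feature vector per trial and time:
8 channels x 41 samples = 328 features. Spearman correlations between all
trial pairs form a symmetric matrix per time point; the diagonal, the
lower triangle, and same-adjective pairs across cueing rounds are
removed. Within-category similarity averages the surviving object-object
and scene-scene cells, between-category similarity the object-scene
cells, with the majority class randomly sub-sampled so both means use the
same number of cells (seeded; with equal counts the sub-selection is a
no-op). The mean series are Fisher z-transformed, with rho clipped to
+/-(1 - 1e-6) so the transform stays finite. Category distinctiveness is
1 minus the mean between-category (Fisher-z) similarity over a stated
window, 1.76-2.06 s by default for the behavioral correlation and
1.5-2.5 s for spindle-count correlations. An optional < 4 Hz low-pass
flag restricts features to the slow components that carry most of the
category information.

## Cluster-based permutation inference

`paired_t_map`, `form_clusters` and `permutation_p` implement
max-cluster-mass permutation inference over time, channel x time, and
channel x frequency x time grids. Adjacency is +/- 1 grid step along time
and frequency; along channels it is a fixed hand-coded neighbour list for
the 8-channel montage (F3-C3, C3-P3, P3-O1, F4-C4, C4-P4, P4-O2, F3-F4,
C3-C4, P3-P4, O1-O2), declared in code because no template exists for
this montage. The cluster-forming threshold defaults to the two-sided
alpha = 0.05 paired-t critical value; 1000 permutations is the default.
For paired condition contrasts (old vs. control ERP/TFR) the permutation
scheme is subject-wise sign flipping of the condition difference, and the
observed cluster's Monte-Carlo p is the +1-corrected proportion of null
maximum |mass| values at least as large as the observed |mass|, which
controls family-wise error two-sidedly.

The within-minus-between similarity contrast needs a different null.
That difference is, in expectation, a squared distance between the two
category centroids in feature space, so under the null it is chi-square
shaped: mean zero but right-skewed, the more so the lower the effective
dimensionality of the features (slow, spatially shared signals make
neighbouring features highly correlated). Sign flipping tests *symmetry*
about zero, which is false for such a null even without any category
signal -- in our calibration studies the sign-flip test's family-wise
error was 0.11-0.14 at desk scale while the identical machinery was
calibrated (0.038) on Gaussian data. `rsa_cluster_test` therefore
permutes the trial category labels within each subject, rebuilding the
within/between cell sets from each subject's fixed similarity matrices
per permutation; this is the exact conditional null for representational
contrasts, and its measured family-wise error (0.04 across 200 replicate
null cohorts) sits inside the 95% binomial band of the nominal 0.05.

## Behavioral scoring

"Recalled" always means the associated image category (object vs. scene)
was reported correctly; items misclassified in the object/scene
categorisation task are excluded from all recall scoring, and cued versus
non-cued status is defined only among items recalled at the first test.
Conditional retention is |recalled at Tm and Tn| / |recalled at Tn|; the
TMR benefit is cued minus non-cued T2-to-T3 retention (range [-1, 1]);
the discrimination index is the hit rate among cued items minus the
false-alarm rate among non-cued items in the post-study awareness test.
Subjects with an empty denominator are excluded with a warning and
counted. Group-level inferential ANOVAs are out of scope; the package
reports condition means and SEMs.

## The synthetic generator

`generate_recording()` builds, per subject: 1/f-shaped Gaussian
background EEG (default exponent 1, 15 uV RMS); discrete SOs as one
-A sin(2 pi t / T) period (down-state half-wave then up-state half-wave;
default T = 1.4 s, A = 75 uV, 5 events/min); Gaussian-windowed spindle
bursts (default 14 Hz, 25 uV, 1 s) whose centres sit at the configured SO
phase with von Mises jitter (kappa = 4 by default) and a per-channel
refractory gap; cue markers only inside N2/N3 with ISI 4 s +/- 200 ms;
for every cue a stereotyped evoked k-complex at 0.4-0.9 s latency and a
sustained condition-independent slow evoked component over ~1.2-2.6 s;
an evoked spindle with probability 0.35 for control cues, multiplied by
1.5 for old cues, expressed on left-hemisphere channels and coupled to
the evoked SO's up-state; and category-specific slow (< 4 Hz)
channel-weighted patterns added in 1.7-2.3 s on old trials, with the
scene weight vector orthogonalized against the object one so the two
categories are maximally distinguishable.

Two generator details exist to make ground truth exact rather than
approximate. First, spindle placement maps the sampled von Mises phase to
time through the *measured* analytic phase of the filtered SO template:
a solitary SO cycle's instantaneous phase is not a uniform ramp, and a
naive linear phase-to-time map makes the injected phase disagree with
what any Hilbert-based estimator measures (we observed 17-28 degree
recovery biases before switching; under the measured map recovery is
within 10 degrees at kappa = 4). Second, the sustained common evoked
component gives between-category similarity a realistic positive
baseline; category patterns then *dilute* it, which is what makes
distinctiveness rise with pattern amplitude (with no shared signal,
between-category similarity is already ~0 and distinctiveness cannot
move).

The latency range of the evoked k-complex (0.4-0.9 s) is a free
simulation parameter, not an empirical claim. Behavioral outcomes are
Bernoulli draws: T1 category recall at 0.55, T1-to-T2 retention at 0.8,
T2-to-T3 retention at 0.65 for non-cued items and 0.65 plus the
subject's true benefit for cued items (clipped to [0, 1] with a
warning); the subject's true benefit is the configured cohort effect
(default 0.2) scaled by a subject-level pattern-strength factor uniform
on [0.6, 1.4], so benefit and true distinctiveness are coupled across
subjects. At least 14 recalled items per category are guaranteed,
mirroring the inclusion criterion. Discrimination responses are
cue-independent (yes rate 0.3).

Everything derives from one master seed: each subject and generator
component reseeds from (seed, subject, component), so any stage can be
regenerated independently and all outputs are bit-reproducible. Functions
that seed internally save and restore the caller's RNG state.

What the generator does not emulate: realistic sleep architecture beyond
stage labels, inter-channel correlation of the background (channels are
independent), amplitude non-stationarity across the night, true artifact
morphologies (rejection tests plant their own outliers), acoustic
stimulus properties, and any relationship between the discrimination
task and cueing. Passing recovery tests on this synthetic data therefore
shows the estimators are correct under the stated signal model, not that
the scientific conclusions transfer to any particular real recording.

## Problem sizes

The test suite and the analysis workflow choose sizes that keep the full
run in the minutes range on one CPU: detector and coupling recovery use
single 20-min 8-channel recordings (with detector recovery at a sparse,
clearly supra-threshold operating point: 3 spindles/min/channel at 18 uV
and 1.5 s, 2 SOs/min, sparse cueing, since the adaptive mean + 1.25 SD
rule by construction selects events that stand out of the candidate
pool); RSA calibration uses 200 replicate null cohorts of 6 subjects,
16 trials, 2 channels, 50 ms steps and 100 permutations, and effect
localization 8 subjects at pattern SNR 2 with 20 ms steps; the workflow
in `analysis/` simulates 8 subjects at 10 min each. The same code paths
scale to experiment-sized inputs linearly in duration, trials and
permutations.

## Known limitations

* The spindle/SO thresholds are adaptive per channel; on recordings whose
  event density is high relative to the background the threshold rises
  with the events themselves, and sensitivity against ground truth drops
  -- a property of the adaptive rule itself, not of the implementation.
* The preferred-phase estimator is envelope-weighted (see above); with
  real multi-spindle segments the difference from the unweighted mean is
  small, but single-event segments estimated with other toolboxes may
  differ by a few degrees.
* EDF support is the minimal continuous 16-bit single-rate subset needed
  for these fixtures, not a general EDF+ reader.
* `permutation_p`'s sign-flip scheme should not be used for
  representational (within/between) contrasts; use `rsa_cluster_test`.
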