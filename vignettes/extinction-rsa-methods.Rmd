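---
title: "Simulating and analysing context-dependent fear extinction in intracranial EEG"
author: "extinctRSA authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing context-dependent fear extinction in intracranial EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Extinction learning suppresses a previously acquired fear response: a cue
that used to predict an aversive outcome (CS+) stops doing so, and a new,
strongly context-dependent memory trace is thought to form alongside the
original fear trace. When the extinguished cue is later encountered in yet
another context, the two traces compete, and fear may return (renewal).
Intracranial EEG (iEEG) in epilepsy patients gives direct access to the
structures involved — amygdala (AMY), hippocampus (HPC), lateral and
orbital prefrontal cortex (lPFC, OFC) and lateral temporal cortex (TMP) —
and representational similarity analysis (RSA) of spectral activity
patterns makes the memory traces of specific cues and contexts measurable.

`extinctRSA` implements the full analysis chain for a three-phase ABC
conditioning design (acquisition, extinction, test, each in its own set of
context videos) together with a synthetic-data generator that produces
multichannel recordings with known, plantable ground truth. The generator
exists so that every stage of the pipeline — from filtering to
cluster-corrected group inference — can be validated by parameter-recovery
and null-calibration experiments rather than by eyeballing.

## Experimental design and schedules

The design follows the standard partial-reinforcement ABC layout:

* 3 cue identities with roles CS++ (always paired), CS+- (paired during
  acquisition only) and CS-- (never paired);
* 24 presentations per cue in each learning phase (72 trials), 16 at test
  (48 trials), with no more than 3 consecutive presentations of the same
  cue;
* 50% reinforcement of CS+ cues, so the aversive US occurs 36 times in
  total (24 for CS++ across both learning phases, 12 for CS+- during
  acquisition);
* 4 contexts during acquisition, 4 new ones during extinction and 8 new
  ones during test, with disjoint pools across phases.

Trial timing is fixation 0.5 s, context video alone 2 s, cue overlaid for
1.75 s, US period 1 s, followed by the rating prompt. The response window and
inter-trial interval are free parameters; the generator uses
2 s and 1.5 s, typical values for self-paced rating designs.

Two scheduling details are under-determined by the design description and
were fixed as follows. Contexts are assigned in exact balance — every
context appears equally often with every cue (24/4 = 6; 16/8 = 2) — so
that same-context and different-context pair counts are identical across
cues, which keeps the context-specificity metric free of pair-count
confounds; the run-length cap is enforced by rejection sampling with a
bounded retry count and a constrained greedy fallback. US positions are
drawn uniformly among each CS+ cue's 24 ordinal slots.

## The synthetic recording generator

`simulateRecording()` synthesizes continuous multichannel voltage at
1 kHz with event markers at video, cue and US onsets. Its components:

* **Background**: per-channel 1/f Gaussian noise (exponent 1, SD 30 uV)
  plus a shared low-rank common component (gain 0.5) that bipolar
  referencing must remove. 1/f background and a common reference signal
  are the two dominant features of real depth-electrode recordings that
  matter for this pipeline.
* **Item signatures**: per cue, a fixed nonnegative channel x frequency
  template (unit L2 norm) over the 44-frequency analysis grid. During cue
  presentation, band-limited noise with this amplitude-spectrum shape is
  added per channel, scaled by `itemPatternGain` times a role- and
  phase-dependent multiplier and a trial-to-trial jitter (SD 0.2).
  The default profile makes CS++ patterns the strongest during extinction
  (multiplier 1.0 vs 0.4) and equal across roles elsewhere, emulating the
  reported pattern of higher item stability for threat cues during
  extinction with no acquisition differences.
* **Context signatures**: analogous per-context templates expressed during
  the video + cue period, strongest during extinction (phase multipliers
  0.5 / 1.0 / 0.5).
* **Theta safety effect**: flat-spectrum 3-10 Hz noise added to AMY
  channels at 1.18-1.75 s after cue onset in extinction trials whose
  current valence is CS-, with amplitude `thetaSafetyEffect`.
* **Artifacts**: brief (5-50 ms) biphasic spikes at Poisson positions
  (default 0.02 per minute per channel, amplitude 15 channel-SDs), with a
  returned position ledger for detector-sensitivity tests.

Effect amplitudes default to 12 uV. With the background's 1/f density
(total variance 900 uV^2 spread as 1/f between 0.1 and 500 Hz), a 12 uV
flat component over 3-10 Hz contributes roughly the same power per
wavelet bandwidth as the background at the band centre, i.e. in-band SNR
near 1 — a planted effect that is reliably recoverable at cohort level
without being a caricature. The artifact rate was chosen so that
ROI-level epoch rejection lands near the reported ~20 rejected cue epochs
per participant.

Ratings (1 threatening ... 4 safe) follow saturating learning curves: all
cues start at the uncertain midpoint (2.5), CS++ descends toward 1 and
CS-- rises toward 4 from `learningOnset` (default ordinal 10, matching
the reported behavioural divergence points of 9-13), CS+- flips to the
safe asymptote during extinction, and test-phase means encode incomplete
extinction (CS++ 2.0 < CS+- 3.0 < CS-- 3.5). A `missRate` fraction of
trials (default 0.08, cf. the reported 12.65 +/- 15.47 missing responses)
has no response.

What the generator does **not** emulate: evoked (phase-locked) responses,
US-evoked auditory potentials, cross-frequency coupling, non-stationary
drift, electrode-specific line noise, or genuinely oscillatory (narrow
peak) theta. Passing recovery tests therefore demonstrates that the
pipeline detects the planted class of spectral-power effects at realistic
SNR — not that it would detect every physiological effect in real data.

## Preprocessing

`filterRecording()` applies 0.1 Hz high-pass, 200 Hz low-pass and
49-51 / 99-101 / 149-151 Hz band-stop filtering. The filters are applied
as the exact squared magnitude response of 4th-order Butterworth designs
in the frequency domain: this is zero-phase by construction and equals a
forward-backward IIR pass in the long-record limit, while avoiding the
numerical fragility of IIR coefficients at a normalized cutoff of 2e-4.

`bipolarReference()` subtracts adjacent contacts within a shaft (N-1
virtual channels per N contacts); the virtual channel inherits the ROI of
its deeper contact.

`detectArtifacts()` implements the three-criterion epileptiform detector:
whole-recording z-scores of amplitude, gradient, and amplitude after a
250 Hz high-pass; a sample is a core if any |z| >= 6 or if amplitude
|z| >= 4 together with gradient or high-frequency |z| >= 3; cores are
padded by +/-1000 ms. Two details deserve note. First, detection runs on
the *unfiltered* (bipolar) signal in `processParticipant()`: the 250 Hz
criterion is meaningless after the 200 Hz low-pass, so the detector must
see the raw signal. Second, on *white* noise the
discrete gradient is strongly anticorrelated with amplitude, so the
conjunction rule fires on a few samples per minute even without
artifacts; on 1/f-type background (where amplitude and derivative are
nearly independent) the false-alarm rate is essentially zero. The padding
means that a single core already flags ~3% of a one-minute record, which
is why the flag-rate tests distinguish the two noise types.

`epochRecording()` cuts 7-s epochs (-3 to 4 s around cue onset) and
rejects an epoch if *any* channel of the analysed ROI carries a flagged
sample inside the window. ROI-level rejection was chosen over per-channel
bookkeeping because RSA feature vectors need all ROI channels in every
retained trial. Conditions
retaining fewer than 8 trials flag the participant-ROI as excluded
(4 for the ratings analyses).

## Time-frequency decomposition and normalization

`buildFrequencyGrid()` returns the 44-frequency variable-cycle grid: 29
linear steps from 1 to 29 Hz with cycles 3 to 6, and 15 steps from 30 to
100 Hz with cycles 6 to 12. `morletTFR()` convolves epochs with complex
Morlet wavelets (Gaussian SD cycles/(2*pi*f), support +/- cycles/(2f),
unit-energy normalization) and returns power at a configurable output
grid (default 20 ms steps; the validation analyses mostly use 50 ms, the
native resolution of the RSA windows). The implementation evaluates the convolution only at
the requested output instants through a cached sparse projection
operator, which is exact and considerably faster than full FFT
convolution when output times are sparse. Output instants whose wavelet
support crosses the epoch edge are refused (`edge = "strict"`), marked NA,
or computed with a clipped renormalized wavelet (`edge = "truncate"`, used
for video-locked analyses where the 1 Hz wavelet is slightly truncated at
the earliest windows).

`zscorePower()` normalizes per channel x frequency against the mean and
SD pooled over all reference trials *and time points* (all trials of the
experiment across phases in the pipeline). Pooling over time makes the
reference a single mean/SD pair per channel and frequency, which matches
the purpose of the normalization — removing common, condition-unspecific
signal — and a `perTime = TRUE` variant is provided for sensitivity
checks.

`tfConditionContrast()` averages z-scored power over ROI channels,
averages trials within condition per participant, computes the group
paired t map, and corrects it with the 2D cluster permutation. The CS-
condition during extinction pools CS+- and CS-- trials (current valence),
and the contrast sign convention is CS+ minus CS-, so the safety-related
theta increase appears as a negative cluster.

## Representational similarity metrics

Feature vectors are the z-scored power values of all ROI channels x 44
frequencies averaged within 500-ms windows stepped by 50 ms (90% overlap),
compared across all trial pairs with Spearman correlations at matching
window centres (centres assigned to window midpoints). Rho values are
Fisher z-transformed (rho clamped to +/-(1 - 1e-12) before atanh) before
any averaging or testing.

* **Item stability** is the mean within-item similarity across repeated
  presentations; because one contingency class holds two items, stability
  is computed per item and the two same-contingency items averaged before
  the CS+ vs CS- paired contrast (never pooling pairs across items).
* **Context specificity** is mean same-context minus different-context
  similarity across all trial-pair combinations; a `pairSet =
  "different-cue"` variant restricts both sets to different-cue pairs to
  control the cue-identity confound.
* **Single-trial variants** average each trial's similarity to all other
  same-item trials (stability) or the same-minus-different context means
  (specificity), the substrate for the coordination analyses.

Group inference contrasts the per-participant series with paired t tests
per window centre and corrects over centres with the 1D cluster
permutation, shuffling cue (or context) labels across trials within each
participant and recomputing the full statistic per permutation.

## Coordination, reinstatement, and behaviour

`crossRoiTrialCorrelation()` correlates two single-trial metric time
courses across trials at every time-by-time combination (Spearman),
yielding temporal generalization maps tested against zero at group level
with 2D cluster correction (trial order of the second region shuffled).
Trials are aligned by the intersection of retained trials, since
rejection is ROI-dependent. `thetaMetricCorrelation()` correlates
single-trial theta-cluster power (z-scored within condition, so
condition-mean differences cannot drive trial-level correlations) with
item stability or context specificity, windowed or time-resolved.

`crossPhaseSimilarity()` correlates each acquisition/extinction trial
with each test trial; `reinstatementRecord()` averages Fisher-z
similarities over same-item pairs and the configured window into
REINST_ACQ and REINST_EXT per cue role, and REINST = REINST_ACQ -
REINST_EXT quantifies the balance between fear- and extinction-trace
reinstatement. Analysis windows default to the empirically established
windows for this paradigm (lPFC context specificity 0.8-1.15 s; TMP item
stability 0.65-1 s), which in real data are derived from the preceding
contrasts; a synthetic run cannot re-derive them, so they are
configuration defaults.
Per-trial extinction-to-test reinstatement (same-item minus
different-item similarity; the different-item set is all non-matching-cue
pairs in the window) is correlated with test-phase ratings per
participant, with an optional 2-SD outlier exclusion and a 4-trial
minimum (8 in the stricter variant).

Behaviour: `rmAnova2way()` is the two-way repeated-measures ANOVA (cue x
phase) with partial eta squared and Bonferroni post hocs, implemented on
`stats::aov` with an `Error(participant/(cue*phase))` stratum;
`learningCurveTest()` compares two roles at every within-condition
ordinal position with paired Wilcoxon signed-rank tests across
participants, cluster-corrected by randomly swapping the two conditions
at every trial (per participant by default; a global-swap variant is
provided).

## Cluster-based permutation inference

All corrections share one machinery: two-sided cluster-forming threshold
at alpha 0.05 (t distribution with participants-1 df, or the permutation
quantile where no t is available), sign-homogeneous 4-connected
components (adjacency in 1D; diagonals do not connect), cluster mass =
summed statistic, null distribution = maximum |mass| per permutation,
and corrected p = (1 + #{null >= observed}) / (1 + nPerm), which cannot
be zero. Labels are shuffled at trial level within participant and the
full group map recomputed per permutation; a participant-level sign-flip
scheme is available but not default. Non-finite statistic bins are
excluded from clustering. Component labeling is implemented in C++
because the calibration experiments evaluate hundreds of thousands of
permutation maps.

Under Gaussian nulls the measured family-wise error at alpha 0.05 is
0.05 +/- 0.02 on 8 x 10 maps; on very small maps the test becomes
conservative simply because many null datasets contain no
supra-threshold cluster at all.

## Problem sizes used in the validation experiments

The package's own validation (test suite and acceptance script) runs at
deliberately reduced scale, chosen as the smallest configurations that
still exercise every stage end to end: FWER calibration on 1,000
synthetic datasets x 500 permutations (8 x 10 bins, 10 participants);
pipeline null calibration on 100 cohorts of 4 participants with a
two-contact AMY and all effect gains zero; recovery on 20 cohorts of 8
participants with a three-contact AMY at the default (SNR ~ 1) gains,
with 200-500 permutations per test and 50-ms TFR steps. Detection rates
at these scales are reported as proportions of cohorts; the acceptance
script re-runs smaller versions of the same experiments from a
user-supplied seed.

## Known limitations

* The generator plants multiplicative band-power signatures with random
  phases; phase-locked or cross-frequency structure is out of scope.
* Electrode localization, white-matter channel removal and atlas-based
  ROI labeling are outside the package: synthetic channel metadata is
  taken as ground truth.
* The frequency-domain filters assume the record is long relative to the
  filter's impulse response; the first/last ~5 s of a record carry edge
  transients (irrelevant here because epochs never start that early).
* The canonical analysis windows (0.8-1.15 s, 0.65-1 s, the 3-10 Hz x
  1.18-1.75 s theta band/window) are configuration defaults, not
  re-derived quantities.
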