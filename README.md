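# extinctRSA

Representational similarity analysis of context-dependent fear extinction
in intracranial EEG, with a fully synthetic, ground-truth-controlled data
generator.

## The problem

In a three-phase ABC conditioning experiment, patients implanted with
depth electrodes see three cues (CS++ always paired with an aversive
stimulus, CS+- paired during acquisition only, CS-- never paired),
embedded in context videos that change between acquisition, extinction
and test. Extinction learning is thought to create a new, highly
context-dependent memory trace that competes with the original fear
trace; its neurophysiological signatures include amygdala theta
(3-10 Hz) power increases for currently safe cues, stable spectral
patterns of individual items, and context-specific patterns in
hippocampus and lateral prefrontal cortex, whose reinstatement at test
predicts renewal and safety ratings.

`extinctRSA` implements the complete analysis chain for this paradigm:

* **schedules** — pseudo-randomized three-phase designs (24/24/16
  presentations per cue, run-length cap 3, 50% reinforcement, balanced
  disjoint context pools) with validation;
* **synthetic data** — continuous multichannel iEEG (1 kHz, 1/f
  background, common-mode component) with plantable effects: theta-band
  "safety" power, per-cue and per-context spectral-spatial signatures,
  epileptiform-like transients, plus learning-curve ratings;
* **preprocessing** — zero-phase band/notch filtering, bipolar
  referencing, the three-criterion (amplitude / gradient / 250 Hz
  high-pass, |z| >= 6 or 4-and-3) artifact detector with +/-1 s padding,
  7-s cue-locked epoching with ROI-level rejection;
* **spectral analysis** — variable-cycle Morlet decomposition on the
  44-frequency grid (1-29 Hz, 3-6 cycles; 30-100 Hz, 6-12 cycles),
  z-scoring against all trials, CS+ vs CS- time-frequency contrasts;
* **RSA** — sliding-window (500 ms / 50 ms, 90% overlap) Spearman
  pattern similarity; item stability and context specificity at contrast
  and single-trial level (Fisher-z throughout);
* **coordination** — cross-ROI temporal generalization maps of
  single-trial metrics; theta-to-representation correlations;
* **reinstatement** — cross-phase similarity, differential reinstatement
  REINST = REINST_ACQ - REINST_EXT, across-participant coupling with
  context specificity, and trial-level reinstatement-to-rating coupling;
* **statistics** — cluster-based permutation correction (1D, 2D
  time-frequency, 2D time x time; trial-label shuffling within
  participant, max-cluster-mass null, p = (1+k)/(1+nPerm)),
  trial-position Wilcoxon learning curves, two-way repeated-measures
  ANOVA with partial eta squared, Fisher z, Bonferroni (0.05/5 ROIs).

The central statistic: for each region, per-trial feature vectors are the
z-scored power of N channels x 44 frequencies in 500-ms windows; item
stability is the mean Fisher-z Spearman correlation of a cue's patterns
across its repeated presentations, context specificity the mean
same-context minus different-context pair correlation, and every group
test is corrected by comparing observed cluster masses against the
permutation distribution of the maximum cluster mass.

## A worked example

Simulate an 8-participant extinction-phase cohort with the default
planted effects, process it end to end, and test the theta contrast:

```r
library(extinctRSA)

gen  <- generatorConfig(rois = c(AMY = 3))
proc <- simulateCohort(8, designConfig(), gen, seed = 7,
                       phases = "extinction", ratings = FALSE,
                       process = function(p)
                         processParticipant(p, rois = "AMY",
                                            timeStep = 0.05))

theta <- cohortThetaContrast(proc, "AMY", freqRange = c(1, 12),
                             nPerm = 500, seed = 1)
subset(clusters(theta$test), p <= 0.05)
#>   cluster     sign      mass nBins           p rowMin rowMax colMin colMax
#> 7       7 negative -1234.551   118 0.001996008      3     12   1.15   1.75
```

The significant negative cluster (higher theta power for currently safe
CS- cues) spans 3-12 Hz from 1.15 to 1.75 s after cue onset — recovering
the planted 3-10 Hz x 1.18-1.75 s safety effect. `rowMin`/`rowMax` are Hz,
`colMin`/`colMax` seconds after cue onset, `mass` the summed t statistic,
and `p` the cluster-corrected permutation p value (500 permutations, so
the smallest attainable p is 1/501).

Item stability and context specificity from the same cohort:

```r
sims <- cohortSimilarities(proc, "AMY")
it <- cohortItemStability(proc, "AMY", nPerm = 500, seed = 2, sims = sims)
subset(clusters(it$test), p <= 0.05 & sign == "positive")
#>   cluster     sign     mass nBins           p rowMin rowMax colMin colMax
#> 1       1 positive 104.3268    21 0.001996008      1      1   0.25   1.25
```

a positive cluster: more stable patterns for the currently threatening
item across window centres 0.25-1.25 s, as planted.

The orchestrated variant (`runPipeline(pipelineConfig())`) runs
simulation, preprocessing, decomposition, the behavioural analyses and
all contrasts from one seeded configuration and writes a JSON report with
a config hash and all derived seeds.

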