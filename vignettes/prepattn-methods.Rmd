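---
title: "prepattn: models, design decisions and what the synthetic tests show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{prepattn: models, design decisions and what the synthetic tests show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`prepattn` implements a complete desk-scale pipeline for studying
*memory-guided attention* with fMRI: a two-task experiment in which
participants attend either to the artistic style of a painting or to the
spatial layout of a room, selecting that attentional state each trial either
from an explicit instruction or from memory for learned stay/switch cues
embedded in the previous trial's search images. This vignette is the
package's own account of the underlying models, the free parameters and
their defaults, the numerical decisions, and — importantly — what passing
the synthetic tests does and does not establish about real data.

## The experiment model

A schedule (`buildSchedule()`) covers two tasks x 4 runs x 25 trials. Each
trial is: an initiation screen (until a key press), an attention cue shown
for 1.5/2/2.5 s, a base image for 2 s, four search images for 1.25 s each
preceded by 0.1 s gaps, and a probe for up to 2 s, followed by a variable
ITI. The *image period* (base onset to last search offset) therefore always
spans 7.4 s. Constraints honored by the scheduler:

* 80% of trials are *valid* (probe matches the trial's attentional state);
* task-relevant and task-irrelevant matches are each present on half of the
  trials, independently, spread over state x validity x cue-type cells as
  equally as possible (seeded greedy assignment);
* a stay/switch cue image is embedded on two-thirds of trials (33/33/34
  stay/switch/none per 100-trial task, a fixed remainder rule), always
  matching the trial's state dimension;
* each of the 20 base images appears exactly once in every aligned,
  non-overlapping 20-trial window and never on consecutive trials. We chose
  aligned windows (rather than a sliding constraint) as the simplest rule
  consistent with the once-per-20-trials constraint; windows may span run boundaries
  because runs hold 25 trials.

In the memory-guided task the state sequence is generated *forward* through
the stay/switch logic (`deriveNextState()`): the first trial of each run and
every trial following a no-cue trial is a free choice. Free choices are made
greedily to keep art/room counts near balance, emulating the instruction to
choose both states about equally often; an error-free replay of the cue
logic over any generated schedule reproduces the stored state labels
exactly (a test asserts this).

**ITIs.** The conventional summary of this ITI set (exponential, rate 1.5,
truncated at 9 s, mean 6.66 s) is internally inconsistent: a
positive-rate exponential truncated at 9 s cannot have a mean above 4.5 s.
We therefore treat the truncated-exponential *family* (including negative
rates, i.e. increasing densities) as the shape and numerically calibrate the
rate so that the fixed 25-value inverse-CDF set has mean 6.66 s exactly
(`sampleItis()`); only the per-run ordering is random. This is a documented
reconstruction of the stated summary properties, not a particular published
sampler.

## The behavioral model

`simulateBehavior()` draws match responses from validity-conditioned hit and
false-alarm rates, so valid-trial sensitivity is above chance and
invalid-trial sensitivity is at chance under the defaults (hits 0.8 / false
alarms 0.2 on valid trials; 0.5/0.5 on invalid). Stay/switch decisions are
correct with probability `selection_accuracy` (default 0.95, the
well-trained regime); an error flips the chosen state, the trial proceeds in
the chosen state with the probe unchanged, and downstream states re-derive
from the participant's own (erroneous) chain. Free choices follow the
schedule's recorded choices by default: the schedule's balancer plays the
role of the participant's own balancing instruction, keeping experienced
validity at the designed 80%. Setting `free_choice = "random"` draws them
anew with `free_choice_art_prob` instead, in which case experienced validity
deviates on free-choice successors because probes are fixed at design time.

Sensitivity is summarized with the standard nonparametric A' (`aPrime()`),
including the symmetric below-chance branch; the textbook form is adopted
(no single canonical formula exists in the literature) and pinned by tests
(chance at H = F, perfect at H = 1, F = 0, monotonicity in both arguments).

## The BOLD forward model

`simulateBold()` generates voxels x volumes matrices per region and run
(TR 1.5 s, volumes sampled at acquisition midpoints, 4 leading volumes
generated and discarded). The neural drive is

* during each image period: `baseline + g_t * image_amp * pattern(state_t)`,
* during each orienting period: `prep_amp(task) * pattern(state_t)` (or the
  *previous* trial's pattern under `prep_target = "previous"`, the retrieval
  emulation used by the switch-only control tests),

convolved with a double-gamma HRF on a 0.1 s grid. The art/room patterns
are unit-norm, zero-mean voxel vectors with exactly the requested
correlation (`makeStatePatterns()`; at 2 voxels centered vectors can only
correlate at +/-1, so the 2-voxel contract is in the inner-product sense).
The trial fidelity factor `g_t` is a unit-mean log-normal (log-SD
`fidelity_sd`), shared across regions through a latent factor with
correlation `quality_coupling_rho` per task — this is the ground truth the
informational-connectivity analysis should recover. Noise is stationary
AR(1) per voxel plus a random-phase slow sinusoidal drift.

The double-gamma is parameterized so that the positive lobe's *mode* equals
the configured peak delay (shape = delay/dispersion + 1; defaults: peak 6 s,
undershoot 16 s, dispersions 1 s, peak:undershoot 6, unit peak amplitude).

**The SNR operating point is a free parameter.** No generative SNR is
published for this paradigm; the defaults (`image_amp = 0.5`, `prep_amp_memory =
0.25`, `prep_amp_explicit = 0.1`, `noise_sd = 1`, `ar1_coef = 0.3`,
`drift_amp = 0.5`, `fidelity_sd = 0.4`, coupling 0.5 vs 0) were chosen once,
by forward simulation, to land measured effects in a moderate regime typical
of reported ROI studies — informational connectivity near r = 0.2 for the
memory task and
near 0 for the explicit task, same-state minus different-state image
similarity around 0.2 on the r scale, and preparatory indices of a few
hundredths on the z scale — while remaining reliably recoverable at group
sizes of 12-29 simulated participants. They are not estimates of any real
dataset.

## Preprocessing and pattern extraction

Each run is z-scored across time within voxel (`zscoreRun()`; zero-variance
voxels map to zeros). Period volumes are selected after shifting the period
forward by 6 s (4 TRs): a volume counts if at least half of its 1.5 s
acquisition overlaps the shifted period, with exact halves counting as in
(the inclusive reading of the at-least-half rule; volumes live on the half-open
grid `[k*TR, (k+1)*TR)`). Boundary trims follow the conservative convention:
the orienting period drops its last selected volume *unless* it is the only
volume covering the attention cue; image-period patterns used for templates
drop their first and last volumes; the main image-period similarity uses no
trim. `selectPeriodTrs()` is the reference implementation; bulk extraction
uses an algebraically identical vectorized path (selections are always
contiguous volume ranges) that the test suite checks against the per-trial
reference.

## Analyses

* **Image-period state similarity** (`imageStateSimilarity()`): Pearson
  correlations between all cross-run trial pairs within a task, Fisher
  transformed, averaged for same-state pairs (art-art and room-room each
  averaged first, so states weigh equally) versus different-state pairs.
  Correlations of exactly +/-1 are clipped to +/-(1 - 1e-12) before the
  transform so degenerate fixtures stay finite.
* **State templates** (`buildTemplates()`): mean image-period patterns per
  state, always excluding the analyzed trial's own run (the leave-one-run-out
  provider, `templateProvider()`); options select valid-only trials (default
  yes), templates common across tasks (default yes) or per task, and trimmed
  or untrimmed source patterns.
* **Preparatory index** (`preparatoryIndex()`): per orienting period,
  `z(corr with same-state template) - z(corr with different-state
  template)`, averaged within state and then across states; the first trial
  of each run is excluded. Subsets expose the robustness variants:
  all orienting periods, only those following a stay/switch cue, or only
  those following a switch cue — the retrieval-vs-preparation control, where
  a positive index means the orienting pattern resembles the *upcoming*
  rather than the previous state.
* **Informational connectivity** (`qualitySeries()`,
  `multivariateConnectivity()`): per-trial same-minus-different template
  match ("attentional-state quality") per region, correlated across regions
  over a task's trials; the per-trial difference is taken on the Fisher-z
  scale by default (`scale = "r"` exposes the raw-difference variant).
  Connectivity is computed per task; a valid-only flag is exposed.
* **Univariate GLM** (`buildDesign()`, `highpassBasis()`, `fitGlmRoi()`):
  single-trial boxcar designs (image-locked: 25 + pooled orienting + pooled
  probe; orienting-locked: one boxcar per orienting period with the first
  trial of each run excluded at the design stage, plus pooled image and
  probe), HRF-convolved, fitted by per-voxel OLS after projecting out a
  DCT drift basis (cutoff 128 s) from data and design. We use OLS without
  prewhitening: inference in this artifact is across simulated participants,
  not within run, so run-level autocorrelation correction buys nothing the
  group test needs. An alternative convention models all 25 orienting
  regressors and drops the first trial's estimate afterwards; excluding it
  from the design instead (24 + 2 regressors) leaves that orienting period
  unmodeled, which is immaterial for the ROI contrast.
* **Searchlight** (`cubeNeighborhoods()`, `searchlightMap()`,
  `groupSearchlight()`): the identical preparatory-index pipeline run on
  every full 3 x 3 x 3 voxel cube inside a mask, the value assigned to the
  center voxel. Cubes partially outside the mask are skipped entirely — only complete cubes count — so maps are defined
  exactly at interior centers. Group inference is a voxelwise one-sample
  sign-flip permutation with max-statistic FWE correction
  (`signFlipPermutation()`, add-one p-values, threshold at the 95th
  percentile of the max-statistic null).
* **Robust skipped correlation** (`skippedCorrelation()`): minimum
  covariance determinant center (subset size floor((n+3)/2) for bivariate
  data; exhaustive elemental-subset search at small n, seeded subsampling
  otherwise; a coordinatewise-median fallback covers exactly collinear
  clouds where the MCD scatter is singular), orthogonal projections onto
  point-center lines, standard 1.5 x IQR boxplot fences per projection
  (quartiles via type-7 quantiles) with the union over projections flagged,
  then Pearson on the retained points. Robust-correlation toolboxes differ in their exact
  fence variant, so the fence multiplier is exposed.

## Group statistics

Paired and one-sample t tests report exact statistics with paired Cohen's d
(mean difference over the SD of differences) and 95% CIs; the 2 x 2
repeated-measures ANOVA (task x validity, on A') reports within-subject F
tests with partial eta squared, and for two-level factors each F provably
equals the squared paired t (asserted in tests). All p-values are two-sided,
matching the field's reporting conventions.

## A genuine property worth knowing: hemodynamic carry-over into the orienting window

The shift-by-6-s selection treats the BOLD signal at time *t* as reflecting
neural activity at *t - 6* only. The double-gamma HRF is dispersed, not a
delta at 6 s: volumes acquired 3-6 s after the base-image onset already
carry part of the image-period response, and those volumes fall inside the
shifted orienting window. Because the image-period pattern always matches
the *upcoming* state, this carry-over biases the per-task preparatory index
positive even when the generator contains no preparatory drive at all
(measured at the defaults: a null-index mean of ~0.056 z against a
between-participant SD of ~0.025). Dropping the last orienting volume — the
conservative rule, implemented here — removes only part of it, and the
only-cue-volume exception deliberately retains late volumes so that the
attentional state is known during the retained window.

Consequences: the one-sample test on a single task's preparatory index is
*not* calibrated under the null in this forward model, and the package's
acceptance suite reports that honestly (the corresponding calibration check
fails, by a wide margin, for any material image amplitude — the bias scales
linearly with it). The *task difference* is clean, because the carry-over is
identical in both tasks. Informational connectivity inherits a milder form
of the same physics: adjacent trials' image responses overlap across the
short ITIs, so each trial's quality score carries a sequence-locked
component (whether neighboring trials share its state) that is identical
for regions experiencing the same trial sequence. Under zero generative
coupling this inflates the null connectivity mean slightly (about +0.017 z
at the defaults; it vanishes when the image signal is removed and persists
without fidelity variance or AR/drift noise), pushing the one-sample
rejection rate to roughly 0.10 at the 0.05 level — the shared-structure
confound known from the informational-connectivity literature. This is a
property of the analysis design,
not of the implementation; it is one plausible contributor to a positive
explicit-task index in real data, and it is exactly why the switch-only
control matters: under carry-over alone the switch-only index stays positive
only if orienting activity resembles the upcoming state, whereas genuine
retrieval of the previous state drives it negative. The generator exposes
both hypotheses via `prep_target`.

## Reproducibility and problem sizes

All randomness flows from one seed through a documented splitting scheme
(`childSeed()`): the same seed and key path always give the same stream, so
stages and participants can be re-run in isolation. Schedules, catalogs and
BOLD matrices are bit-reproducible under a fixed seed.

The test suite runs entirely on synthetic data at desk scale: regions of
15-50 voxels, groups of 12-29 simulated participants, 100-1000 simulated
group datasets for calibration and recovery checks, searchlight grids up to
8^3, and 200-10000 permutations/replicates for the statistical calibration
checks. Null calibration shares one schedule across datasets (only noise,
drift, fidelity factors and patterns resample); recovery checks likewise.
These sizes were chosen so the whole suite completes on a single CPU in
minutes while keeping Monte-Carlo error well inside the asserted bands.

What passing these tests shows: the machinery is internally correct (oracle
equivalences, exact recoveries, calibrated where calibration is
attainable), and the full chain recovers the qualitative generative pattern
— stronger preparatory coding and coupling for memory-guided attention —
under known ground truth. What it does not show: anything about real
neural data. The generator has stationary Gaussian AR(1) noise, sinusoidal
drift, no motion, no physiological noise, no spatial autocorrelation, no
voxel-size or smoothing effects, and its SNR is a chosen operating point.

## Known limitations

* Real-data mode reads 4D NIfTI + mask + event TSVs
  (`readBoldRegion()`, the event-table writer exercises the format), but
  scanner preprocessing (motion correction, unwarping, registration,
  smoothing) is out of scope; inputs are assumed preprocessed.
* No prewhitening; within-run GLM inference is not supported by design.
* The searchlight skips partial cubes; anatomically tight masks lose edge
  voxels.
* The ITI construction matches the stated mean and truncation, not any
  particular published sampler.
* Cue durations are drawn uniformly from {1.5, 2, 2.5} s with per-run
  balance; other distributions can be supplied via the design config.
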