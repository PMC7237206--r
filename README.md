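# prepattn

Template-based analysis of preparatory attentional states in fMRI, as a
tested, reusable, desk-scale pipeline.

## The problem

In memory-guided attention experiments, participants attend on each trial to
one of two features of composite images — the artistic style of a painting
("art" state) or the spatial layout of a room ("room" state) — and select
that state either from an explicit instruction or from memory for learned
stay/switch cues embedded in the previous trial's search images. The
scientific questions are whether brain regions (1) represent the *current*
attentional state during search, (2) represent the *upcoming* state already
during the pre-trial orienting period — preparatory coding — especially when
the state must be selected from memory, and (3) coordinate trial-by-trial
attentional-state quality across regions (informational connectivity).

`prepattn` is for methodologists and students of these paradigms: it
generates the full two-task experiment design, simulates behavior and BOLD
with known ground truth, and implements the analysis stack so every stage is
verifiable by parameter recovery and design-constant checks without any
data download.

## The core quantities

For trial *t* with voxel pattern **p**ₜ (period-averaged, run-wise z-scored,
hemodynamically shifted by 6 s), and leave-one-run-out state templates
**T**_art, **T**_room built from image-period patterns:

* image-period state similarity: mean Fisher-z Pearson correlation of
  cross-run trial pairs, same state (art–art, room–room) vs different state;
* preparatory index (orienting period):
  `z(r(pₜ, T_same)) − z(r(pₜ, T_diff))`, averaged within and then across
  states — positive values mean the orienting pattern resembles the
  *upcoming* state;
* attentional-state quality: the same difference for image-period patterns,
  per trial; informational connectivity = Pearson correlation of two
  regions' quality series across a task's trials;
* univariate single-trial GLM (double-gamma HRF, DCT high-pass at 128 s)
  with ROI-mean estimates and a robust *skipped correlation*
  (MCD center → projections → 1.5×IQR fences → Pearson) for
  individual-difference analyses;
* a 27-voxel cube searchlight running the identical preparatory analysis per
  neighborhood, with group sign-flip max-statistic FWE inference;
* nonparametric sensitivity A′ with a 2×2 repeated-measures ANOVA
  (task × cue validity) for behavior.

## Worked example

```r
library(prepattn)
cfg <- pipelineConfig(seed = 1, n_participants = 12)
bundle <- runPipeline(cfg)
print(bundle$group$preparatory_task_diff, digits = 3)
#>        region mean_diff_z    t dof        p     d
#> 1 hippocampus      0.0412 2.92  11 1.40e-02 0.842
#> 2         v12      0.0758 6.61  11 3.83e-05 1.907
#> 3       vmpfc      0.0572 4.72  11 6.25e-04 1.364
print(bundle$group$connectivity, digits = 3)
#>            task mean_r mean_z    t dof        p    d
#> 1      explicit 0.0337 0.0341 1.25  11 2.39e-01 0.36
#> 2 memory_guided 0.2338 0.2406 7.70  11 9.41e-06 2.22
print(bundle$group$behavior_anova, digits = 3)
#>          effect       F df1 df2        p partial_eta_sq
#> 1          task   0.453   1  11 5.15e-01         0.0395
#> 2      validity 193.282   1  11 2.53e-08         0.9462
#> 3 task:validity   0.169   1  11 6.89e-01         0.0152
```

Reading the output: the generator's defaults plant preparatory drive and
inter-region coupling that are stronger for the memory-guided task, and the
pipeline recovers exactly that pattern — a positive memory-minus-explicit
preparatory-index difference in every region (first table), informational
connectivity above zero only for the memory-guided task with a significant
task difference (second table), and behavior showing a large cue-validity
effect on A′ with no task main effect (third table), i.e. the two tasks are
matched in difficulty while attention is clearly cued.

`writeResultBundle(bundle, "out/")` serializes all participant-level tables
(CSV) with group results, config and a checksummed manifest;
`readResultBundle("out/")` restores and verifies them. A thin CLI wrapper
with `simulate` / `analyze` / `report` subcommands lives at
`inst/cli/prepattn.R`. Event tables are written in a BIDS-events-like TSV
dialect; region matrices can be written to and read from 4D NIfTI against a
binary mask.

The methods vignette (`vignettes/prepattn-methods.Rmd`) documents the
models, every tunable parameter, the numerical decisions, and one genuine
property of the analysis worth knowing before interpreting per-task
preparatory indices: hemodynamic carry-over of the image period into the
shifted orienting window biases single-task indices positive, while task
differences and the switch-only control remain clean.

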