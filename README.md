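# tcfsim

Simulation and analysis of **tracking continuous flash suppression
(tCFS)** experiments with moving dot stimuli.

## What problem this addresses

In continuous flash suppression (CFS), a high-contrast dynamic Mondrian
mask shown to one eye suppresses a target shown to the other eye from
awareness. Classic "breaking CFS" studies measure only how long (or at
what contrast) a target takes to break into awareness, which cannot
distinguish genuinely deeper suppression from an overall sensitivity
shift. The tracking variant ramps target contrast continuously: down until
the visible target is re-suppressed (reCFS threshold), then up until it
breaks through again (bCFS threshold), zig-zagging for 12 responses per
trial. **Suppression depth** is the difference

```
depth [dB] = mean(bCFS) − mean(reCFS),   dB = 20·log10(contrast)
```

— the contrast range over which the target stays suppressed. Comparing
suppression depth across stimulus manipulations (inverting a point-light
walker, scrambling its dots in space or time, changing its speed,
replacing it with radial optic flow, varying mask contrast) asks whether
interocular suppression cares about high-level structure or only local
motion.

No human data ships with this package. Instead, `tcfsim` is built for
*parameter recovery*: it simulates the complete experiments against a
stochastic observer population with planted thresholds, then runs the
standard analysis pipeline and checks that the planted values come back.
It is aimed at psychophysicists who want to prototype tCFS designs, test
analysis code against ground truth, or quantify biases (frame
quantisation, reaction delay) before collecting data.

## What's inside

* **Stimuli** — `synth_gait()` (31-dot, 300-frame looped procedural
  walker), `project()`, `rotate_vertical()`, `extract_static()`,
  `scale_speed()`, `invert_animation()`, `spatial_scramble()`,
  `temporal_scramble()`, `coherent_optic_flow()`, `scrambled_optic_flow()`,
  plain-text trajectory I/O.
* **Masks** — `make_mondrian()`, `mask_sequence()`: overlapping-circle
  patterns at a controlled RMS contrast (pixel SD), refreshed at 12 Hz.
* **Engine** — `run_trial()`, `run_session()`: the dB-linear
  contrast-tracking state machine (0.07 dB/frame at 60 Hz, clamped to
  [−33.98, 0] dB, 12 alternating responses starting with reCFS).
* **Observers** — `observer_params()`, `population_params()`,
  `generate_dataset()`: planted bCFS/depth levels, participant random
  intercepts, threshold jitter, lapses, reaction delay; presets for the
  three experiment layouts (4×8, 6×8, 5×8 trials×blocks).
* **Analysis** — `screen_participants()`, `aggregate_thresholds()`,
  `within_subject_sem()`, `rm_anova()` (fully within-subject, partial eta
  squared), `posthoc_pairwise()` (Bonferroni, Cohen's d),
  `analyze_tcfs()`, `report_tcfs()`.

## Worked example

Simulate the four-condition biomotion experiment at its published sample
size (15 participants, planted condition depths 13.22–13.95 dB, planted
bCFS −10.4 dB) and recover the planted structure:

```r
library(tcfsim)
log <- generate_dataset(1, seed = 42)   # 5,760 threshold responses
res <- analyze_tcfs(log)

res$grand_means
#>   bcfs_db recfs_db depth_db
#> 1   -10.4    -23.8     13.5

res$condition_means
#>   condition mean_bcfs_db mean_recfs_db mean_depth_db sd_depth_db
#> 1 Inverted         -10.4         -23.7          13.4        1.53
#> 2 SpatScr          -10.4         -24.4          14.0        1.50
#> 3 TempScr          -10.3         -23.6          13.3        1.48
#> 4 Upright          -10.3         -23.6          13.3        1.43

res$anova_depth
#>   effect    df_num df_den   ss ss_error    F        p partial_eta_sq
#> 1 condition      3     42 5.71     1.41 56.8 7.74e-15          0.802
```

The grand means land on the planted −10.4 dB (bCFS) and −23.8 dB (reCFS);
each condition's mean depth recovers its planted value to within ~0.1 dB
(the ~0.07 dB excess over the planted depths is the expected
frame-quantisation bias of a 0.07 dB/frame staircase, documented in the
vignette). The one-way repeated-measures ANOVA on depth and the Bonferroni
post hocs single out the spatially scrambled condition — the one planted
with a deeper suppression:

```r
dplyr::select(res$posthoc_depth, pair, t, p_bonferroni, cohens_d)
#>   pair                     t p_bonferroni cohens_d
#> 1 Inverted - SpatScr -10.1    0.000000524  -0.430
#> 2 Inverted - TempScr   1.10   1             0.055
#> ...
```

`report_tcfs(log, res, "out/")` writes the summary/ANOVA/post hoc CSVs and
the standard figure panels (threshold-by-response traces, bCFS/reCFS dot
plots, depth bars with within-participant SEM).

Command-line wrappers live in `inst/scripts/`
(`simulate.R`, `analyze.R`).

## Documentation

The methods vignette (`vignettes/tcfs-simulation.Rmd`) describes the
stimulus models, the engine's threshold-crossing rules and their biases,
the observer population model and what it does and does not emulate, the
statistical conventions (uncorrected dfs, d_av effect sizes, the 10%
clamp screening rule), and all numerical design choices.
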