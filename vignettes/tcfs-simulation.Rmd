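---
title: "Simulating and analysing tracking continuous flash suppression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing tracking continuous flash suppression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcfsim)
```

## The method

Continuous flash suppression (CFS) presents a high-contrast dynamic
Mondrian mask to one eye and a weak target to the other; the mask keeps the
target out of awareness for extended periods. The *tracking* variant (tCFS)
turns the classic breakthrough measurement into a continuous staircase: the
target starts at maximum contrast and ramps *down* until the observer
reports it has vanished (the re-suppression threshold, reCFS), then ramps
*up* until it breaks back into awareness (the breakthrough threshold,
bCFS), and so on, zig-zagging for a fixed number of responses. The
difference

$$\text{suppression depth} = \overline{\text{bCFS}} - \overline{\text{reCFS}} \quad [\mathrm{dB}]$$

is the contrast range over which the target remains suppressed, a direct
measure of suppression strength that a one-directional breakthrough time
cannot provide.

Contrast is expressed in decibels of normalised Michelson-style contrast,
$c \in (0, 1]$, with $\mathrm{dB} = 20\log_{10} c$. The coded target range
0.02–1.0 maps to $[-33.98, 0]$ dB. Ramps move linearly in dB (0.07
dB/frame at 60 Hz, i.e. 4.2 dB/s), which perceptually linearises the
contrast change.

`tcfsim` reproduces this paradigm end-to-end in simulation: dot-motion
stimuli and their manipulations, masks with controlled RMS contrast, the
trial state machine, a stochastic observer population, and the
repeated-measures analysis pipeline that recovers suppression depth.

## Stimuli

### The walker

`synth_gait()` produces the 31-dot, 300-frame looped point-light walker
used as the base stimulus in all conditions. The walker is a procedural
two-level kinematic model: a trunk carrier with vertical bob at twice the
step rate plus sinusoidal limb pendula at the step rate (legs antiphase,
arms counter-swinging, distal joints phase-lagged). Several markers are
deliberately clustered at the head, neck, shoulders and hips, reproducing
the overlap property of toolbox-rendered walkers that matters for the
spatial-scramble comparison. The procedural skeleton is a synthetic
stand-in for a motion-capture actor: the scientific claims tested here
hinge on local dot kinematics, not on a specific gait recording.

One numerical conflict is worth spelling out. A 300-frame loop at 60 Hz is
5 s; at the nominal 1.05 steps/s that is 5.25 step cycles, which cannot
close seamlessly. Seamlessness is prioritised: the generator snaps the
loop to the nearest integer number of step cycles (5, i.e. an effective
1.0 steps/s) and records both the nominal and effective rates in the
animation metadata. Because every marker trajectory is a sum of first and
second harmonics of the step cycle, each marker is then exactly periodic
and the wrap-around displacement is no larger than any intra-loop step.

```{r walker}
walker <- synth_gait()
walker
attr(walker, "step_frequency_effective_hz")
```

### Manipulations

All transforms preserve dot count and frame count, and the three classic
"global form" manipulations preserve each dot's speed distribution over a
full loop exactly — the premise that local motion is untouched while
global structure is destroyed:

* `invert_animation()` reflects about the vertical centre (an isometry);
* `spatial_scramble()` redraws each dot's starting position uniformly in
  the subspace and replays its displacement series verbatim. Scrambled
  dots are *not* re-clipped to the subspace when their trajectories carry
  them outside (clipping would alter local motion); the out-of-bounds
  fraction is recorded on the result.
* `temporal_scramble()` cyclically shifts each dot's own looped trajectory
  by a random number of frames.

For the speed and flow conditions: `scale_speed(anim, 2)` shows the
identical sequence at twice the rate by nearest-frame resampling (frame
skipping, not interpolation — the mean finite-difference speed doubles up
to slight chord shortening on curved trajectories); `extract_static()`
freezes the maximum-stride frame (index 40; the generator is 0-based, and
a 1-based interpretation is available via `index_base` since the original
convention is unknowable — the two differ by one frame in 300);
`coherent_optic_flow()` moves each dot radially about the display centre,

$$r_i(t) = r_{0i}\,\bigl(1 + 0.2\,\mathrm{amp}\,\sin(2\pi t/\mathrm{modperiod} + \varphi_i)\bigr),$$

with all $\varphi_i = 0$, so local speed is proportional to eccentricity;
`scrambled_optic_flow()` uses per-dot uniform random phases. The source
description of the scrambled variant is ambiguous — its printed expression
randomises the modulation *period*, while the stated intent (twice) is a
randomised starting *phase*. Random phase is the default here;
`literal_randoffsets = TRUE` reproduces the random-period reading.
`amp` defaults to 1 and `modperiod` to one step cycle (neither value is
specified by the study; both are configuration).

### Masks

`make_mondrian()` paints 300 overlapping circles (radii 2–20% of the image
side, uniform gray levels) on a mid-gray 400 × 400 px canvas and rescales
intensities affinely about the mean to a target RMS contrast (pixel SD on
the 0–1 scale) within ±0.005, restoring the 0.5 mean. The circle count
and radius distribution are unspecified upstream and are configuration
choices giving dense overlap. `mask_sequence()` refreshes patterns at 12
Hz within a 60 Hz playback stream (a new pattern every 5 frames). The
three mask-strength levels used in the mask-contrast experiment are RMS
0.07, 0.10 and 0.13; the single-mask experiments use 0.10, interpreting
the coded "maximum contrast value of 0.1" as the same RMS quantity (the
mask-contrast experiment states the medium level matches it).

## The engine and the synthetic observer

`run_trial()` is event-driven: for each reversal it computes the exact
frame at which the observer's (jittered) threshold is crossed, adds the
reaction delay, records the clamped contrast and flips direction. A
frame-by-frame reference engine (stepping one 0.07 dB frame at a time and
asking the response predicate at every frame) is kept internally and the
two are asserted to agree exactly in the test suite.

Observer thresholds are planted directly in measurement space: a bCFS
level, a suppression depth (reCFS = bCFS − depth), per-reversal Gaussian
jitter, an optional lapse probability (response at a uniformly random ramp
position) and an optional reaction delay in frames. Planting in
measurement space makes recoveries unbiased at zero delay; the study never
separates perceptual threshold from motor latency, so delay is an optional
realism knob, default 0. Two small systematic effects are worth knowing:

* **Quantisation**: responding at the first frame at or past threshold
  overshoots each threshold by up to one step (mean ≈ step/2), inflating
  measured depth by ≈ 0.07 dB. This is inherent to the frame-quantised
  staircase, not a bug.
* **Delay bias**: with reaction delay $d$ frames the ramp keeps moving
  during the delay, so measured depth exceeds planted depth by
  $2\,d \times 0.07$ dB. The test suite verifies this law over
  $d \in \{0, 15, 30, 60\}$.

`run_session()` presents each condition once per block in a freshly
randomised order (4 × 8, 6 × 8 and 5 × 8 trial-by-block presets), target
side alternating; `generate_dataset()` runs a whole sampled population
through sessions and returns the tidy trial log.

### The population generator

`population_params()` adds the hierarchical structure of a participant
sample: per-condition planted (bCFS, depth) pairs, and participant-level
random intercepts on both quantities, shared across conditions within a
participant. The shipped presets (`load_population_preset(1:3)`) plant the
published group condition means: depths 13.22/13.23/13.24/13.95 dB for the
four biomotion targets; 12.85–13.18 dB (grand 13.0) across the six
mask-by-orientation conditions; 12.11–13.53 dB across the five motion
types, with between-participant SDs of 1.5/3.6/2.9 dB and threshold-level
SD 3.0 dB. Per-condition bCFS levels are only partially published: the
four biomotion targets share the grand −10.4 dB (no significant bCFS
differences were reported), mask levels shift bCFS in tandem (−12.4/−10.4/
−8.4 dB for low/medium/high, the ±2 dB spacing being a package choice
consistent with the reported ordering), and the motion-type levels follow
the reported ordering (moving biomotion lowest, static highest). The
per-reversal jitter SD is not derivable from published group SDs; 1 dB is
the package default and is flagged as a free choice.

Intercept sampling is *exact-moment* by default (`empirical = TRUE`): the
sampled intercepts are standardised to sample mean 0 and sample SD equal
to the population SD. This is a deliberate design decision for
parameter-recovery work: recovered condition means then measure the
fidelity of the measurement machinery (engine + aggregation) rather than
finite-sample intercept noise, which at $n = 15$–$25$ with SDs of 1.5–3.6
dB would otherwise dominate. Set `empirical = FALSE` for fully random
sampling (used, e.g., in the variance-recovery tests).

What the generator does *not* emulate: serial dependence between
reversals, adaptation and slow drift over a session, criterion shifts,
asymmetric up/down jitter, correlated bCFS/depth intercepts, and any
stimulus-driven response behaviour (the engine consumes thresholds, not
rendered frames — rendering is available for export but is not in the
response loop). Passing recovery tests therefore show the pipeline is
correct and unbiased under the planted hierarchical model, not that the
model captures everything human observers do.

## Analysis pipeline

`analyze_tcfs()` chains the stages; each is exported separately.

* `screen_participants()` excludes participants with more than 10% of
  responses at a contrast clamp bound. The original exclusion rule is
  stated only as "ceiling or floor effects"; the 10% strict-greater
  criterion is the documented package default.
* `aggregate_thresholds()` averages the 48 bCFS and 48 reCFS responses per
  participant × condition (in the 8-block designs) and takes depth as the
  difference.
* `within_subject_sem()` subject-centres the repeated measures and applies
  the $\sqrt{J/(J-1)}$ small-sample factor, the standard
  within-participant error bar for repeated-measures plots.
* `rm_anova()` is the classical fully within-subject sums-of-squares
  decomposition: every effect is tested against its interaction with
  participants, with uncorrected (sphericity-assumed) degrees of freedom —
  matching the convention of the reported analyses; partial eta squared is
  $SS_e/(SS_e+SS_{err})$. It supports all the layouts used (2×4, 1×4,
  2×3×2, 1×6, 2×5, 1×5) and is verified against `stats::aov` error strata
  and, for two-level factors, against the squared paired $t$. A
  Greenhouse–Geisser correction is deliberately not applied by default
  since the reference analyses report uncorrected dfs.
* `posthoc_pairwise()` runs all pairwise paired $t$-tests with Bonferroni
  correction (multiplier = number of pairs, capped at 1). Cohen's d
  defaults to the average-SD variant
  $d_{av} = \bar{\Delta} / \tfrac{1}{2}(s_1 + s_2)$, which is the variant
  most consistent with published values of this kind; $d_z$ is available.
  Published d values of the reference analyses could not be reproduced
  exactly under any standard variant, and their sign convention is
  internally inconsistent; this package documents its variant (sign =
  first minus second level) rather than imitating those digits.
* `report_tcfs()` writes deterministic CSV tables and the three standard
  panels (threshold-by-response traces including the 0 dB trial start,
  bCFS/reCFS dot plots, depth bars with within-participant SEM), with each
  figure's data table alongside.

```{r pipeline}
log <- generate_dataset(1, n_participants = 6, seed = 7)
res <- analyze_tcfs(log)
res$grand_means
res$condition_means
res$anova_depth
```

## Numerical choices and degenerate inputs

* Ramp steps are exact multiples of 0.07 dB; all threshold crossings use a
  1e-9 dB epsilon so floating-point equality at a bound cannot flip a
  frame.
* At a clamp bound the ramp holds until the observer responds (no
  auto-reversal); such responses are flagged for screening.
* An observer that never responds trips a configurable frame-budget
  watchdog (`max_trial_frames`).
* Zero-circle masks, unreachable RMS targets after clipping, ragged
  trajectory files, out-of-range static frames, unbalanced ANOVA designs,
  single-condition SEM requests and sub-two-participant post hocs all fail
  fast with informative errors.
* Speed scaling uses nearest-frame sampling; non-integer factors resolve
  by `round()`.

## Problem sizes

The shipped tests and the acceptance script run the full pipeline at the
published sample sizes (15/20/25 participants, 8 blocks), which simulate
in seconds because the engine is event-driven. The ANOVA calibration test
uses 10,000 simulated null datasets of 10 participants × 4 conditions;
Monte-Carlo checks of transform properties use 30–100 seeds. These sizes
were chosen to make Monte-Carlo error comfortably smaller than the
assertion tolerances.

## Known limitations

* The walker is procedural, not motion-capture; its inter-marker
  correlation structure is stylised (pure harmonics of the step cycle).
* The observer is a planted-threshold model; it cannot generate emergent
  suppression phenomena (e.g. depth differences between conditions arise
  only if planted).
* `rm_anova()` handles balanced, fully within-subject designs only —
  exactly the designs simulated here.
* Bayesian model comparison of the reference analyses is out of scope.
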