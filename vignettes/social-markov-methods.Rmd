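---
title: "Modelling and measuring social-preference dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and measuring social-preference dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socialMarkov)
```

## The measurement problem

In a two-stimulus social preference (SP) test a subject rodent divides a
5-minute session between investigating a confined conspecific and an
object (or, in the social novelty preference variant, a familiar versus
a novel conspecific). Video tracking yields a raw log of investigation
intervals per stimulus. Two features of such logs drive every design
decision in this package:

* tracking fragments continuous investigation into pieces separated by
  sub-second gaps, so analysis begins with a *gap merge*: any gap
  strictly shorter than 0.5 s between consecutive same-stimulus events
  is treated as part of one bout (a gap of exactly 0.5 s is not merged,
  and the threshold is a parameter);
* group-level structure lives in *binned cohort curves* — 20-s-binned
  investigation time and stimulus-transition rate, mean ± SEM across
  subjects — rather than in single-session values.

One refinement of the merge rule is worth stating explicitly: merging
is per stimulus, but a gap that contains an investigation event of the
*other* stimulus is never bridged. A purely per-stimulus merge would,
when the animal darts to the other chamber and back within half a
second, produce bouts of the two stimuli that overlap in time — an
impossibility, since the animal investigates one chamber at a time. The
blocked merge keeps every processed session consistent with that
constraint. Simulated sessions are passed through the identical merge,
so model output and experimental data receive the same preprocessing.

Other conventions, chosen once and used everywhere:

* intervals are half-open `[onset, offset)` in decimal seconds;
* bout-duration categories: short `< 6` s, long `> 19` s, intermediate
  in between with both boundaries inclusive (the conventional labels
  "<6", "6-19", ">19" leave the boundary values to the implementation;
  placing them in the middle category is the reading that keeps both
  extreme classes strict);
* bouts *starting* during the final minute are excluded from bout-level
  analyses — the end of the session truncates them toward artificially
  short durations. A bout that starts earlier and spans into the last
  minute is kept whole, since its onset was unconstrained;
* the first bout of a session counts as a stimulus transition by
  default (it begins investigation of a new stimulus); the convention
  is a flag because raster-style displays sometimes omit it;
* the relative differential investigation index,
  `RDI = |t1 - t2| / (t1 + t2)`, is undefined when the animal
  investigated nothing; that case returns `NA` with a warning rather
  than a silent zero;
* the arena "center" for occupancy ratios is the concentric region
  holding 30% of the arena *area* (linear scale `sqrt(0.3)`); "inner
  30%" is dimensionally ambiguous and the area reading matches how
  open-field centers are usually defined;
* in the two-class contact split (short `< 6` s vs long), a contact of
  exactly 6 s is counted as long so the classes always partition the
  total;
* per-bin mean bout duration is `NA`, not 0, for bins without onsets,
  and missing values propagate into cohort means as "mean over
  available subjects".

## The behavioral Markov model

The simulator is a discrete-time Markov chain over four states:
investigating stimulus 1 (S1), investigating stimulus 2 (S2), stillness
(S3), and arena exploration (S4). Direct S1↔S2, S1↔S4 and S2↔S4 moves
are structurally forbidden: switching stimuli or starting to explore
always passes through stillness, where the next behavior is chosen.

Two latent quantities evolve as the session unfolds. Each stimulus
carries a reward value

    r_i(t) = r_i0 * exp(s * T_i / tau_r),

where `T_i` is the cumulative time spent investigating stimulus *i*,
`s = +1` for mice (familiarity builds social reward) and `s = -1` for
rats (novelty-driven reward depletes with exposure). Anxiety decays
with habituation to the arena and is relieved by a decisive reward
difference between the stimuli:

    a(t) = a0 * exp(-t / tau_a) - |r1 - r2|.

The transition rows are:

* from S1 (resp. S2): stay with probability
  `sigmoid(beta1_r * r_i + beta1_a * a)`, otherwise fall to stillness;
* from S3: softmax over the four logits
  `{beta2_r * r1, beta2_r * r2, S0 * beta2_a * a, E0}` for S1, S2,
  stay-still, and explore. (A common written form of this row repeats one
  denominator term; the softmax over the four distinct logits is the
  only normalization under which the row sums to one, and is what the
  package implements.);
* from S4: keep exploring with probability
  `sigmoid(S0 + E0 - beta2_a * a)`, otherwise fall to stillness.

Every step the chain advances one time unit, increments `T_1` or `T_2`
if the step was spent investigating (including the entry step), and
recomputes `r_1`, `r_2`, `a` — anxiety uses the *current*, time-varying
rewards, so the conflict term grows as preferences develop. `a(t)` may
go negative late in a session; the formula is left unclamped by default
(a `clampAnxiety` switch exists for sensitivity analyses) because
clamping alters the exploration dynamics the parameters were fitted
under. The chain starts in stillness (configurable): animals typically
freeze briefly when the partitions are lifted.

Dwell runs in S1/S2 become investigation events, which then pass
through the standard 0.5-s gap merge like any experimental log.

### Parameters

`modelPreset()` ships the four fitted parameter columns (mouse/rat ×
SP/SNP). Shared values: `a0 = 7.66`, `tau_a = 10355.62`,
`beta1_r = 1.1`, `beta2_r = 1.12`, `beta1_a = -0.08`, `beta2_a = 0.71`,
`S0 = 2.72`, `E0 = 5.19`. Per regime: initial rewards
(`mice_SP` 4.98/4.72, `mice_SNP` 4.70/4.90, `rats_SP` 5.80/4.72,
`rats_SNP` 5.05/5.30) and `tau_r` (100406 for mice, 33406 for rats; the
two values are taken to split by species, which is how the preset table
reads most naturally). In the SNP presets stimulus 2 is treated as the
novel animal — its initial reward is the one close to the SP value in
rats and the larger one in mice, consistent with novelty carrying the
higher initial social reward.

### Time calibration

The preset time constants are expressed in Markov *steps*, and no step
length in behavioral seconds accompanies them. The step length is
therefore an explicit calibration, `calibrateTimeScale()`, scored over
the candidate grid {0.001, 0.01, 0.1, 1} s/step on two requirements a
realistic mouse SP session must meet: investigation-bout durations
concentrated between 1 and 40 s, and a cohort-mean transition-rate
curve that rises to an early peak and settles lower by the final two
minutes. Only 0.01 s/step satisfies both — at 0.1 s/step and above the
anxiety time constant (10355.62 steps ≈ 17 min and longer) exceeds the
whole session, so anxiety never decays and the early stillness phase
never ends; at 0.001 s/step anxiety is gone within seconds and bout
mass collapses into sub-second fragments. The calibrated default
(`defaultSecondsPerStep()`, 0.01 s) makes `tau_a` ≈ 104 s of a 300-s
test and is recorded in the package, not recomputed per run.

With that calibration a 60-subject simulated mouse SP cohort reproduces
the qualitative two-phase structure of experimental mice — transition
rate peaking near 50 s and declining to a stable late level, short
exploratory bouts early and longer bouts late — and the contrast with
the rat presets runs in the observed directions (rats commit to the
social stimulus immediately: higher first-minute RDI, fewer
first-minute transitions). One quantitative caveat is documented
deliberately: in our simulations the late-test transition rate settles
near a quarter of the peak value, lower than the roughly-half-of-peak
plateau of experimental mouse curves. Under the preset parameters
the exploration state becomes very sticky once anxiety has decayed
(stay probability `sigmoid(S0 + E0)` ≈ 0.9996, mean dwell ≈ 27 s), and
long exploration stints suppress late transitions. None of the
defensible convention choices (first-bout counting, initial state,
anxiety clamping, frozen-versus-current rewards in the anxiety term)
moves this ratio by more than a few percentage points.

## Synthetic data and what the tests do (and do not) show

The generators in this package are *renewal processes*, deliberately a
different mechanism from the Markov model: per stimulus, exponential
waits at a phase-specific initiation hazard and exponential bout
durations at a phase-specific mean, with an early (first 60 s) and a
late phase. This keeps metric tests non-circular — when the metrics
recover a generator's ground truth (occupancy fractions matching
`hazard * meanBout / (1 + hazard * meanBout)`, zero mean signed
preference under symmetric hazards, known center-occupancy fractions,
injected piezo burst times), the evidence is independent of the
simulator the metrics are also applied to. Cross-stimulus collisions
are resolved by truncating the later-starting bout, so generated
sessions always satisfy the non-overlap invariant.

What the generators do *not* emulate: autocorrelated bout structure,
within-phase non-stationarity, tracker jitter and dropped frames,
arena-position-dependent investigation, or any coupling between
stimulus movement and subject behavior. Passing tests therefore
establish the *arithmetic* of the pipeline on schema-faithful data, not
robustness to every artifact of real recordings.

Default regime values live in `inst/extdata/regimes.json`. The
mouse-like early phase uses equal hazards of 0.05/s and 3-s mean bouts
(frequent sampling of both stimuli); the rat-like early phase uses
0.08/s vs 0.005/s with 25-s mean bouts for the social stimulus
(immediate commitment). Late phases in both regimes shift to fewer,
longer, stimulus-1-biased bouts. These are plausibility settings for
fixture generation, not fitted quantities.

## Piezo pipeline choices

The movement pipeline decimates 20-kHz input to 2 kHz with an
anti-aliasing IIR stage, applies a 4th-order 10–100 Hz Butterworth
band-pass forward and backward (zero phase, so detected event times are
not skewed by filter delay), normalizes by the session's maximum
absolute value, and thresholds at 20% of that maximum. Suprathreshold
runs closer than 0.5 s are fused into one movement event — the raw
extent of a "movement" is not otherwise defined — and each event
carries both its peak time (`time`, the downstream alignment point,
matching how movement-triggered averages are aligned to the movement
peak) and its first threshold crossing (`onset`). On synthetic bursts
at twice the threshold, detection is exact and insensitive to the
threshold across 20–40%.

Movement-triggered investigation requires a quiet pre-window (3.5 s
with neither investigation nor another movement) before each trigger
and measures per-stimulus investigation in the 3.5-s response window.
Control epochs are built deterministically: the earliest non-overlapping
movement-free stretches long enough to hold a quiet pre-window plus a
response window, taken first-to-last and matched in number to the
qualifying movements. Deterministic earliest-first sampling was chosen
over random placement so that reruns are exactly reproducible; its
known bias is toward early-session epochs.

## Fitting

`fitParameters()` is a compact NSGA-II: fast non-dominated sorting,
crowding distance, binary tournaments, blend (BLX-0.5) crossover,
per-gene uniform mutation within bounds, (mu + lambda) elitism, and an
external archive of every non-dominated solution encountered — the
returned front. The objectives are RMS discrepancies of the stimulus-1
and stimulus-2 investigation curves and the transition-rate curve
(optionally the pooled category curves). Evaluations use common random
numbers: a fixed set of per-replicate seeds shared by every candidate,
so fronts are reproducible from the master seed and candidate rankings
are not dominated by simulation noise. Because objectives are averaged
over finitely many simulated cohorts, the archive's best weighted
objective is monotone by construction while individual population
members remain noisy.

The self-consistency test fits `r10`, `r20`, `a0` (bounds ±50%) to a
target generated from known parameter values, at population 32,
20 generations, 5 replicates of 20-subject cohorts per evaluation —
sizes at which the whole run completes in minutes on one core while
still recovering the generating parameters to within a few percent. The
target cohort uses 200 subjects so the check measures fit quality
rather than the sampling noise of the target itself; parameter recovery
is reported but only the curve discrepancy is asserted, since
identifiability of the full parameter vector from summary curves is not
established.

## Known limitations

* The step-length calibration selects from a coarse grid; the true
  step length under which the preset parameters were originally fitted is unknown, and
  the late-test transition-rate level (above) is sensitive to it.
* The SNP novel/familiar labelling of the preset reward pairs is an
  interpretation; swapping labels mirrors the predicted preference.
* Statistical hypothesis tests are out of scope by design: the package
  emits tidy per-session and cohort tables for external tools.
* The fitting module targets cohort summary curves only; it does not
  fit individual trajectories or quantify uncertainty beyond the
  Pareto front.
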