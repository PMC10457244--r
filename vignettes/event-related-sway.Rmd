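---
title: "Event-related bin statistics of force-plate sway: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-related bin statistics of force-plate sway: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swaybins)
```

## The measurement problem

Quiet upright stance is an actively controlled equilibrium. A force plate
measures the ground reaction as three forces and three moments; the moment
about the plate's mediolateral axis governs anteroposterior (AP) sway and
the moment about the anteroposterior axis governs mediolateral (ML) sway.
Classical posturography aggregates sway over tens of seconds, which is far
too coarse to see whether a *single cognitive operation* — here, resolving
the response conflict of an incongruent Simon-task trial — perturbs balance
control. `swaybins` implements an event-related alternative: the continuous
moment series is epoched around behavioural events (target onset, manual
response) and summarised in short 150 ms bins, trial by trial, exactly as
event-related potentials are extracted from EEG.

Two complementary parameters are computed per bin and axis:

* **AV** — the absolute mean of the baseline-centred moment: the balance
  *state* held during the bin;
* **SD** — the sample standard deviation of the centred moment: the ongoing
  balance-control *effort* in the bin.

Because the plate's axis labelling is a hardware convention, the analysis
never addresses `mx`/`my` directly: an `axis_map()` declares which channel
is the AP-controlling and which the ML-controlling moment, and which
physical direction a positive ML moment points to.

## Pipeline and numerical choices

1. **Filtering.** A 4th-order Butterworth low-pass at 10 Hz is applied
   forward and backward (`lowpass_dual_butterworth()`). The dual pass
   cancels the phase response exactly and squares the magnitude response,
   so the nominal cutoff sits at gain 0.5 rather than 1/sqrt(2); the cutoff
   is deliberately not pre-warped. Each pass starts from the filter's exact
   steady state scaled to the first sample and the series is extended by
   odd reflection over 3 x order samples, so a constant series passes
   through to machine precision and edge transients are suppressed. The
   10 Hz cutoff (shortest cycle 100 ms) removes mechanical and
   electromagnetic noise while keeping everything a supraspinal balance
   controller could produce.
2. **Trigger decoding.** Trial phases arrive as binary pulse channels: one
   fixation channel and four condition channels (congruency x target side),
   thresholded per channel at half the low-to-high range for robustness to
   analog noise. Rising edges time-stamp fixation and target onsets, the
   condition channel's falling edge time-stamps the response. A pulse of
   full timeout width (default 1.5 s) has no response to report and marks
   the trial unresponsive.
3. **Segmentation and labels.** One trial per fixation onset; the previous
   trial's congruency is attached within the block and is undefined for the
   first trial of a block (those trials never enter the post-congruent
   subset). Correctness and the responding hand come from the behavioural
   log, since the trigger lines do not carry them.
4. **Exclusions.** Trials are removed in a fixed precedence order, each
   counted once: unresponsive (no response before the timeout; the trial
   envelope then exceeds 2 s), errors, post-error trials (a correct trial
   immediately after an error; a trial after an unresponsive trial is not
   post-error), and slow correct responses (RT >= 1250 ms). Note that with
   the standard trial envelope (200 ms fixation + RT + 350 ms feedback +
   200 ms blank) a responded trial crosses the 2 s duration criterion
   exactly when its RT crosses 1250 ms, so "unresponsive" is reserved for
   trials with no response at all and slow responded trials form their own
   category — this is the only reading under which the two categories can
   both be non-empty. For the sway analysis the retained trials are further
   restricted (by default) to those following a congruent trial, where the
   Simon effect is robust and not washed out by congruency-sequence
   reversal.
5. **Binning.** Each trial segment is centred at the mean of its own 200 ms
   pre-target fixation window, per axis. Bins are half-open and inclusive
   of the anchor sample — `[target, target+150)`, `[response-150, response)`
   and `[response, response+150)` — so the response sample belongs to
   exactly one bin; the bin length is `round(150 * fs / 1000)` samples
   (38 at 250 Hz). Windows that would leave the recording are dropped from
   that bin's analysis and counted.
6. **Parameters and transforms.** The signed ML mean is recoded so that
   positive values point toward the response side (a diagnostic; its
   absolute value, the AV parameter, is recoding-invariant). AV and SD are
   natural-log-transformed with an epsilon floor of 1e-12 N·m; continuous
   data make exact zeros measure-zero events, but degenerate synthetic
   windows must not crash, so floored values carry a flag. Logs are taken
   per trial and averaged within participant x condition cells; the
   alternative (log of the cell mean) is exposed as
   `analysis_config(transform_order = "cell")` because the convention is
   genuinely ambiguous, and per-trial-first is the stricter reading.

## Inference

Target-aligned parameters are compared between congruencies with paired
t tests, reported with the paired effect size dz = mean(d)/sd(d) (so
dz x sqrt(n) = t). Response-aligned parameters enter a 2 x 2
within-subject ANOVA (time bin x congruency); every effect is tested
against its own effect-by-subject interaction and summarised with partial
eta squared = SS_effect / (SS_effect + SS_error). No sphericity correction
is applied: two-level factors have none, and the three-bin modulation
analysis is reported with uncorrected degrees of freedom (2, 94 at n = 48).
Follow-up per-bin t tests are always computed but flagged "protected" only
when the omnibus interaction passes the configured alpha (0.01 for sway
contrasts; behavioural contrasts report raw p values). Missing cells lead
to listwise deletion per analysis, with a message. The design power
calculation (`power_paired_t()`) uses the noncentral t distribution with
noncentrality dz x sqrt(n); at n = 48, dz = 0.5, alpha = 0.05 it gives
0.925.

## What the generator emulates

`simulate_behavior_study()` / `run_study()` produce complete synthetic
sessions: 48 participants x 10 blocks x 80 trials by default, with the
standard trial envelope (200 ms fixation, response timeout 1.5 s, 350 ms
feedback, 200 ms blank; the response-to-target interval after a response is
750 ms, and all event times are quantised to the sample grid).

**Behaviour.** Reaction times are lognormal within each previous-congruency
x congruency cell, mixed with an exponential slow tail beyond the 1250 ms
cutoff; draws reaching the timeout become unresponsive. The default cell
means (432/486/467/451 ms, common within-cell SD 90 ms) encode a +54 ms
congruency effect after congruent trials and a -16 ms (reversed) effect
after incongruent trials around a 459 ms grand mean — the canonical
congruency-sequence pattern for a standing Simon task. Error probabilities
(2.65/9.95/6.6/4.4%) encode a +7.3 percentage-point post-congruent and
-2.2 point post-incongruent error effect at 5.9% errors overall; the slow
tail mass (3.5%) places about 3% of trials beyond the cutoff. Participants
differ by a normal shift of all RT cell means (SD 40 ms) and a normal
shift of the error log-odds (SD 0.35) centred at -sigma^2/2 so the
population-mean error rates stay at their calibrated values. Under these
defaults the exclusion rules remove about 14-15% of trials, partitioned
into errors, post-errors and slow responses in roughly the calibrated
proportions.

**Sway.** Moments are generated phenomenologically, not from inverted-
pendulum mechanics: the claims under test concern within-bin statistics,
not pendulum dynamics. Each axis is the sum of

* a slow stationary Ornstein-Uhlenbeck drift (tau = 20 s, SD 2 N·m) — the
  multi-second equilibrium oscillation of quiet stance;
* a fast OU fluctuation (tau = 0.3 s, SD 1 N·m) scaled by a phase-gain
  profile — the corrective activity whose within-bin SD the pipeline
  measures;
* a per-trial mean-shift ramp rising from target onset to a random plateau
  (SD 0.3 N·m) at the response — the postural lean accompanying the manual
  reaction, which gives the AV parameter its trial structure;
* white measurement noise (SD 0.3 N·m).

The phase gains are 1 during fixation, `gamma_target` (default 1) for one
bin after target onset, and `gamma_response = 0.92 * gamma_target` from one
bin before to one bin after the response — an 8% drop in fluctuation from
target processing to response execution. On incongruent trials only, the
ML-controlling fluctuation in the pre-response bin is additionally scaled
by `1 - delta`: the congruency injection. With `delta = 0` the generator is
congruency-blind by exchangeability, which the null-calibration tests
exploit.

**Why `delta = 0.20`.** The injection multiplies the fast fluctuation
before filtering. The zero-phase low-pass has an impulse response of
roughly 50 ms, which bleeds unreduced fluctuation across the edges of the
150 ms injection window; empirically the pipeline-measured SD reduction is
about 0.72 of the configured `delta`, stable across seeds. The default is
therefore calibrated on the measurement scale: `delta = 0.20` makes the
full pipeline recover an ML pre-response reduction of about 14%, the
magnitude the package's acceptance analyses are anchored to. The same
attenuation applies to the gain profile, so the measured pooled
target-to-response reduction sits near 8% with `gamma_response = 0.92`.

**What is deliberately not emulated.** Real postural sway is
non-stationary over minutes (fatigue, strategy drift), has heavier-tailed
increments, and couples the two axes; manual key presses, gaze shifts and
breathing leave structured artefacts; and the true effect of cognitive
conflict on balance is unknown — here it is injected by construction.
Passing recovery tests therefore demonstrates that the *pipeline measures
faithfully what the model puts in* (and nothing where nothing was put in),
not that real data would show these effects.

## Scale choices and statistical calibration

Simulated studies in the test suite run at reduced problem sizes chosen to
keep the statistical structure intact: full-design recoveries use 48
participants at 250 Hz (bin length 38 samples), while property and
calibration suites use 8-20 participants, 1-3 blocks and 125 Hz, where the
targeted invariants (exchangeability, monotonicity, identity relations) are
scale-free. The type-I calibration runs the entire pipeline over 200
null-injection datasets and checks the fraction of significant congruency
contrasts against its nominal level at alpha = 0.05 rather than 0.01: the
acceptance band is proportional to alpha, and at 0.01 a 200-dataset Monte
Carlo estimate is dominated by Poisson noise even when the pipeline is
exactly calibrated.

## Known limitations

* The RT distribution family (lognormal plus exponential tail) is a
  modelling convenience; any family with the calibrated cell means would
  do, and the configuration accepts arbitrary cell parameters.
* The sway generator's drift/noise scales set the floor under the
  measurable effects; gross changes to them change the attenuation factor
  between configured and recovered reductions.
* `rm_anova()` covers the two designs the pipeline needs (2 x 2 and one-way
  within-subject, complete cells, listwise deletion); it is not a general
  mixed-model engine.
* Block duration is emergent (lead-in + summed trial envelopes + tail)
  rather than fixed; fixing it would require padding or truncating trials
  and serves no analysis purpose.
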