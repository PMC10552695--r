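---
title: "The timed sequence task: contingency model, synthetic agents, and analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The timed sequence task: contingency model, synthetic agents, and analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(timedseq)
```

## The paradigm

The timed sequence task trains mice, in an ordinary two-lever operant box,
to emit a four-press heterogeneous sequence — left, left, right, right —
with each interpress interval inside an experimenter-defined window. Because
a correct trial requires both the right serial order and the right timing,
the behavior becomes highly stereotyped, and the paradigm then probes
flexibility by perturbing exactly one thing at a time: the sequence
structure (every fourth trial shortened to LLR), one timing window (the
LEFT, RIGHT, and MIDDLE probes raise one lower bound), or the reinforcement
itself (extinction).

`timedseq` implements the paradigm as a deterministic simulation so that its
contingencies can be exercised, its log format parsed and produced, and its
entire analysis battery computed without hardware. The package is organized
the way the experiment is: stage configurations, a contingency engine, a log
dialect, synthetic animals, and analyzers.

## Stage configurations

The 15 stages are available as `builtin_stage()` objects and as a bundled
YAML protocol document, fully parameterized with the paradigm's canonical
settings:

```{r}
vapply(stage_names(), function(id) {
  cfg <- builtin_stage(id)
  paste(cfg$target_sequence, collapse = "")
}, "")
```

Decisions embedded in the configurations:

* **Closed windows.** An interval exactly equal to a window bound is
  correct. The stage descriptions state the bounds without specifying edge
  handling; closing the intervals makes the printed bounds themselves legal,
  which is directly testable by boundary probing (and is what the boundary
  sweep in the test suite asserts, at a resolution of one 0.01 s tick).
* **Untimed transitions** use the sentinel window [0.05 s, 3600 s] rather
  than infinity, mirroring the acquisition software's defaults. The 0.05 s
  floor also acts as a debounce.
* **One type covers all stages.** Habituation stages are `stage_config`s
  with an empty target sequence and a delivery schedule (habituation 3: one
  pellet every 2 min over 30 min, hence exactly 15); basic operant training
  is a length-1 sequence with an any-lever flag.
* **Two baseline stages.** The initial timed-baseline acquisition stage and
  the baseline re-establishment blocks run between probes carry different
  advancement rules (10-session cap with a 3-consecutive-day criterion
  versus a 3-session cap with a single 40-reward day), so they are distinct
  stages, giving 15 stages in total; the canonical protocol flow
  (`builtin_protocol()`) has 18 entries because re-establishment recurs
  after each probe.
* The advancement and exclusion rules encode the paradigm's per-stage
  criteria literally, including forced advancement after the session cap on
  the timed stages and outright exclusion on the earlier ones.

## The contingency engine

`run_session()` replays a time-ordered press stream through
`handle_press()`, the single contingency step. All times are quantized to a
0.01 s clock tick at ingest and compared in integer ticks, so boundary
behavior is exact and a session serializes byte-identically on every run.

Precedence per press: an active time-out claims the press first (a time-out
press is tallied per lever, advances nothing, and does **not** extend the
time-out); then the lever identity is checked against the expected position;
then the interval from the previous press against the transition's closed
window. Errors reset the sequence to position zero and schedule a
`timeout_s` (default 5 s) lockout, implemented as the half-open interval
[onset, onset + 5 s): the first press at exactly 5 s after the error is free
again, which is the quantity the lockout-probing benchmark recovers.

Other engine decisions:

* **Lateness is evaluated at press time.** The log dialect records presses
  and rewards, so a window overrun only becomes an error when the late press
  actually arrives; a trial with no further presses simply never completes.
* **No predecessor, no timing check.** The first press of a session, after a
  reward, or after a time-out expiry starts a fresh trial and cannot be a
  timing error.
* **Alternation is indexed by completed trials.** Under the alternating rule
  (period 4, alternate LLR) the shortened target applies to every fourth
  *completed* trial, so an error-free session yields exactly 30 LLRR and 10
  LLR rewards; failed attempts do not advance the schedule. A stereotyped
  fourth press emitted after a shortened trial's reward lands on the next
  trial's contingency (an incorrect first press), which is also how the
  probe analyzer counts it.
* **Extinction** keeps the full contingency chain and the 40-trial cap but
  delivers no reward; sessions end at the trial cap, the time cap, or (on
  reinforced stages) the reward cap, whichever comes first.
* **Cue lights** are emitted as paired on/off events bracketing exactly the
  period a lever is armed. They are derivable from the other events, so
  analyzers may ignore them, but recording them keeps the event stream a
  complete account of the box state.

## The log dialect

One session per row; each event is a token `<ticks>.<code>` where the
integer part counts 0.01 s ticks since the previous event and the fractional
part is a fixed-width three-digit event code. Absolute times are recovered
as prefix sums. The code table (`event_codes()`) is package-defined and
closed: press codes encode role × lever, plus reward, manual pellet, trial
completion, time-out onset/offset, cue transitions, and session markers.
Acquisition software code tables vary between installations, so this
dialect is its own normative specification; it preserves the
time-dot-code decimal structure while making parsing unambiguous. Readers
are lenient about unknown codes (kept, labeled `unknown`, reported in one
warning) and strict about malformed tokens (error with row and column).

## Synthetic agents

`generate_session()` co-simulates a parameterized policy against the engine,
so the stream reacts to contingencies the way a live animal's would: presses
stop when a trial errors out, time-out pressing happens during actual
time-outs, and the stream ends with the session.

* **Timing** on each transition is log-normal (positive support and the
  right skew typical of interresponse times; the paradigm itself publishes
  no distribution). The `perfect` preset presses deterministically at window
  midpoints.
* **Errors** are injected per press: wrong lever with `lever_confusion_p`,
  an interval deliberately below/above the window with `premature_p` /
  `late_p`; the log-normal's own tails add naturally occurring timing
  errors.
* **Time-out pressing** is Poisson at `timeout_press_rate` per second,
  biased toward the left (first) lever.
* **Activity structure** is a two-state renewal process with exponential
  bout and pause dwell times; it exists to exercise the bout/pause analyzer,
  not to model motivation.
* **Perseveration** is a per-trial mixture: with probability `perseveration`
  the agent samples its pre-change sequence and timing; otherwise a
  window-adapted policy whose median sits just above a raised lower bound
  (15% into the window). This is the minimal mechanism for the probe-stage
  contrasts. A second mechanism, `structure_adapt_p`, lets adapted trials
  bridge a raised lower bound by inserting an extra press of the preceding
  lever — only meaningful where the transition crosses levers (the MIDDLE
  probe), where the insertion produces the characteristic wrong-third-left
  trials. Perseveration alone cannot generate those sequence-structure
  errors, which is why the mechanism exists.
* **Pacing** (approach latencies of 3–10 s, pellet retrieval and consumption
  of 8–18 s, 1–4 s to re-engage after a time-out) is calibrated to the
  paradigm's session economics: trained animals reach the 40-reward cap
  within a baseline hour, while first probe and extinction sessions are
  typically limited by the clock instead — the regime in which per-session
  probe measures are meaningful counts rather than rates.

The `control_like` and `vpa_like` presets differ only in documented
directions — longer interpress intervals, a lower time-out pressing rate,
and higher perseveration for the VPA-like policy; the magnitudes are free
parameters chosen once. With the default presets a simulated cohort
reproduces the corresponding group contrasts in *sign* (fewer first-session
time-out presses, longer first-session intervals, fewer third-left
insertions in the MIDDLE probe); the test suite asserts exactly those sign
constraints at the study's n = 11 per group and nothing about magnitudes.

What passing these simulations does **not** show about real data: agents are
stationary within a stage (no within-stage learning curves), their
parameters are not fitted to any animal, and the bout/pause process is
phenomenological. The synthetic cohort validates the *machinery* — engine,
logs, analyzers, criteria — not any biological claim.

## Analysis

`classify_trials()` replays the recorded press stream through the engine and
requires every recorded press role to match the recomputed contingency; any
divergence is an integrity error naming the first discrepant event. That
replay is also the module's master oracle: for any agent-generated session,
`summarize_session()` must reproduce the engine's internal tallies exactly,
and the test corpus asserts this across all stages and presets.

* **Trials** start at the first non-time-out press after session start, a
  reward, or time-out expiry; time-out presses belong to no trial. Each
  trial is labeled by its emitted prefix and failure mode (`LL_fast2`,
  `LLL_wrong3`, …) and mapped to display labels: `LLRRP` for the complete
  correct sequence, the bare emitted string for wrong-lever and too-fast
  errors (`R`, `LR`, `LLL`, `LLRL`, `LL`, `LLRR`), and a trailing macron for
  too-slow errors (`LL̄`, `LLRR̄`). The canonical nine-label set for
  four-press stages omits third-press timing errors, which the contingencies
  nevertheless permit (an L–R interval outside 0.5–20 s); the package keeps
  those as `LLR`/`LLR̄` rather than forcing them into a wrong bin.
* **Interval statistics** are computed only over correctly executed
  sequences, per transition, with the sample sd (n − 1 denominator, a
  choice the paradigm leaves open) and `cv = sd/mean`.
* **Bouts and pauses** split the press train at interpress gaps ≥ a
  threshold; the split point is not a task parameter, so it is an
  argument with a 30 s default, and the partition starts at the first press
  (time before any pressing is neither bout nor pause). Pause counts are
  nonincreasing in the threshold.
* **Criteria** (`check_criteria()`) return advance/repeat/exclude per the
  stage rules; probe stages run a fixed three sessions with no criteria.
* **Outliers** use the single-pass mean ± 2 sd rule with the sample sd. The
  rule is deliberately not iterated. Note its edge behavior: with n = 5 and
  a single extreme value the sample sd grows so fast that the extreme point
  can remain inside the band; flagging is strict (`outside` the range), so
  such values are kept.
* **Probe measures** extract the stage-appropriate counters: premature and
  delayed fourth presses (alternating, RIGHT), third-press-incorrect-left
  and third-press-too-fast (MIDDLE), and for extinction the last-interval
  series of completed trials plus right-started trials following an
  unrewarded completion.

## Numerical choices and problem sizes

The clock tick is 0.01 s everywhere (ingest quantization, window
comparisons, log tokens); ε in all boundary tests is one tick. The engine
and analyzers are deterministic; all randomness lives in the agents and is
seed-controlled, with the global RNG state restored after generation.

The shipped test suite runs the cross-module corpus at 111 sessions (all 15
stages × three noisy presets × three seeds, plus habituations), the
parameter-recovery check at ≥ 200 correct trials per transition with a
3-Monte-Carlo-SE tolerance, and the cohort contrast at 11 animals per group
with a fixed master seed — sizes chosen to make sampling error negligible
relative to the asserted effects while keeping a full run in tens of
seconds.

## Known limitations

* Within-stage learning is not modeled; agents are stationary per stage.
* The log dialect is this package's own; no bit-compatibility with any
  acquisition software's output is attempted.
* Group-level inference (t tests, ANOVA, post hoc corrections) is out of
  scope by design: the package exports per-animal, per-session parameter
  tables and leaves statistics to the caller.
* Habituation consumption (whether the animal actually ate the pellets) is
  assumed; the simulator has no model of satiety.
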