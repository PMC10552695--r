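# timedseq

Simulation and analysis of the **timed lever-press sequence task**, a
multi-stage operant paradigm for studying motor learning and cognitive
flexibility in mice. In the task an animal must emit a fixed heterogeneous
sequence of four lever presses — left, left, right, right (LLRR) — with every
interpress interval inside a predefined time window, e.g. at baseline

* L–L: 0.5–5 s, L–R: 0.5–20 s, R–R: 0.5–5 s,

to earn a food reward. Any wrong lever, any interval outside its window, or
any press during the 5 s post-error time-out makes the trial incorrect. After
training, the required sequence (every fourth trial shortened to LLR) or a
single timing window (LEFT/RIGHT/MIDDLE probes, which raise one lower bound)
is altered, and an extinction session withholds the reward — each alteration
probing how readily the automatized sequence can be changed.

`timedseq` reproduces the whole paradigm in software, for task designers who
want to explore contingency settings before running animals and for analysts
who need the paradigm's full behavioral parameter set from plain-text event
logs:

* **config** — all 15 protocol stages (3 habituations, operant training,
  LR/LLR/LLRR acquisition, timed baseline and stricter limits, the four
  flexibility probes, baseline re-establishment, extinction) as validated,
  serializable `stage_config` objects.
* **engine** — a deterministic event-driven state machine
  (`run_session()`, `handle_press()`) on a 0.01 s clock with closed timing
  windows, 5 s time-outs, cue lights, alternation schedules, and session
  caps (60 min / 40 rewards at baseline, whichever comes first).
* **logio** — the decimal-encoded log dialect (`<ticks>.<code>` tokens, one
  row per session) with byte-stable writers and lenient readers.
* **agents** — parameterized synthetic mouse policies (`preset()`,
  `generate_session()`): log-normal interpress timing, lever confusion,
  premature/late presses, Poisson time-out pressing, bout/pause activity,
  and perseveration after contingency changes.
* **analysis** — trial-outcome classification (LLRRP, R, LR, LLL, LL, …),
  interval statistics and variability (CV), bout/pause detection, cumulative
  records, advancement/exclusion criteria, the ±2 SD outlier rule, and
  probe-specific flexibility measures.

## Worked example

Simulate a noisy but competent animal's first baseline timed session and
analyze it:

```r
library(timedseq)
cfg <- builtin_stage("LLRR_baseline")
cfg
#> <stage_config> LLRR_baseline
#>   sequence: LLRR
#>   windows : [0.5,5] [0.5,20] [0.5,5] s
#>   caps    : 60 min / 40 rewards; timeout 5 s; reinforced

stream <- generate_session(preset("control_like"), cfg, seed = 1)
log <- run_session(cfg, stream)
log
#> <session_log> animal sim, stage LLRR_baseline (1970-01-01)
#>   768 events, 40 rewards, 40 completed trials, ended at 2775.45 s

s <- summarize_session(log, cfg)
s$interval_stats
#>   transition  n mean    sd    cv
#> 1        L-L 40 1.38 0.343 0.249
#> 2        L-R 40 1.29 0.357 0.277
#> 3        R-R 40 1.31 0.380 0.290

sort(s$category_counts, decreasing = TRUE)
#> LLRRP  LLRR  LLRL    LL     R   LLR   LLL   LLR̄    LL̄  LLRR̄    LR
#>    40     7     5     4     4     3     2     2     1     1     1
```

The session ended when the 40th reward was earned (at 2775 s, before the
60 min cap). The interval table gives the per-transition mean, sd, and
coefficient of variation of the interpress intervals, computed only over the
40 correctly executed sequences. The category table partitions all 70 trial
attempts by emitted prefix and failure mode: `LLRRP` is the complete correct
sequence followed by the pellet; `LLRR` a fourth press below its 0.5 s lower
bound; `LLL` a wrong third left press; a trailing macron (`LL̄`) marks a
too-slow press. Time-out presses (115 here) belong to no trial and are
tallied per lever.

Logs round-trip through the plain-text dialect:

```r
writeLines(write_log(log)[5])   # "0.001 0.081 1605.011 144.011 0.083 ..."
```

and a cohort study runs end-to-end from the shell:

```sh
inst/cli/timedseq simulate --preset control_like,vpa_like --n 11 --seed 1 --outdir sim
inst/cli/timedseq analyze --logs 'sim/*/sessions.log' --outdir tables
```

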