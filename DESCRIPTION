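Package: timedseq
Title: Simulation and Analysis of the Timed Lever-Press Sequence Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An event-driven simulator and analysis suite for a multi-stage
    operant paradigm in which mice learn a timed four-press lever sequence
    (LLRR) whose interpress intervals must fall inside stage-specific time
    windows. Provides machine-readable configurations for all fifteen training
    and probe stages, a deterministic contingency engine (rewards, 5 s
    time-outs, cue lights, session caps), a plain-text decimal-encoded event
    log dialect with readers and writers, parameterized synthetic mouse
    policies (timing noise, lever confusion, perseveration, activity bouts)
    for desk-scale experiments, and analyzers for the behavioral parameters
    the paradigm records: trial-outcome classification, press accounting,
    interpress-interval statistics and variability, bout/pause structure,
    cumulative records, advancement/exclusion criteria, and probe-specific
    flexibility measures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Collate:
    'codes.R'
    'config.R'
    'engine.R'
    'logio.R'
    'agents.R'
    'analysis.R'
    'cli.R'
    'timedseq-package.R'
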