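# Scripted press-stream builders used as independent drivers for the engine:
# deterministic streams written from the stage tables, not via the agent
# module.

window_mid <- function(w) if (w[["high"]] >= 3600) 1 else (w[["low"]] + w[["high"]]) / 2

# error-free stream pressing at window midpoints, following the alternation
# schedule when present
scripted_perfect <- function(cfg, n_trials = 60, trial_gap = 5, t0 = 10) {
  t <- t0
  ts <- numeric(0)
  lv <- character(0)
  completed <- 0L
  for (i in seq_len(n_trials)) {
    sq <- if (!is.null(cfg$alternation)) alternation_target(completed, cfg) else cfg$target_sequence
    for (k in seq_along(sq)) {
      if (k > 1) t <- t + window_mid(cfg$windows[[k - 1]])
      ts <- c(ts, t)
      lv <- c(lv, sq[k])
    }
    completed <- completed + 1L
    t <- t + trial_gap
  }
  press_stream(ts, lv)
}

# one scripted trial with every transition at its midpoint except one, which
# gets `gap`; returns the resulting session log
probe_gap_session <- function(stage_id, vary_trans, gap, t0 = 10) {
  cfg <- builtin_stage(stage_id)
  gaps <- vapply(cfg$windows, window_mid, 0)
  gaps[vary_trans] <- gap
  ts <- t0 + cumsum(c(0, gaps))
  run_session(cfg, press_stream(ts, cfg$target_sequence))
}

trial_ok <- function(log) log$summary$completed_trials == 1
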