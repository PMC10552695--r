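test_that("a correct baseline sequence is rewarded press by press", {
  cfg <- builtin_stage("LLRR_baseline")
  state <- new_session_state(cfg)
  roles <- character(0)
  stream <- list(list(t = 10.0, lever = "L"), list(t = 11.0, lever = "L"),
                 list(t = 15.0, lever = "R"), list(t = 16.0, lever = "R"))
  for (p in stream) {
    res <- handle_press(state, cfg, p)
    state <- res$state
    roles <- c(roles, res$outcome$role)
  }
  expect_equal(roles, rep("correct", 4))
  expect_true(res$outcome$trial_completed)
  expect_true(res$outcome$rewarded)
  expect_equal(state$rewards, 1L)
})

test_that("interval checks honor closed window bounds exactly", {
  cfg <- builtin_stage("LLRR_baseline")
  # 0.2 s gap: below the 0.5 s lower bound -> too fast, with a time-out
  state <- new_session_state(cfg)
  state <- handle_press(state, cfg, list(t = 10.0, lever = "L"))$state
  res <- handle_press(state, cfg, list(t = 10.2, lever = "L"))
  expect_equal(res$outcome$role, "too_fast")
  expect_true(any(res$events[, "code"] == 71)) # time-out onset emitted
  expect_equal(res$state$timeout_until_tick, 1520L)

  # exactly at the bound is correct
  state <- new_session_state(cfg)
  state <- handle_press(state, cfg, list(t = 10.0, lever = "L"))$state
  expect_equal(handle_press(state, cfg, list(t = 10.5, lever = "L"))$outcome$role,
               "correct")
})

test_that("boundary sweep: window edges are legal, one tick beyond is not", {
  timed <- c("LLRR_baseline", "LLRR_strict", "LLRR_alternating", "LLRR_rebaseline",
             "LLRR_LEFT", "LLRR_RIGHT", "LLRR_MIDDLE", "Extinction")
  for (id in timed) {
    cfg <- builtin_stage(id)
    for (i in seq_along(cfg$windows)) {
      w <- cfg$windows[[i]]
      expect_true(trial_ok(probe_gap_session(id, i, w[["low"]])),
                  label = sprintf("%s window %d at low", id, i))
      expect_true(trial_ok(probe_gap_session(id, i, w[["high"]])),
                  label = sprintf("%s window %d at high", id, i))
      expect_false(trial_ok(probe_gap_session(id, i, w[["low"]] - 0.01)),
                   label = sprintf("%s window %d at low - tick", id, i))
      expect_false(trial_ok(probe_gap_session(id, i, w[["high"]] + 0.01)),
                   label = sprintf("%s window %d at high + tick", id, i))
    }
  }
})

test_that("sessions terminate at the reward cap, time cap, or trial cap", {
  cfg <- builtin_stage("LLRR_baseline")
  log <- run_session(cfg, scripted_perfect(cfg, n_trials = 60))
  expect_equal(log$summary$rewards, 40)
  expect_equal(log$summary$completed_trials, 40)
  expect_equal(log$summary$total_presses, 160)
  # the session ends at the 40th reward, not the time cap
  expect_lt(log$summary$end_s, cfg$session_cap_min * 60)
  expect_equal(log$events$t[log$events$label == "session_end"],
               max(log$events$t[log$events$label == "reward"]))

  empty <- run_session(cfg, press_stream(numeric(0), character(0)))
  expect_equal(empty$summary$rewards, 0)
  expect_equal(empty$summary$end_s, 3600)

  ext <- builtin_stage("Extinction")
  elog <- run_session(ext, scripted_perfect(ext, n_trials = 60))
  expect_equal(elog$summary$rewards, 0)
  expect_equal(elog$summary$completed_trials, 40)
  expect_equal(sum(elog$events$label == "reward"), 0)
})

test_that("presses during a time-out never advance the sequence or extend it", {
  cfg <- builtin_stage("LR")
  state <- new_session_state(cfg)
  res <- handle_press(state, cfg, list(t = 10, lever = "R")) # wrong first lever
  expect_equal(res$outcome$role, "incorrect_lever")
  state <- res$state
  until0 <- state$timeout_until_tick
  for (tt in c(11, 12.5, 14.9)) {
    res <- handle_press(state, cfg, list(t = tt, lever = "L"))
    expect_equal(res$outcome$role, "timeout_press")
    state <- res$state
  }
  expect_equal(state$timeout_until_tick, until0) # not extended
  expect_equal(state$pos, 0L)
  # first press at expiry starts a fresh, untimed-checked sequence
  res <- handle_press(state, cfg, list(t = 15.0, lever = "L"))
  expect_equal(res$outcome$role, "correct")
  res <- handle_press(res$state, cfg, list(t = 16.0, lever = "R"))
  expect_true(res$outcome$rewarded)
})

test_that("an error resets the sequence and the next trial restarts cleanly", {
  cfg <- builtin_stage("LLRR_baseline")
  # L, L, then L again (wrong lever at position 3)
  st <- press_stream(c(10, 11, 12, 20, 21, 22, 23),
                     c("L", "L", "L", "L", "L", "R", "R"))
  log <- run_session(cfg, st)
  expect_equal(log$summary$rewards, 1)
  expect_equal(log$summary$incorrect_presses, 1)
  expect_equal(log$summary$correct_presses, 6)
})

test_that("press after session end is rejected", {
  cfg <- builtin_stage("LLRR_baseline")
  state <- new_session_state(cfg)
  state$ended <- TRUE
  expect_error(handle_press(state, cfg, list(t = 10, lever = "L")),
               "session end")
  state <- new_session_state(cfg)
  expect_error(handle_press(state, cfg, list(t = 3600, lever = "L")),
               "session end")
})

test_that("alternation requires the shortened sequence every fourth trial", {
  cfg <- builtin_stage("LLRR_alternating")
  expect_equal(alternation_target(0, cfg), c("L", "L", "R", "R"))
  expect_equal(alternation_target(1, cfg), c("L", "L", "R", "R"))
  expect_equal(alternation_target(2, cfg), c("L", "L", "R", "R"))
  expect_equal(alternation_target(3, cfg), c("L", "L", "R"))
  expect_equal(alternation_target(7, cfg), c("L", "L", "R"))
  expect_error(alternation_target(0, builtin_stage("LLRR_baseline")),
               "no alternation")

  log <- run_session(cfg, scripted_perfect(cfg, n_trials = 60))
  expect_equal(log$summary$rewards, 40)
  expect_equal(log$summary$total_presses, 30 * 4 + 10 * 3)
  trials <- classify_trials(log, cfg)
  expect_equal(sum(trials$seq_len == 4), 30)
  expect_equal(sum(trials$seq_len == 3), 10)
  # the shortened trials recur with period 4
  expect_equal(which(trials$seq_len == 3), seq(4, 40, by = 4))
})

test_that("a surplus fourth press after a shortened trial hits the next trial", {
  cfg <- builtin_stage("LLRR_alternating")
  # complete three LLRR then an LLR trial, then press the stereotyped 4th R
  st <- scripted_perfect(cfg, n_trials = 4)
  extra_t <- st$t[nrow(st)] + 1
  st <- rbind(st, data.frame(t = extra_t, lever = "R"))
  log <- run_session(cfg, st)
  expect_equal(log$summary$rewards, 4)
  expect_equal(log$summary$incorrect_presses, 1) # the surplus press
  trials <- classify_trials(log, cfg)
  expect_equal(trials$display[nrow(trials)], "R")
})

test_that("habituation sessions emit only their scheduled events", {
  h3 <- run_habituation(builtin_stage("Habituation3"))
  rw <- h3$events[h3$events$label == "reward", ]
  expect_equal(nrow(rw), 15)
  expect_equal(rw$t, seq(120, 1800, by = 120))
  expect_equal(h3$summary$end_s, 1800)

  h1 <- run_habituation(builtin_stage("Habituation1"))
  expect_equal(sum(h1$events$label == "reward"), 0)
  expect_equal(h1$summary$end_s, 600)

  h2 <- run_habituation(builtin_stage("Habituation2"))
  expect_equal(sum(h2$events$label == "manual_pellet"), 4)
  expect_equal(sum(h2$events$label == "reward"), 0)

  expect_error(run_habituation(builtin_stage("LR")), "not a habituation")
  expect_error(run_session(builtin_stage("Habituation1"),
                           press_stream(1, "L")), "habituation")
})

test_that("cue-light events bracket armed periods", {
  cfg <- builtin_stage("LLRR_baseline")
  log <- run_session(cfg, scripted_perfect(cfg, n_trials = 3))
  for (lv in c("L", "R")) {
    on <- sum(log$events$label == paste0("cue_on_", lv))
    off <- sum(log$events$label == paste0("cue_off_", lv))
    expect_equal(on, off)
  }
  # the session starts with the first lever armed
  expect_equal(log$events$label[2], "cue_on_L")
})

test_that("identical inputs give byte-identical serialized logs", {
  cfg <- builtin_stage("LLRR_strict")
  st <- generate_session(preset("control_like"), cfg, seed = 11)
  a <- write_log(run_session(cfg, st))
  b <- write_log(run_session(cfg, st))
  expect_identical(a, b)
})
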