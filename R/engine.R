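# Event-driven contingency engine.
#
# The engine replays a stream of timed lever presses against a stage
# configuration and emits the exact contingency outcomes: correct-press
# advancement, wrong-lever and timing errors, 5 s time-outs, reward delivery,
# cue-light transitions, and session termination at the reward/trial/time
# cap. All times are quantized to a 0.01 s clock tick at ingest; interval
# comparisons are carried out in integer ticks, so the printed window bounds
# are themselves legal (closed windows) and boundary behavior is exact.

TICK_S <- 0.01

to_ticks <- function(t) as.integer(round(t / TICK_S))

#' A timed lever press
#'
#' @param t Time in seconds from session start (quantized to 0.01 s ticks).
#' @param lever `"L"` or `"R"`.
#' @return A one-row data frame with columns `t` and `lever`.
#' @export
press <- function(t, lever) {
  stopifnot(all(lever %in% c("L", "R")), all(t >= 0))
  data.frame(t = round(to_ticks(t)) * TICK_S, lever = lever,
             stringsAsFactors = FALSE)
}

#' Build a press stream
#'
#' Convenience constructor for scripted streams: `press_stream(c(1, 2), c("L", "R"))`.
#'
#' @param t Numeric vector of press times (seconds, nondecreasing).
#' @param lever Character vector of levers, recycled against `t`.
#' @return A data frame with columns `t` and `lever`, one row per press.
#' @export
press_stream <- function(t, lever) {
  if (length(t) == 0) {
    return(data.frame(t = numeric(0), lever = character(0), stringsAsFactors = FALSE))
  }
  press(t, rep_len(lever, length(t)))
}

# active target for the trial following `completed_trials` completions
next_active <- function(cfg, completed_trials) {
  if (!is.null(cfg$alternation) &&
      (completed_trials + 1L) %% cfg$alternation$period == 0L) {
    seqv <- cfg$alternation$alternate_sequence
  } else {
    seqv <- cfg$target_sequence
  }
  n <- length(seqv)
  list(seq = seqv,
       windows = if (n > 1) cfg$windows[seq_len(n - 1L)] else list())
}

#' Target sequence for the upcoming trial under an alternation rule
#'
#' With the alternating stage's rule (period 4, alternate LLR) the schedule
#' is indexed by completed trials: trials 1-3 require the base LLRR, every
#' fourth requires the shortened LLR.
#'
#' @param completed_trials Number of trials completed so far in the session.
#' @param cfg A `stage_config` with an alternation rule.
#' @return Character vector: the active target sequence for the next trial.
#' @export
#' @examples
#' cfg <- builtin_stage("LLRR_alternating")
#' alternation_target(3, cfg) # "L" "L" "R"
alternation_target <- function(completed_trials, cfg) {
  if (is.null(cfg$alternation)) {
    stop("stage '", cfg$stage_id, "' has no alternation rule", call. = FALSE)
  }
  next_active(cfg, as.integer(completed_trials))$seq
}

#' Initialize session state
#'
#' @param cfg A `stage_config`.
#' @return A `session_state` list tracking position in the sequence, the
#'   last press time, the active time-out, reward/trial tallies, and the
#'   currently armed (cue-lit) lever.
#' @export
new_session_state <- function(cfg) {
  act <- next_active(cfg, 0L)
  structure(list(
    pos = 0L,
    last_press_tick = NA_integer_,
    timeout_until_tick = NA_integer_,
    rewards = 0L,
    completed_trials = 0L,
    attempts = 0L,
    elapsed_tick = 0L,
    ended = FALSE,
    end_tick = NA_integer_,
    cap_tick = to_ticks(cfg$session_cap_min * 60),
    active_seq = act$seq,
    active_windows = act$windows,
    lit = if (cfg$any_lever) "LR" else if (length(act$seq)) act$seq[1] else NA_character_,
    counts = c(correct_L = 0L, correct_R = 0L, incorrect_L = 0L, incorrect_R = 0L,
               too_fast_L = 0L, too_fast_R = 0L, too_slow_L = 0L, too_slow_R = 0L,
               timeout_L = 0L, timeout_R = 0L)
  ), class = "session_state")
}

cue_codes_on  <- c(L = 81L, R = 82L)
cue_codes_off <- c(L = 83L, R = 84L)

cue_events <- function(from, to, tick_off, tick_on = tick_off) {
  ev <- list()
  levers <- function(x) if (is.na(x)) character(0) else if (x == "LR") c("L", "R") else x
  for (lv in setdiff(levers(from), levers(to))) {
    ev[[length(ev) + 1L]] <- c(tick_off, cue_codes_off[[lv]])
  }
  for (lv in setdiff(levers(to), levers(from))) {
    ev[[length(ev) + 1L]] <- c(tick_on, cue_codes_on[[lv]])
  }
  ev
}

#' Process one lever press
#'
#' The core contingency step. Precedence: a press inside an active time-out
#' is a time-out press (tallied per lever, never advancing the sequence and
#' never extending the time-out); otherwise a press of the wrong lever is an
#' error; otherwise the interval from the previous press is checked against
#' the transition's closed window (too fast / too slow); otherwise the press
#' is correct and the sequence advances. Completing the final press of the
#' active sequence completes the trial, delivers a reward iff the stage is
#' reinforced, and re-arms the sequence (consulting the alternation schedule).
#' Every error resets the sequence position and schedules a
#' `cfg$timeout_s`-second time-out. The first press of a session, and the
#' first press after a reward or after a time-out expires, has no
#' predecessor and is never timing-checked.
#'
#' @param state A `session_state`.
#' @param cfg The stage configuration.
#' @param p A single press (see [press()]): list/row with `t` and `lever`.
#' @return `list(state =, outcome =, events =)` where `outcome` is
#'   `list(role =, trial_completed =, rewarded =)` and `events` is an
#'   integer matrix of `(tick, code)` rows.
#' @export
handle_press <- function(state, cfg, p) {
  if (state$ended) stop("press after session end", call. = FALSE)
  tk <- to_ticks(p$t)
  if (tk >= state$cap_tick) stop("press after session end", call. = FALSE)
  if (tk < state$elapsed_tick) stop("presses must be time-ordered", call. = FALSE)
  state$elapsed_tick <- tk
  lever <- p$lever
  ev <- list()
  role <- NULL
  trial_completed <- FALSE
  rewarded <- FALSE

  in_timeout <- !is.na(state$timeout_until_tick) && tk < state$timeout_until_tick
  if (!in_timeout && !is.na(state$timeout_until_tick)) {
    # time-out expired before this press; offset/cue events were emitted
    # (future-dated) when it was scheduled
    state$timeout_until_tick <- NA_integer_
  }

  if (in_timeout) {
    role <- "timeout_press"
    state$counts[[paste0("timeout_", lever)]] <- state$counts[[paste0("timeout_", lever)]] + 1L
    ev[[length(ev) + 1L]] <- c(tk, press_code(role, lever))
  } else {
    expected <- if (cfg$any_lever) lever else state$active_seq[state$pos + 1L]
    if (lever != expected) {
      role <- "incorrect_lever"
    } else if (state$pos > 0L && !is.na(state$last_press_tick)) {
      w <- state$active_windows[[state$pos]]
      gap <- tk - state$last_press_tick
      if (gap < to_ticks(w[["low"]])) role <- "too_fast"
      else if (gap > to_ticks(w[["high"]])) role <- "too_slow"
      else role <- "correct"
    } else {
      role <- "correct"
    }

    if (role == "correct") {
      state$counts[[paste0("correct_", lever)]] <- state$counts[[paste0("correct_", lever)]] + 1L
      ev[[length(ev) + 1L]] <- c(tk, press_code(role, lever))
      state$pos <- state$pos + 1L
      state$last_press_tick <- tk
      if (state$pos >= length(state$active_seq)) {
        trial_completed <- TRUE
        state$completed_trials <- state$completed_trials + 1L
        state$attempts <- state$attempts + 1L
        ev[[length(ev) + 1L]] <- c(tk, .EVENT_CODES[["trial_complete"]])
        if (cfg$reinforced) {
          rewarded <- TRUE
          state$rewards <- state$rewards + 1L
          ev[[length(ev) + 1L]] <- c(tk, .EVENT_CODES[["reward"]])
        }
        act <- next_active(cfg, state$completed_trials)
        state$active_seq <- act$seq
        state$active_windows <- act$windows
        state$pos <- 0L
        state$last_press_tick <- NA_integer_
        new_lit <- if (cfg$any_lever) "LR" else act$seq[1]
        ev <- c(ev, cue_events(state$lit, new_lit, tk))
        state$lit <- new_lit
        if (state$rewards >= cfg$reward_cap ||
            (!is.na(cfg$trial_cap) && state$completed_trials >= cfg$trial_cap)) {
          state$ended <- TRUE
          state$end_tick <- tk
        }
      } else {
        new_lit <- state$active_seq[state$pos + 1L]
        ev <- c(ev, cue_events(state$lit, new_lit, tk))
        state$lit <- new_lit
      }
    } else {
      state$counts[[paste0(sub("incorrect_lever", "incorrect", role), "_", lever)]] <-
        state$counts[[paste0(sub("incorrect_lever", "incorrect", role), "_", lever)]] + 1L
      ev[[length(ev) + 1L]] <- c(tk, press_code(role, lever))
      state$attempts <- state$attempts + 1L
      state$pos <- 0L
      state$last_press_tick <- NA_integer_
      if (cfg$timeout_s > 0) {
        until <- tk + to_ticks(cfg$timeout_s)
        state$timeout_until_tick <- until
        ev[[length(ev) + 1L]] <- c(tk, .EVENT_CODES[["timeout_on"]])
        ev[[length(ev) + 1L]] <- c(until, .EVENT_CODES[["timeout_off"]])
        new_lit <- if (cfg$any_lever) "LR" else state$active_seq[1]
        # cue goes dark for the lockout, re-arming the first lever at expiry
        ev <- c(ev, cue_events(state$lit, NA_character_, tk))
        ev <- c(ev, cue_events(NA_character_, new_lit, until))
        state$lit <- new_lit
      }
    }
  }

  events <- if (length(ev)) do.call(rbind, ev) else matrix(integer(0), ncol = 2)
  colnames(events) <- c("tick", "code")
  list(
    state = state,
    outcome = list(role = role, trial_completed = trial_completed, rewarded = rewarded),
    events = events
  )
}

finalize_log <- function(cfg, state, ev_list, animal_id, date) {
  end_tick <- if (state$ended && !is.na(state$end_tick)) state$end_tick else state$cap_tick
  ev <- do.call(rbind, ev_list)
  ev <- ev[ev[, 1] <= end_tick, , drop = FALSE]
  # cue lights off at session end for whatever is still armed; a scheduled
  # re-arm falling beyond the end has already been dropped
  for (lv in c("L", "R")) {
    n_on <- sum(ev[, 2] == cue_codes_on[[lv]])
    n_off <- sum(ev[, 2] == cue_codes_off[[lv]])
    if (n_on > n_off) ev <- rbind(ev, c(end_tick, cue_codes_off[[lv]]))
  }
  ev <- rbind(ev, c(end_tick, .EVENT_CODES[["session_end"]]))
  ev <- ev[order(ev[, 1]), , drop = FALSE]
  events <- data.frame(
    t = ev[, 1] * TICK_S,
    code = as.integer(ev[, 2]),
    label = code_label(ev[, 2]),
    stringsAsFactors = FALSE
  )
  summary <- engine_summary(state, end_tick)
  structure(list(
    header = list(
      animal_id = animal_id,
      stage_id = cfg$stage_id,
      date = date,
      fingerprint = cfg_fingerprint(cfg)
    ),
    events = events,
    summary = summary
  ), class = "session_log")
}

engine_summary <- function(state, end_tick) {
  cts <- state$counts
  list(
    rewards = state$rewards,
    completed_trials = state$completed_trials,
    attempts = state$attempts,
    presses = as.list(cts),
    total_presses = sum(cts),
    correct_presses = sum(cts[c("correct_L", "correct_R")]),
    incorrect_presses = sum(cts[c("incorrect_L", "incorrect_R",
                                  "too_fast_L", "too_fast_R",
                                  "too_slow_L", "too_slow_R")]),
    timeout_presses = sum(cts[c("timeout_L", "timeout_R")]),
    end_s = end_tick * TICK_S
  )
}

#' Run a full session over a press stream
#'
#' Replays [handle_press()] over a time-ordered press stream, truncating at
#' session termination (reward cap, trial cap, or time cap, whichever comes
#' first), and assembles the complete session log: every emitted event plus
#' a summary whose counts equal the engine's internal tallies. An empty
#' stream yields an empty session that ends at the time cap.
#'
#' @param cfg A `stage_config` (not a habituation stage; see
#'   [run_habituation()]).
#' @param presses Data frame with columns `t` (seconds, nondecreasing) and
#'   `lever` (`"L"`/`"R"`); see [press_stream()].
#' @param animal_id,date Header metadata recorded in the log.
#' @return A `session_log`: `list(header, events, summary)`.
#' @export
#' @examples
#' cfg <- builtin_stage("LLRR_baseline")
#' log <- run_session(cfg, press_stream(c(10, 11, 15, 16), c("L", "L", "R", "R")))
#' log$summary$rewards
run_session <- function(cfg, presses, animal_id = "sim", date = "1970-01-01") {
  if (length(cfg$target_sequence) == 0) {
    stop("stage '", cfg$stage_id, "' is a habituation stage; use run_habituation()",
         call. = FALSE)
  }
  if (nrow(presses) > 1 && any(diff(presses$t) < -TICK_S / 2)) {
    stop("press stream is not time-ordered", call. = FALSE)
  }
  state <- new_session_state(cfg)
  ev_list <- list(c(0L, .EVENT_CODES[["session_start"]]))
  ev_list <- c(ev_list, cue_events(NA_character_, state$lit, 0L))
  n <- nrow(presses)
  if (n > 0) {
    for (i in seq_len(n)) {
      tk <- to_ticks(presses$t[i])
      if (tk >= state$cap_tick) {
        state$ended <- TRUE
        state$end_tick <- state$cap_tick
        break
      }
      res <- handle_press(state, cfg, list(t = presses$t[i], lever = presses$lever[i]))
      state <- res$state
      if (nrow(res$events)) ev_list[[length(ev_list) + 1L]] <- res$events
      if (state$ended) break
    }
  }
  finalize_log(cfg, state, ev_list, animal_id, date)
}

#' Run a habituation session
#'
#' Habituation stages involve no lever contingencies: the first has the
#' feeder off, the second starts with manually preloaded pellets, and the
#' third delivers a reward automatically every 2 minutes over a 30 minute
#' session (15 deliveries). The log contains only the scheduled events.
#'
#' @param cfg A habituation `stage_config` (empty target sequence).
#' @param animal_id,date Header metadata.
#' @return A `session_log`.
#' @export
#' @examples
#' log <- run_habituation(builtin_stage("Habituation3"))
#' sum(log$events$label == "reward") # 15
run_habituation <- function(cfg, animal_id = "sim", date = "1970-01-01") {
  if (length(cfg$target_sequence) > 0 || is.null(cfg$schedule)) {
    stop("stage '", cfg$stage_id, "' is not a habituation stage", call. = FALSE)
  }
  s <- cfg$schedule
  cap_tick <- to_ticks(cfg$session_cap_min * 60)
  ev <- list(c(0L, .EVENT_CODES[["session_start"]]))
  n_pre <- s$preloaded_pellets %||% 0L
  for (i in seq_len(n_pre)) ev[[length(ev) + 1L]] <- c(0L, .EVENT_CODES[["manual_pellet"]])
  n_del <- 0L
  if (!is.na(s$delivery_interval_s %||% NA_real_) && (s$n_deliveries %||% 0L) > 0) {
    for (k in seq_len(s$n_deliveries)) {
      tk <- to_ticks(k * s$delivery_interval_s)
      if (tk > cap_tick) break
      ev[[length(ev) + 1L]] <- c(tk, .EVENT_CODES[["reward"]])
      n_del <- n_del + 1L
    }
  }
  ev[[length(ev) + 1L]] <- c(cap_tick, .EVENT_CODES[["session_end"]])
  m <- do.call(rbind, ev)
  m <- m[order(m[, 1]), , drop = FALSE]
  events <- data.frame(t = m[, 1] * TICK_S, code = as.integer(m[, 2]),
                       label = code_label(m[, 2]), stringsAsFactors = FALSE)
  state <- new_session_state(cfg)
  state$rewards <- n_del + n_pre
  summary <- engine_summary(state, cap_tick)
  structure(list(
    header = list(animal_id = animal_id, stage_id = cfg$stage_id, date = date,
                  fingerprint = cfg_fingerprint(cfg)),
    events = events,
    summary = summary
  ), class = "session_log")
}

#' @export
print.session_log <- function(x, ...) {
  cat(sprintf("<session_log> animal %s, stage %s (%s)\n",
              x$header$animal_id, x$header$stage_id, x$header$date))
  cat(sprintf("  %d events, %d rewards, %d completed trials, ended at %.2f s\n",
              nrow(x$events), x$summary$rewards, x$summary$completed_trials,
              x$summary$end_s))
  invisible(x)
}
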