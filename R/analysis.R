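# Behavioral parameter extraction from session logs.
#
# Everything here is computed by replaying the press stream recorded in the
# log through the engine and checking that the recorded contingency events
# match the recomputed ones — the replay is the integrity check, and the
# engine's tallies are the oracle the summary must reproduce.

PRESS_LABELS <- names(.EVENT_CODES)[grep("^press_", names(.EVENT_CODES))]

log_presses <- function(log) {
  ev <- log$events[log$events$label %in% PRESS_LABELS, , drop = FALSE]
  data.frame(t = ev$t, lever = press_lever_of_code(ev$code),
             role = unname(press_role_of_code(ev$code)),
             stringsAsFactors = FALSE)
}

macron <- function(s) {
  n <- nchar(s)
  paste0(substr(s, 1, n - 1), substr(s, n, n), "\u0304")
}

category_label <- function(emitted, mode, pos, rewarded) {
  em <- paste(emitted, collapse = "")
  switch(mode,
    none = paste0(em, "P"),
    wrong = em,
    too_fast = em,
    too_slow = macron(em)
  )
}

internal_category <- function(emitted, mode, pos) {
  em <- paste(emitted, collapse = "")
  switch(mode,
    none = paste0(em, "_ok"),
    wrong = paste0(em, "_wrong", pos),
    too_fast = paste0(em, "_fast", pos),
    too_slow = paste0(em, "_slow", pos)
  )
}

#' Classify the trials of a session
#'
#' Replays the press stream recorded in the log against the stage
#' configuration, verifies that every recorded press role matches the
#' recomputed contingency (an integrity error names the first divergent
#' event otherwise), and partitions all non-time-out presses into trials. A
#' trial starts at the first non-time-out press after session start, a
#' reward, or time-out expiry, and ends with a completed sequence or an
#' error press; time-out presses belong to no trial.
#'
#' Each trial gets an internal category (`emitted prefix` + failure mode and
#' position, e.g. `"LL_fast2"`) and a display label matching the field's
#' conventions: `LLRRP` correct complete sequence, `R`/`LR`/`LLL`/`LLRL`
#' wrong-lever errors named by the emitted string, `LL`/`LLRR` too-fast
#' errors, and a trailing macron for too-slow errors.
#'
#' @param log A `session_log`.
#' @param cfg The stage configuration the log was recorded under.
#' @return A data frame of trial records: `start_t`, `end_t`, `n_presses`,
#'   `emitted`, `category`, `display`, `fail_mode`, `fail_pos`, `rewarded`,
#'   `seq_len` (active target length), with the per-trial press times and
#'   realized interpress intervals in list-columns `press_t` and `intervals`.
#' @export
classify_trials <- function(log, cfg) {
  pr <- log_presses(log)
  n <- nrow(pr)
  state <- new_session_state(cfg)
  rec <- list()
  cur_t <- numeric(0)
  cur_lv <- character(0)
  cur_target_len <- length(state$active_seq)
  for (i in seq_len(n)) {
    if (state$ended) {
      stop("log integrity error: press at ", pr$t[i], " s after recomputed session end",
           call. = FALSE)
    }
    res <- handle_press(state, cfg, list(t = pr$t[i], lever = pr$lever[i]))
    state <- res$state
    role <- res$outcome$role
    if (role != pr$role[i]) {
      stop(sprintf(
        "log integrity error at %.2f s: recorded press role '%s' but contingencies give '%s'",
        pr$t[i], pr$role[i], role), call. = FALSE)
    }
    if (role == "timeout_press") next
    if (length(cur_t) == 0) cur_target_len <- length(state$active_seq)
    cur_t <- c(cur_t, pr$t[i])
    cur_lv <- c(cur_lv, pr$lever[i])
    finished <- res$outcome$trial_completed ||
      role %in% c("incorrect_lever", "too_fast", "too_slow")
    if (finished) {
      mode <- switch(role, correct = "none", incorrect_lever = "wrong",
                     too_fast = "too_fast", too_slow = "too_slow")
      pos <- length(cur_t)
      rec[[length(rec) + 1L]] <- list(
        start_t = cur_t[1], end_t = cur_t[pos], n_presses = pos,
        emitted = paste(cur_lv, collapse = ""),
        category = internal_category(cur_lv, mode, pos),
        display = category_label(cur_lv, mode, pos, res$outcome$rewarded),
        fail_mode = mode, fail_pos = if (mode == "none") NA_integer_ else pos,
        rewarded = res$outcome$rewarded,
        seq_len = if (res$outcome$trial_completed) pos else cur_target_len,
        press_t = list(cur_t), intervals = list(if (pos > 1) diff(cur_t) else numeric(0))
      )
      cur_t <- numeric(0)
      cur_lv <- character(0)
    }
  }
  if (length(rec) == 0) {
    return(data.frame(start_t = numeric(0), end_t = numeric(0),
                      n_presses = integer(0), emitted = character(0),
                      category = character(0), display = character(0),
                      fail_mode = character(0), fail_pos = integer(0),
                      rewarded = logical(0), seq_len = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(
    start_t = vapply(rec, `[[`, 0, "start_t"),
    end_t = vapply(rec, `[[`, 0, "end_t"),
    n_presses = vapply(rec, function(r) as.integer(r$n_presses), 1L),
    emitted = vapply(rec, `[[`, "", "emitted"),
    category = vapply(rec, `[[`, "", "category"),
    display = vapply(rec, `[[`, "", "display"),
    fail_mode = vapply(rec, `[[`, "", "fail_mode"),
    fail_pos = vapply(rec, function(r) as.integer(r$fail_pos %||% NA_integer_), 1L),
    rewarded = vapply(rec, `[[`, TRUE, "rewarded"),
    seq_len = vapply(rec, function(r) as.integer(r$seq_len), 1L),
    stringsAsFactors = FALSE
  )
  out$press_t <- lapply(rec, function(r) r$press_t[[1]])
  out$intervals <- lapply(rec, function(r) r$intervals[[1]])
  out
}

transition_names <- function(cfg) {
  sq <- cfg$target_sequence
  if (length(sq) < 2) return(character(0))
  paste0(sq[-length(sq)], "-", sq[-1])
}

#' Summarize a session
#'
#' Computes the full per-session parameter set: rewards and completed
#' trials, presses by role and lever, the trial-category table, per-
#' transition interpress-interval statistics (computed only over correctly
#' executed sequences; `cv = sd/mean` with the sample sd), bout and pause
#' durations, and cumulative series for the standard metrics.
#'
#' @param log A `session_log`.
#' @param cfg Its stage configuration.
#' @param gap_threshold_s Interpress gap (s) splitting bouts from pauses
#'   (default 30).
#' @return A `session_summary` list.
#' @export
summarize_session <- function(log, cfg, gap_threshold_s = 30) {
  trials <- classify_trials(log, cfg)
  counts <- summary_from_events(log$events)
  cat_counts <- if (nrow(trials)) table(trials$display) else table(character(0))
  # interval statistics over correct complete sequences only, per transition
  ok <- trials[trials$fail_mode == "none" & trials$n_presses == trials$seq_len, ,
               drop = FALSE]
  n_trans <- max(0L, length(cfg$target_sequence) - 1L)
  tnames <- transition_names(cfg)
  istats <- if (n_trans > 0) {
    do.call(rbind, lapply(seq_len(n_trans), function(i) {
      vals <- unlist(lapply(ok$intervals, function(iv) {
        if (length(iv) >= i) iv[i] else NULL
      }))
      n <- length(vals)
      m <- if (n) mean(vals) else NA_real_
      s <- if (n > 1) stats::sd(vals) else if (n == 1) 0 else NA_real_
      data.frame(transition = tnames[i], n = n, mean = m, sd = s,
                 cv = if (!is.na(m) && m > 0 && !is.na(s)) s / m else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(transition = character(0), n = integer(0), mean = numeric(0),
               sd = numeric(0), cv = numeric(0), stringsAsFactors = FALSE)
  }
  bp <- detect_bouts(log, gap_threshold_s)
  cum <- lapply(stats::setNames(nm = c("rewards", "incorrect_presses",
                                       "timeout_presses", "completed_trials",
                                       "correct_presses")),
                function(m) cumulative_series(log, m))
  structure(c(
    list(stage_id = log$header$stage_id, animal_id = log$header$animal_id,
         date = log$header$date),
    counts,
    list(n_trials = nrow(trials),
         category_counts = cat_counts,
         interval_stats = istats,
         bout_durations = bp$bout_durations,
         pause_durations = bp$pause_durations,
         cumulative = cum)
  ), class = "session_summary")
}

#' Split a session into activity bouts and pauses
#'
#' Any interpress gap of at least `gap_threshold_s` seconds is a pause;
#' bouts are the maximal complementary runs of pressing. Together the
#' durations partition the span from the first to the last press. The
#' threshold is configurable because the split point is an analysis choice,
#' not a task parameter.
#'
#' @param log A `session_log` (all press events count as activity,
#'   including time-out presses).
#' @param gap_threshold_s Positive gap threshold in seconds (default 30).
#' @return `list(bout_durations =, pause_durations =)` in seconds.
#' @export
detect_bouts <- function(log, gap_threshold_s = 30) {
  stopifnot(gap_threshold_s > 0)
  t <- log_presses(log)$t
  if (length(t) <= 1) {
    return(list(bout_durations = if (length(t)) 0 else numeric(0),
                pause_durations = numeric(0)))
  }
  gaps <- diff(t)
  is_pause <- gaps >= gap_threshold_s
  pause_durations <- gaps[is_pause]
  cut_after <- which(is_pause)
  starts <- c(1L, cut_after + 1L)
  ends <- c(cut_after, length(t))
  bout_durations <- t[ends] - t[starts]
  list(bout_durations = bout_durations, pause_durations = pause_durations)
}

CUM_METRIC_LABELS <- list(
  rewards = "reward",
  incorrect_presses = c("press_incorrect_L", "press_incorrect_R",
                        "press_too_fast_L", "press_too_fast_R",
                        "press_too_slow_L", "press_too_slow_R"),
  timeout_presses = c("press_timeout_L", "press_timeout_R"),
  completed_trials = "trial_complete",
  correct_presses = c("press_correct_L", "press_correct_R")
)

#' Cumulative record of a session metric
#'
#' The classic cumulative curve: a nondecreasing step function starting at
#' zero whose final value equals the session's summary count for the metric.
#'
#' @param log A `session_log`.
#' @param metric One of `"rewards"`, `"incorrect_presses"`,
#'   `"timeout_presses"`, `"completed_trials"`, `"correct_presses"`.
#' @return Data frame with columns `t` (s) and `count`.
#' @export
cumulative_series <- function(log, metric) {
  labels <- CUM_METRIC_LABELS[[metric]]
  if (is.null(labels)) {
    stop("unknown metric '", metric, "'; choose one of: ",
         paste(names(CUM_METRIC_LABELS), collapse = ", "), call. = FALSE)
  }
  t <- log$events$t[log$events$label %in% labels]
  data.frame(t = c(0, t), count = 0:length(t))
}

#' Apply a stage's advancement/exclusion rule to a session history
#'
#' Implements the per-stage rules: a rewards-criterion stage advances after
#' the required number of consecutive successful sessions (e.g. 40 rewards
#' on 3 consecutive days); once the session cap is reached without meeting
#' the criterion, the animal is excluded outright on the pre-timed stages,
#' while on the timed stages it is excluded only when the final session also
#' has fewer than the minimum trial count and is otherwise force-advanced.
#' Probe stages run a fixed number of sessions with no criteria.
#'
#' @param history List of session summaries from the same stage, in order
#'   (engine summaries or [summarize_session()] results both work).
#' @param rule An [advancement_rule()].
#' @return `"advance"`, `"repeat"`, or `"exclude"`.
#' @export
#' @examples
#' cfg <- builtin_stage("LR")
#' s40 <- list(rewards = 40, attempts = 45)
#' check_criteria(list(s40, s40, s40), cfg$criteria) # "advance"
check_criteria <- function(history, rule) {
  stopifnot(length(history) >= 1, inherits(rule, "advancement_rule"))
  n <- length(history)
  if (rule$type == "none") {
    k <- if (is.na(rule$fixed_sessions)) 1L else rule$fixed_sessions
    return(if (n >= k) "advance" else "repeat")
  }
  rewards <- vapply(history, function(s) as.numeric(s$rewards), 0)
  trials <- vapply(history, function(s) {
    as.numeric(s$n_trials %||% s$attempts %||% NA_real_)
  }, 0)
  k <- rule$consecutive_days
  if (n >= k && all(rewards[(n - k + 1):n] >= rule$reward_target)) {
    return("advance")
  }
  if (!is.na(rule$max_sessions) && n >= rule$max_sessions) {
    if (!is.na(rule$last_session_min_trials)) {
      if (!is.na(trials[n]) && trials[n] < rule$last_session_min_trials) {
        return("exclude")
      }
      return(if (rule$force_advance) "advance" else "exclude")
    }
    return(if (rule$force_advance) "advance" else "exclude")
  }
  "repeat"
}

#' Flag outliers by the two-standard-deviation rule
#'
#' Single pass: values outside `mean(x) +/- 2 * sd(x)` (sample sd, n-1
#' denominator) are flagged and excluded; the rule is not iterated on its
#' own output.
#'
#' @param values Numeric vector, at least 3 values.
#' @return `list(kept =, excluded =)` where `excluded` holds the indices of
#'   flagged values.
#' @export
#' @examples
#' exclude_outliers(c(1, 1, 1, 1, 1, 200))$excluded # 6
exclude_outliers <- function(values) {
  if (length(values) < 3) {
    stop("outlier rule needs at least 3 values", call. = FALSE)
  }
  m <- mean(values)
  s <- stats::sd(values)
  out <- which(values < m - 2 * s | values > m + 2 * s)
  list(kept = if (length(out)) values[-out] else values, excluded = out)
}

PROBE_STAGES <- c("LLRR_alternating", "LLRR_LEFT", "LLRR_RIGHT", "LLRR_MIDDLE",
                  "Extinction")

#' Probe-stage flexibility measures
#'
#' Stage-specific counters for the flexibility probes:
#' * alternating and RIGHT — number of fourth presses emitted too fast
#'   (premature) and too slow (delayed); on the alternating stage also the
#'   number of surplus fourth presses emitted right after a completed
#'   shortened (LLR) trial, i.e. stereotyped completions.
#' * MIDDLE — number of third presses incorrect Left (sequence-structure
#'   insertions) and third presses emitted too fast.
#' * Extinction — the duration of the last interpress interval of every
#'   completed trial, and the number of trials started with a Right press
#'   immediately after an unrewarded completed trial.
#'
#' @param log A `session_log` from a probe or extinction stage.
#' @param cfg Its stage configuration.
#' @return Named list of counters (and, for extinction, the last-interval
#'   vector).
#' @export
probe_measures <- function(log, cfg) {
  if (!cfg$stage_id %in% PROBE_STAGES) {
    stop("stage '", cfg$stage_id, "' is not a probe or extinction stage",
         call. = FALSE)
  }
  trials <- classify_trials(log, cfg)
  fast_at <- function(p) sum(trials$fail_mode == "too_fast" & trials$fail_pos == p)
  slow_at <- function(p) sum(trials$fail_mode == "too_slow" & trials$fail_pos == p)
  wrong_at <- function(p, lv) sum(trials$fail_mode == "wrong" & trials$fail_pos == p &
                                    substr(trials$emitted, p, p) == lv)
  switch(cfg$stage_id,
    LLRR_alternating = {
      prev_short_ok <- c(FALSE, trials$fail_mode[-nrow(trials)] == "none" &
                                  trials$seq_len[-nrow(trials)] == 3)
      list(
        fourth_too_fast = fast_at(4L),
        fourth_too_slow = slow_at(4L),
        surplus_fourth_press = sum(prev_short_ok & trials$emitted == "R" &
                                     trials$fail_mode == "wrong")
      )
    },
    LLRR_RIGHT = list(fourth_too_fast = fast_at(4L), fourth_too_slow = slow_at(4L)),
    LLRR_LEFT = list(second_too_fast = fast_at(2L), second_too_slow = slow_at(2L)),
    LLRR_MIDDLE = list(
      third_incorrect_left = wrong_at(3L, "L"),
      third_too_fast = fast_at(3L)
    ),
    Extinction = {
      done <- trials$fail_mode == "none"
      last_iv <- vapply(trials$intervals[done], function(iv) iv[length(iv)], 0)
      after_done <- c(FALSE, done[-nrow(trials)])
      list(
        completed_trials = sum(done),
        last_interval_s = last_iv,
        right_start_after_omission = sum(after_done &
                                           substr(trials$emitted, 1, 1) == "R")
      )
    }
  )
}

#' @export
print.session_summary <- function(x, ...) {
  cat(sprintf("<session_summary> %s / %s: %d rewards, %d trials, %d presses\n",
              x$animal_id, x$stage_id, x$rewards, x$n_trials, x$total_presses))
  invisible(x)
}
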