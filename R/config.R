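# Stage configurations for the timed sequence task.
#
# A "stage" is one block of the 15-stage protocol: three habituation
# sessions, basic operant training, sequence acquisition (LR, LLR, LLRR),
# the timed LLRR stages (baseline and stricter limits), and the flexibility
# probes (alternating 3xLLRR + 1xLLR, LEFT, RIGHT, MIDDLE, extinction),
# plus the baseline re-establishment stage run between probes.

#' Interpress timing window
#'
#' A closed interval `[low, high]` of seconds within which the interval
#' between two consecutive presses of a trial must fall. An interval exactly
#' equal to either bound is correct. Untimed transitions use the sentinel
#' window `[0.05, 3600]` rather than infinity, mirroring the acquisition
#' software's defaults.
#'
#' @param low,high Window bounds in seconds, `0 <= low <= high`.
#' @return An object of class `time_window`: a named numeric vector
#'   `c(low=, high=)`.
#' @export
#' @examples
#' time_window(0.5, 5)
time_window <- function(low, high) {
  stopifnot(is.numeric(low), is.numeric(high), length(low) == 1, length(high) == 1)
  if (is.na(low) || is.na(high) || low < 0 || low > high) {
    stop("time_window: need 0 <= low <= high, got [", low, ", ", high, "]")
  }
  structure(c(low = low, high = high), class = "time_window")
}

#' @export
print.time_window <- function(x, ...) {
  cat(sprintf("[%g, %g] s\n", x[["low"]], x[["high"]]))
  invisible(x)
}

# Sentinel for transitions with no experimenter-imposed timing.
untimed_window <- function() time_window(0.05, 3600)

is_untimed <- function(w) w[["high"]] >= 3600

#' Stage advancement / exclusion rule
#'
#' Encodes the per-stage performance criteria and exclusion rules: how many
#' consecutive successful sessions advance an animal, after how many sessions
#' an animal is excluded or force-advanced, and the minimum trial count on
#' the final session below which the animal is excluded.
#'
#' @param type `"rewards"` (success means the session reaches
#'   `reward_target` rewards) or `"none"` (probe stages: advance after
#'   `fixed_sessions` sessions, never exclude).
#' @param reward_target Rewards needed for a session to count as successful.
#' @param consecutive_days Number of consecutive successful sessions needed
#'   to advance.
#' @param max_sessions Session cap; reaching it without meeting the criterion
#'   triggers exclusion or forced advancement. `NA` for uncapped.
#' @param last_session_min_trials If set, an animal at `max_sessions` is
#'   excluded only when the final session has fewer than this many trials.
#' @param fixed_sessions For `type = "none"`: number of sessions to run.
#' @param force_advance Whether an animal that exhausts `max_sessions`
#'   without exclusion is moved to the next stage automatically.
#' @return An object of class `advancement_rule`.
#' @export
advancement_rule <- function(type = c("rewards", "none"),
                             reward_target = NA_real_,
                             consecutive_days = 1L,
                             max_sessions = NA_integer_,
                             last_session_min_trials = NA_integer_,
                             fixed_sessions = NA_integer_,
                             force_advance = FALSE) {
  type <- match.arg(type)
  structure(
    list(
      type = type,
      reward_target = as.numeric(reward_target),
      consecutive_days = as.integer(consecutive_days),
      max_sessions = as.integer(max_sessions),
      last_session_min_trials = as.integer(last_session_min_trials),
      fixed_sessions = as.integer(fixed_sessions),
      force_advance = isTRUE(force_advance)
    ),
    class = "advancement_rule"
  )
}

#' Stage configuration
#'
#' Full contingency description of one protocol stage: the target press
#' sequence, one timing window per transition between consecutive presses,
#' the post-error time-out, session caps, reinforcement flag, the optional
#' alternation rule, the habituation delivery schedule, and the advancement
#' rule.
#'
#' @param stage_id Stage name (free for user-defined stages; see
#'   [stage_names()] for the built-in ones).
#' @param target_sequence Character vector over `c("L", "R")`; empty for
#'   habituation stages, length 1 with `any_lever = TRUE` for basic operant
#'   training.
#' @param windows List of [time_window()] objects, one per transition
#'   (`length(target_sequence) - 1`).
#' @param any_lever If `TRUE`, any lever counts as the (single) target press.
#' @param timeout_s Post-error lockout in seconds (default 5).
#' @param session_cap_min Session duration cap in minutes.
#' @param reward_cap Session reward cap; the session ends at whichever of the
#'   two caps is reached first.
#' @param trial_cap Completed-trial cap (used by extinction, where no rewards
#'   are delivered); `NA` to disable.
#' @param reinforced Whether completed trials deliver a reward.
#' @param alternation `NULL`, or `list(period =, alternate_sequence =)`: every
#'   `period`-th completed trial requires the alternate sequence instead.
#' @param schedule `NULL`, or
#'   `list(delivery_interval_s =, n_deliveries =, preloaded_pellets =)` for
#'   habituation stages.
#' @param criteria An [advancement_rule()].
#' @return A validated object of class `stage_config`.
#' @export
#' @examples
#' cfg <- builtin_stage("LLRR_baseline")
#' cfg$windows[[2]] # the 0.5-20 s L-R window
stage_config <- function(stage_id,
                         target_sequence = character(0),
                         windows = list(),
                         any_lever = FALSE,
                         timeout_s = 5,
                         session_cap_min = 60,
                         reward_cap = 40,
                         trial_cap = NA_real_,
                         reinforced = TRUE,
                         alternation = NULL,
                         schedule = NULL,
                         criteria = advancement_rule("none", fixed_sessions = 1L)) {
  cfg <- structure(
    list(
      stage_id = as.character(stage_id),
      target_sequence = as.character(target_sequence),
      windows = windows,
      any_lever = isTRUE(any_lever),
      timeout_s = as.numeric(timeout_s),
      session_cap_min = as.numeric(session_cap_min),
      reward_cap = as.numeric(reward_cap),
      trial_cap = as.numeric(trial_cap),
      reinforced = isTRUE(reinforced),
      alternation = alternation,
      schedule = schedule,
      criteria = criteria
    ),
    class = "stage_config"
  )
  validate_stage_config(cfg)
}

#' Validate a stage configuration
#'
#' Checks the structural invariants: window count equals sequence length
#' minus one, positive caps, lever labels in `{L, R}`, alternation only with
#' a shorter alternate sequence, schedule only on press-free stages.
#'
#' @param cfg A `stage_config`.
#' @return `cfg`, invisibly unchanged, or an error naming the stage and the
#'   offending field.
#' @export
validate_stage_config <- function(cfg) {
  bad <- function(field, msg) {
    stop("invalid stage '", cfg$stage_id, "', field '", field, "': ", msg,
         call. = FALSE)
  }
  seq_len_ <- length(cfg$target_sequence)
  if (seq_len_ > 0 && !all(cfg$target_sequence %in% c("L", "R"))) {
    bad("target_sequence", "lever labels must be 'L' or 'R'")
  }
  n_win <- length(cfg$windows)
  if (seq_len_ > 0 && n_win != seq_len_ - 1) {
    bad("windows", sprintf("need %d windows for a %d-press sequence, got %d",
                           seq_len_ - 1, seq_len_, n_win))
  }
  if (seq_len_ == 0 && n_win != 0) bad("windows", "habituation stages take no windows")
  for (w in cfg$windows) {
    if (!inherits(w, "time_window")) bad("windows", "entries must be time_window objects")
  }
  if (!is.na(cfg$timeout_s) && cfg$timeout_s < 0) bad("timeout_s", "must be nonnegative")
  if (is.na(cfg$session_cap_min) || cfg$session_cap_min <= 0) {
    bad("session_cap_min", "must be positive")
  }
  if (is.na(cfg$reward_cap) || cfg$reward_cap <= 0) bad("reward_cap", "must be positive")
  if (cfg$any_lever && seq_len_ != 1) {
    bad("any_lever", "any-lever mode requires a length-1 target sequence")
  }
  if (!is.null(cfg$alternation)) {
    a <- cfg$alternation
    if (is.null(a$period) || a$period < 2) bad("alternation", "period must be >= 2")
    if (!all(a$alternate_sequence %in% c("L", "R"))) {
      bad("alternation", "alternate sequence labels must be 'L' or 'R'")
    }
    if (length(a$alternate_sequence) > seq_len_) {
      bad("alternation", "alternate sequence may not be longer than the base sequence")
    }
  }
  if (!is.null(cfg$schedule) && seq_len_ > 0) {
    bad("schedule", "delivery schedules apply only to press-free stages")
  }
  if (!inherits(cfg$criteria, "advancement_rule")) {
    bad("criteria", "must be an advancement_rule")
  }
  invisible(cfg)
}

#' @export
print.stage_config <- function(x, ...) {
  cat("<stage_config> ", x$stage_id, "\n", sep = "")
  if (length(x$target_sequence)) {
    cat("  sequence: ", paste(x$target_sequence, collapse = ""),
        if (x$any_lever) " (any lever)", "\n", sep = "")
    if (length(x$windows)) {
      b <- vapply(x$windows, function(w) sprintf("[%g,%g]", w[1], w[2]), "")
      cat("  windows : ", paste(b, collapse = " "), " s\n", sep = "")
    }
  } else {
    cat("  habituation stage\n")
  }
  cat(sprintf("  caps    : %g min / %g rewards%s; timeout %g s; %s\n",
              x$session_cap_min, x$reward_cap,
              if (!is.na(x$trial_cap)) sprintf(" / %g trials", x$trial_cap) else "",
              x$timeout_s,
              if (x$reinforced) "reinforced" else "not reinforced"))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Built-in stages (Tables 1-4 and the Methods stage descriptions).

baseline_windows <- function() {
  list(time_window(0.5, 5), time_window(0.5, 20), time_window(0.5, 5))
}

.stage_builders <- list(
  Habituation1 = function() stage_config(
    "Habituation1",
    session_cap_min = 10, reward_cap = 40,
    schedule = list(delivery_interval_s = NA_real_, n_deliveries = 0L,
                    preloaded_pellets = 0L),
    criteria = advancement_rule("none", fixed_sessions = 1L)
  ),
  Habituation2 = function() stage_config(
    "Habituation2",
    session_cap_min = 10, reward_cap = 40,
    schedule = list(delivery_interval_s = NA_real_, n_deliveries = 0L,
                    preloaded_pellets = 4L),
    criteria = advancement_rule("rewards", reward_target = 4,
                                consecutive_days = 1L, max_sessions = 10L)
  ),
  Habituation3 = function() stage_config(
    "Habituation3",
    session_cap_min = 30, reward_cap = 15,
    schedule = list(delivery_interval_s = 120, n_deliveries = 15L,
                    preloaded_pellets = 0L),
    criteria = advancement_rule("rewards", reward_target = 15,
                                consecutive_days = 1L, max_sessions = 10L)
  ),
  OperantTraining = function() stage_config(
    "OperantTraining",
    target_sequence = "L", any_lever = TRUE,
    session_cap_min = 30, reward_cap = 40,
    criteria = advancement_rule("rewards", reward_target = 40,
                                consecutive_days = 1L, max_sessions = 10L)
  ),
  LR = function() stage_config(
    "LR",
    target_sequence = c("L", "R"),
    windows = list(untimed_window()),
    criteria = advancement_rule("rewards", reward_target = 40,
                                consecutive_days = 3L, max_sessions = 10L)
  ),
  LLR = function() stage_config(
    "LLR",
    target_sequence = c("L", "L", "R"),
    windows = list(untimed_window(), untimed_window()),
    criteria = advancement_rule("rewards", reward_target = 40,
                                consecutive_days = 3L, max_sessions = 10L)
  ),
  LLRR = function() stage_config(
    "LLRR",
    target_sequence = c("L", "L", "R", "R"),
    windows = list(untimed_window(), untimed_window(), untimed_window()),
    criteria = advancement_rule("rewards", reward_target = 40,
                                consecutive_days = 3L, max_sessions = 10L)
  ),
  LLRR_baseline = function() stage_config(
    "LLRR_baseline",
    target_sequence = c("L", "L", "R", "R"),
    windows = baseline_windows(),
    criteria = advancement_rule("rewards", reward_target = 40,
                                consecutive_days = 3L, max_sessions = 10L,
                                last_session_min_trials = 10L,
                                force_advance = TRUE)
  ),
  LLRR_strict = function() stage_config(
    "LLRR_strict",
    target_sequence = c("L", "L", "R", "R"),
    windows = list(time_window(0.5, 2), time_window(0.5, 10), time_window(0.5, 2)),
    criteria = advancement_rule("rewards", reward_target = 40,
                                consecutive_days = 3L, max_sessions = 10L,
                                last_session_min_trials = 10L,
                                force_advance = TRUE)
  ),
  LLRR_alternating = function() stage_config(
    "LLRR_alternating",
    target_sequence = c("L", "L", "R", "R"),
    windows = baseline_windows(),
    alternation = list(period = 4L, alternate_sequence = c("L", "L", "R")),
    criteria = advancement_rule("none", fixed_sessions = 3L)
  ),
  LLRR_rebaseline = function() stage_config(
    "LLRR_rebaseline",
    target_sequence = c("L", "L", "R", "R"),
    windows = baseline_windows(),
    criteria = advancement_rule("rewards", reward_target = 40,
                                consecutive_days = 1L, max_sessions = 3L,
                                last_session_min_trials = 10L,
                                force_advance = TRUE)
  ),
  LLRR_LEFT = function() stage_config(
    "LLRR_LEFT",
    target_sequence = c("L", "L", "R", "R"),
    windows = list(time_window(1.5, 5), time_window(0.5, 20), time_window(0.5, 5)),
    criteria = advancement_rule("none", fixed_sessions = 3L)
  ),
  LLRR_RIGHT = function() stage_config(
    "LLRR_RIGHT",
    target_sequence = c("L", "L", "R", "R"),
    windows = list(time_window(0.5, 5), time_window(0.5, 20), time_window(1.5, 5)),
    criteria = advancement_rule("none", fixed_sessions = 3L)
  ),
  LLRR_MIDDLE = function() stage_config(
    "LLRR_MIDDLE",
    target_sequence = c("L", "L", "R", "R"),
    windows = list(time_window(0.5, 5), time_window(3, 20), time_window(0.5, 5)),
    criteria = advancement_rule("none", fixed_sessions = 3L)
  ),
  Extinction = function() stage_config(
    "Extinction",
    target_sequence = c("L", "L", "R", "R"),
    windows = baseline_windows(),
    reinforced = FALSE, trial_cap = 40,
    criteria = advancement_rule("none", fixed_sessions = 1L)
  )
)

#' Names of the built-in stages
#'
#' The 15 stages of the protocol, in canonical order: three habituations,
#' basic operant training, the LR/LLR/LLRR acquisition sequence, timed LLRR
#' with baseline then stricter limits, the alternating sequence probe, the
#' baseline re-establishment stage, the LEFT/RIGHT/MIDDLE timing probes, and
#' extinction.
#'
#' @return Character vector of length 15.
#' @export
stage_names <- function() names(.stage_builders)

#' Retrieve a built-in stage configuration
#'
#' Returns the fully populated canonical configuration for one of the 15
#' protocol stages. Repeated calls return identical values.
#'
#' @param stage_id One of [stage_names()].
#' @return A `stage_config`.
#' @export
#' @examples
#' builtin_stage("LLRR_strict")$windows[[1]] # 0.5-2 s L-L
builtin_stage <- function(stage_id) {
  b <- .stage_builders[[stage_id]]
  if (is.null(b)) {
    stop("unknown stage '", stage_id, "'; valid stages: ",
         paste(stage_names(), collapse = ", "), call. = FALSE)
  }
  b()
}

#' The canonical stage protocol
#'
#' @param flow If `TRUE` (default) returns the full study flow in which the
#'   baseline re-establishment stage recurs after each flexibility probe
#'   (18 entries); if `FALSE`, each of the 15 stages once, in canonical
#'   order.
#' @return Ordered list of `stage_config` objects.
#' @export
builtin_protocol <- function(flow = TRUE) {
  ids <- if (flow) {
    c("Habituation1", "Habituation2", "Habituation3", "OperantTraining",
      "LR", "LLR", "LLRR", "LLRR_baseline", "LLRR_strict",
      "LLRR_alternating", "LLRR_rebaseline",
      "LLRR_LEFT", "LLRR_rebaseline",
      "LLRR_RIGHT", "LLRR_rebaseline",
      "LLRR_MIDDLE", "LLRR_rebaseline",
      "Extinction")
  } else {
    stage_names()
  }
  lapply(ids, builtin_stage)
}

# ---------------------------------------------------------------------------
# Protocol documents: flat YAML, one stage per block.

cfg_to_plain <- function(cfg) {
  out <- list(
    stage_id = cfg$stage_id,
    target_sequence = as.list(cfg$target_sequence),
    windows = lapply(cfg$windows, function(w) list(low = w[["low"]], high = w[["high"]])),
    any_lever = cfg$any_lever,
    timeout_s = cfg$timeout_s,
    session_cap_min = cfg$session_cap_min,
    reward_cap = cfg$reward_cap,
    trial_cap = if (is.na(cfg$trial_cap)) NULL else cfg$trial_cap,
    reinforced = cfg$reinforced,
    alternation = if (is.null(cfg$alternation)) NULL else list(
      period = cfg$alternation$period,
      alternate_sequence = as.list(cfg$alternation$alternate_sequence)
    ),
    schedule = if (is.null(cfg$schedule)) NULL else {
      s <- cfg$schedule
      list(
        delivery_interval_s = if (is.na(s$delivery_interval_s)) NULL else s$delivery_interval_s,
        n_deliveries = s$n_deliveries,
        preloaded_pellets = s$preloaded_pellets
      )
    },
    criteria = {
      r <- cfg$criteria
      drop_na <- function(x) if (length(x) == 1 && is.na(x)) NULL else x
      list(
        type = r$type,
        reward_target = drop_na(r$reward_target),
        consecutive_days = r$consecutive_days,
        max_sessions = drop_na(r$max_sessions),
        last_session_min_trials = drop_na(r$last_session_min_trials),
        fixed_sessions = drop_na(r$fixed_sessions),
        force_advance = r$force_advance
      )
    }
  )
  out[!vapply(out, is.null, TRUE)]
}

plain_to_cfg <- function(x) {
  if (is.null(x$stage_id)) stop("protocol stage block lacks a stage_id", call. = FALSE)
  # start from the builtin of the same name, when one exists, so that a block
  # giving only a stage_id (or a single override) inherits canonical defaults
  base <- if (x$stage_id %in% stage_names()) builtin_stage(x$stage_id) else NULL
  get_field <- function(field, default) {
    if (!is.null(x[[field]])) x[[field]]
    else if (!is.null(base)) base[[field]]
    else default
  }
  windows <- if (!is.null(x$windows)) {
    lapply(x$windows, function(w) {
      w <- unlist(w)
      if (length(w) != 2) {
        stop("invalid stage '", x$stage_id, "', field 'windows': ",
             "each window needs two bounds", call. = FALSE)
      }
      time_window(as.numeric(w[[1]]), as.numeric(w[[2]]))
    })
  } else if (!is.null(base)) base$windows else list()
  alternation <- if (!is.null(x$alternation)) {
    list(period = as.integer(x$alternation$period),
         alternate_sequence = as.character(unlist(x$alternation$alternate_sequence)))
  } else if (!is.null(x["alternation"]) && "alternation" %in% names(x)) NULL
  else if (!is.null(base)) base$alternation else NULL
  schedule <- if (!is.null(x$schedule)) {
    s <- x$schedule
    list(delivery_interval_s = if (is.null(s$delivery_interval_s)) NA_real_
                               else as.numeric(s$delivery_interval_s),
         n_deliveries = as.integer(s$n_deliveries %||% 0L),
         preloaded_pellets = as.integer(s$preloaded_pellets %||% 0L))
  } else if (!is.null(base)) base$schedule else NULL
  criteria <- if (!is.null(x$criteria)) {
    r <- x$criteria
    advancement_rule(
      type = r$type %||% "none",
      reward_target = r$reward_target %||% NA_real_,
      consecutive_days = r$consecutive_days %||% 1L,
      max_sessions = r$max_sessions %||% NA_integer_,
      last_session_min_trials = r$last_session_min_trials %||% NA_integer_,
      fixed_sessions = r$fixed_sessions %||% NA_integer_,
      force_advance = r$force_advance %||% FALSE
    )
  } else if (!is.null(base)) base$criteria
  else advancement_rule("none", fixed_sessions = 1L)
  stage_config(
    stage_id = x$stage_id,
    target_sequence = as.character(unlist(get_field("target_sequence", character(0)))),
    windows = windows,
    any_lever = get_field("any_lever", FALSE),
    timeout_s = get_field("timeout_s", 5),
    session_cap_min = get_field("session_cap_min", 60),
    reward_cap = get_field("reward_cap", 40),
    trial_cap = x$trial_cap %||% (if (!is.null(base)) base$trial_cap else NA_real_),
    reinforced = get_field("reinforced", TRUE),
    alternation = alternation,
    schedule = schedule,
    criteria = criteria
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a protocol document
#'
#' Parses a YAML protocol document (one stage per block under the top-level
#' `protocol` key) into an ordered list of validated stage configurations.
#' A block that gives only a built-in `stage_id` inherits that stage's
#' canonical defaults; any field present in the block overrides the default.
#'
#' @param path Path to a protocol file, or a YAML string.
#' @return Ordered list of `stage_config` objects.
#' @seealso [save_protocol()] for the inverse; the bundled canonical document
#'   is at `system.file("extdata", "protocol_full.yaml", package = "timedseq")`.
#' @export
load_protocol <- function(path) {
  doc <- if (length(path) == 1 && !grepl("\n", path) && file.exists(path)) {
    yaml::read_yaml(path)
  } else {
    yaml::yaml.load(paste(path, collapse = "\n"))
  }
  stages <- doc$protocol %||% doc
  if (!is.list(stages) || length(stages) == 0) {
    stop("protocol document contains no stage blocks", call. = FALSE)
  }
  lapply(stages, plain_to_cfg)
}

#' Write a protocol document
#'
#' Serializes a list of stage configurations to the flat YAML protocol
#' format. `load_protocol(save_protocol(cfgs, path))` reproduces the input.
#'
#' @param cfgs List of `stage_config` objects.
#' @param path Output file path; if `NULL`, the YAML text is returned.
#' @return `path` (or the YAML string), invisibly.
#' @export
save_protocol <- function(cfgs, path = NULL) {
  if (inherits(cfgs, "stage_config")) cfgs <- list(cfgs)
  doc <- list(protocol = lapply(cfgs, cfg_to_plain))
  txt <- yaml::as.yaml(doc, precision = 12)
  if (is.null(path)) return(invisible(txt))
  writeLines(txt, path)
  invisible(path)
}

# Short stable fingerprint of a configuration, recorded in log headers so a
# log can be checked against the configuration it claims to come from.
cfg_fingerprint <- function(cfg) {
  s <- yaml::as.yaml(cfg_to_plain(cfg), precision = 12)
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 1000000007
  sprintf("%08x", h)
}
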