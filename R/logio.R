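# Plain-text session log dialect.
#
# One session per row: all successive events as whitespace-separated decimal
# tokens "<ticks>.<code>", where the integer part counts 0.01 s clock ticks
# elapsed since the previous event and the fixed-width three-digit
# fractional part is the event code (see event_codes()). Four "#"-prefixed
# header lines (animal, stage, date, config fingerprint) precede each row.
# Summary files are flat "key: value" text with a fixed key order.

summary_from_events <- function(events) {
  cnt <- function(lbl) sum(events$label %in% lbl)
  cts <- c(
    correct_L = cnt("press_correct_L"), correct_R = cnt("press_correct_R"),
    incorrect_L = cnt("press_incorrect_L"), incorrect_R = cnt("press_incorrect_R"),
    too_fast_L = cnt("press_too_fast_L"), too_fast_R = cnt("press_too_fast_R"),
    too_slow_L = cnt("press_too_slow_L"), too_slow_R = cnt("press_too_slow_R"),
    timeout_L = cnt("press_timeout_L"), timeout_R = cnt("press_timeout_R")
  )
  completed <- cnt("trial_complete")
  error_presses <- sum(cts[c("incorrect_L", "incorrect_R", "too_fast_L", "too_fast_R",
                             "too_slow_L", "too_slow_R")])
  list(
    # manually preloaded pellets count as obtained rewards (habituation 2)
    rewards = cnt("reward") + cnt("manual_pellet"),
    completed_trials = completed,
    attempts = completed + error_presses,
    presses = as.list(as.integer(cts)) |> stats::setNames(names(cts)),
    total_presses = as.integer(sum(cts)),
    correct_presses = as.integer(sum(cts[c("correct_L", "correct_R")])),
    incorrect_presses = as.integer(error_presses),
    timeout_presses = as.integer(sum(cts[c("timeout_L", "timeout_R")])),
    end_s = if (nrow(events)) events$t[nrow(events)] else 0
  )
}

#' Write session logs in the decimal-encoded dialect
#'
#' Renders each session as four header lines followed by one row of
#' `<ticks>.<3-digit code>` tokens, where ticks count 0.01 s intervals since
#' the previous event. Output is byte-stable: identical logs serialize
#' identically.
#'
#' @param logs A `session_log` or list of them.
#' @param path Output file; if `NULL` the lines are returned invisibly.
#' @return The file path, or the character vector of lines when `path` is
#'   `NULL`, invisibly.
#' @export
#' @examples
#' log <- run_session(builtin_stage("LR"), press_stream(c(1, 2), c("L", "R")))
#' writeLines(write_log(log))
write_log <- function(logs, path = NULL) {
  if (inherits(logs, "session_log")) logs <- list(logs)
  out <- character(0)
  for (lg in logs) {
    ev <- lg$events
    if (nrow(ev) && !all(ev$code %in% .EVENT_CODES)) {
      bad <- unique(ev$code[!ev$code %in% .EVENT_CODES])
      stop("unregistered event code(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    h <- lg$header
    out <- c(out,
             paste0("# animal: ", h$animal_id),
             paste0("# stage: ", h$stage_id),
             paste0("# date: ", h$date),
             paste0("# fingerprint: ", h$fingerprint))
    if (nrow(ev) == 0) {
      out <- c(out, "")
    } else {
      ticks <- to_ticks(ev$t)
      dt <- diff(c(0L, ticks))
      out <- c(out, paste(sprintf("%d.%03d", dt, ev$code), collapse = " "))
    }
  }
  if (is.null(path)) return(invisible(out))
  writeLines(out, path)
  invisible(path)
}

parse_event_row <- function(row, row_no) {
  if (!nzchar(trimws(row))) {
    return(data.frame(t = numeric(0), code = integer(0), label = character(0),
                      stringsAsFactors = FALSE))
  }
  tokens <- strsplit(trimws(row), "[[:space:]]+")[[1]]
  m <- regmatches(tokens, regexec("^([0-9]+)\\.([0-9]{3})$", tokens))
  bad <- which(vapply(m, length, 1L) != 3L)
  if (length(bad)) {
    stop(sprintf("malformed log token '%s' at row %d, column %d",
                 tokens[bad[1]], row_no, bad[1]), call. = FALSE)
  }
  dt <- vapply(m, function(x) as.integer(x[2]), 1L)
  code <- vapply(m, function(x) as.integer(x[3]), 1L)
  data.frame(t = cumsum(dt) * TICK_S, code = code, label = code_label(code),
             stringsAsFactors = FALSE)
}

#' Read session logs from the decimal-encoded dialect
#'
#' Reconstructs absolute event times as prefix sums of the inter-event tick
#' counts. Events with codes absent from the registered table are kept (label
#' `"unknown"`) and reported in a single warning rather than dropped.
#'
#' @param source Path to a log file, or a character vector of its lines.
#' @return List of `session_log` objects; each carries a summary recomputed
#'   from its events.
#' @export
read_log <- function(source) {
  lines <- if (length(source) == 1 && file.exists(source)) readLines(source) else source
  logs <- list()
  header <- list()
  i <- 0L
  expect_row <- FALSE
  for (ln in lines) {
    i <- i + 1L
    if (grepl("^#", ln)) {
      kv <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
      if (length(kv) == 3) header[[trimws(kv[2])]] <- trimws(kv[3])
      expect_row <- TRUE
    } else if (expect_row) {
      events <- parse_event_row(ln, i)
      unknown <- unique(events$code[events$label == "unknown"])
      if (length(unknown)) {
        warning("unregistered event code(s) in log row ", i, ": ",
                paste(unknown, collapse = ", "), call. = FALSE)
      }
      logs[[length(logs) + 1L]] <- structure(list(
        header = list(
          animal_id = header[["animal"]] %||% NA_character_,
          stage_id = header[["stage"]] %||% NA_character_,
          date = header[["date"]] %||% NA_character_,
          fingerprint = header[["fingerprint"]] %||% NA_character_
        ),
        events = events,
        summary = summary_from_events(events)
      ), class = "session_log")
      header <- list()
      expect_row <- FALSE
    }
    # blank lines outside a session are ignored
  }
  logs
}

SUMMARY_KEY_ORDER <- c(
  "rewards", "completed_trials", "attempts", "total_presses",
  "correct_presses", "incorrect_presses", "timeout_presses",
  "presses_correct_L", "presses_correct_R",
  "presses_incorrect_L", "presses_incorrect_R",
  "presses_too_fast_L", "presses_too_fast_R",
  "presses_too_slow_L", "presses_too_slow_R",
  "presses_timeout_L", "presses_timeout_R",
  "end_s"
)

#' Write a session summary file
#'
#' Flat `key: value` text with a fixed key order, mirroring the per-session
#' summary file the acquisition software produces.
#'
#' @param summary A session summary (the `summary` element of a
#'   `session_log`, or the result of [summarize_session()]).
#' @param path Output file; if `NULL`, lines are returned invisibly.
#' @return The path or the lines, invisibly.
#' @export
write_summary <- function(summary, path = NULL) {
  flat <- c(
    summary[c("rewards", "completed_trials", "attempts", "total_presses",
              "correct_presses", "incorrect_presses", "timeout_presses")],
    stats::setNames(summary$presses, paste0("presses_", names(summary$presses))),
    summary["end_s"]
  )
  out <- vapply(SUMMARY_KEY_ORDER, function(k) {
    v <- flat[[k]]
    paste0(k, ": ", format(v %||% 0, scientific = FALSE, trim = TRUE))
  }, "")
  if (is.null(path)) return(invisible(out))
  writeLines(out, path)
  invisible(path)
}

#' Read a session summary file
#'
#' @param source Path or character vector of `key: value` lines.
#' @return Named list of numeric values.
#' @export
read_summary <- function(source) {
  lines <- if (length(source) == 1 && file.exists(source)) readLines(source) else source
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexec("^([^:]+):\\s*(.*)$", lines))
  out <- lapply(kv, function(x) as.numeric(x[3]))
  names(out) <- vapply(kv, function(x) trimws(x[2]), "")
  out
}
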