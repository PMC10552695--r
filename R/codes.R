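# Event code table of the log dialect. The dialect is package-defined: the
# original acquisition software's numeric assignments are not public, so this
# table is the normative one for logs written and read here. Codes are
# rendered as fixed-width three-digit fractional parts of the decimal tokens.

.EVENT_CODES <- c(
  session_start   = 1L,
  session_end     = 2L,
  press_correct_L = 11L,
  press_correct_R = 12L,
  press_incorrect_L = 21L,
  press_incorrect_R = 22L,
  press_too_fast_L  = 31L,
  press_too_fast_R  = 32L,
  press_too_slow_L  = 41L,
  press_too_slow_R  = 42L,
  press_timeout_L   = 51L,
  press_timeout_R   = 52L,
  reward          = 61L,
  manual_pellet   = 62L,
  trial_complete  = 63L,
  timeout_on      = 71L,
  timeout_off     = 72L,
  cue_on_L        = 81L,
  cue_on_R        = 82L,
  cue_off_L       = 83L,
  cue_off_R       = 84L
)

#' The event code table of the log dialect
#'
#' Every event the engine can emit has a registered integer code; the table
#' is closed and versioned with the package. Press codes encode both the
#' role the press played (correct, incorrect lever, too fast, too slow,
#' emitted during time-out) and the lever.
#'
#' @return A data frame with columns `code` and `label`.
#' @export
#' @examples
#' event_codes()
event_codes <- function() {
  data.frame(code = unname(.EVENT_CODES), label = names(.EVENT_CODES),
             stringsAsFactors = FALSE)
}

code_label <- function(codes) {
  lbl <- names(.EVENT_CODES)[match(codes, .EVENT_CODES)]
  lbl[is.na(lbl)] <- "unknown"
  lbl
}

# press-role helpers ---------------------------------------------------------

PRESS_CODES <- .EVENT_CODES[grep("^press_", names(.EVENT_CODES))]

press_code <- function(role, lever) {
  nm <- switch(role,
    correct = "press_correct_",
    incorrect_lever = "press_incorrect_",
    too_fast = "press_too_fast_",
    too_slow = "press_too_slow_",
    timeout_press = "press_timeout_",
    stop("unknown press role '", role, "'")
  )
  .EVENT_CODES[[paste0(nm, lever)]]
}

press_role_of_code <- function(code) {
  lbl <- code_label(code)
  role <- sub("^press_", "", sub("_[LR]$", "", lbl))
  c(correct = "correct", incorrect = "incorrect_lever", too_fast = "too_fast",
    too_slow = "too_slow", timeout = "timeout_press")[role]
}

press_lever_of_code <- function(code) {
  ifelse(code %% 10L == 1L, "L", "R")
}
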