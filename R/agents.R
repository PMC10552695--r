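# Synthetic mouse policies.
#
# Agents generate press streams for any stage so that every engine and
# analysis path can be exercised at desk scale. A policy is stationary
# within a stage: interpress timing on trained transitions is log-normal
# (positive support, right-skewed interresponse times), wrong-lever and
# out-of-window presses are injected with fixed probabilities, pressing
# during time-outs follows a Poisson rate, activity alternates bouts and
# pauses via a two-state renewal process with exponential dwell times, and
# responses to a contingency change mix the pre-change ("trained") policy
# with a window-adapted one via the perseveration probability.

#' Synthetic agent parameters
#'
#' @param interval_mu Per-transition log-normal `meanlog` (log seconds),
#'   recycled across transitions. `NA` entries derive the median from the
#'   trained window's midpoint (used by the `perfect` preset).
#' @param interval_sigma Per-transition log-normal `sdlog`; 0 gives
#'   deterministic timing.
#' @param lever_confusion_p Probability that a press lands on the wrong lever.
#' @param premature_p,late_p Probabilities of deliberately sampling an
#'   interval below / above the active window.
#' @param timeout_press_rate Presses per second emitted during time-outs.
#' @param bout_mean_s,pause_mean_s Mean dwell times (s) of the activity /
#'   inactivity states of the two-state renewal process; `Inf` bout mean
#'   disables pausing.
#' @param pause_p Probability that the session starts inside a pause.
#' @param perseveration After a contingency change, probability per trial of
#'   emitting the previously trained sequence and timing instead of the
#'   window-adapted policy.
#' @param structure_adapt_p Among adapted trials at a raised lower time
#'   bound, probability of bridging the wait by inserting an extra press of
#'   the preceding lever (a sequence-structure change; only applies where
#'   the transition crosses levers, as in the MIDDLE probe).
#' @return An object of class `agent_params`.
#' @export
agent_params <- function(interval_mu = log(1.3),
                         interval_sigma = 0.25,
                         lever_confusion_p = 0.05,
                         premature_p = 0.08,
                         late_p = 0.03,
                         timeout_press_rate = 0.8,
                         bout_mean_s = 180,
                         pause_mean_s = 90,
                         pause_p = 0.1,
                         perseveration = 0.2,
                         structure_adapt_p = 0.3) {
  p <- list(interval_mu = interval_mu, interval_sigma = interval_sigma,
            lever_confusion_p = lever_confusion_p, premature_p = premature_p,
            late_p = late_p, timeout_press_rate = timeout_press_rate,
            bout_mean_s = bout_mean_s, pause_mean_s = pause_mean_s,
            pause_p = pause_p, perseveration = perseveration,
            structure_adapt_p = structure_adapt_p)
  for (f in c("lever_confusion_p", "premature_p", "late_p", "pause_p",
              "perseveration", "structure_adapt_p")) {
    v <- p[[f]]
    if (any(v < 0 | v > 1)) stop("agent_params: ", f, " must lie in [0, 1]")
  }
  if (p$timeout_press_rate < 0) stop("agent_params: timeout_press_rate must be >= 0")
  if (any(p$interval_sigma < 0)) stop("agent_params: interval_sigma must be >= 0")
  if (p$bout_mean_s <= 0 || p$pause_mean_s < 0) {
    stop("agent_params: bout/pause means must be positive")
  }
  structure(p, class = "agent_params")
}

#' Agent presets
#'
#' Four canned policies. `control_like` and `vpa_like` differ only in
#' documented directions drawn from the phenotype the paradigm was validated
#' on: the VPA-like agent has longer interpress intervals (higher
#' `interval_mu` on every transition), a lower time-out pressing rate, and
#' higher perseveration after contingency changes. `perfect` makes no errors
#' and presses at window midpoints; `random` picks levers uniformly with
#' uninformative timing.
#'
#' @param name One of `"control_like"`, `"vpa_like"`, `"perfect"`, `"random"`.
#' @return An `agent_params` object.
#' @export
#' @examples
#' preset("vpa_like")$perseveration > preset("control_like")$perseveration
preset <- function(name = c("control_like", "vpa_like", "perfect", "random")) {
  name <- match.arg(name)
  switch(name,
    control_like = agent_params(),
    vpa_like = agent_params(
      interval_mu = log(1.6),
      timeout_press_rate = 0.3,
      perseveration = 0.5
    ),
    perfect = agent_params(
      interval_mu = NA_real_, interval_sigma = 0,
      lever_confusion_p = 0, premature_p = 0, late_p = 0,
      timeout_press_rate = 0, bout_mean_s = Inf, pause_mean_s = 0,
      pause_p = 0, perseveration = 0, structure_adapt_p = 0
    ),
    random = agent_params(
      interval_mu = log(1.0), interval_sigma = 1.0,
      lever_confusion_p = 0.5, premature_p = 0, late_p = 0,
      timeout_press_rate = 0.5, bout_mean_s = 300, pause_mean_s = 60,
      pause_p = 0.2, perseveration = 0, structure_adapt_p = 0
    )
  )
}

other_lever <- function(lv) if (lv == "L") "R" else "L"

# policy median for transition i: trained median, bumped into the current
# window when a raised lower bound would otherwise make it premature
policy_medians <- function(params, cfg, trained) {
  n <- length(cfg$windows)
  if (n == 0) return(list(base = numeric(0), adapted = numeric(0)))
  mu <- rep_len(params$interval_mu, n)
  tw <- trained$windows
  win_mid <- function(w) if (is_untimed(w)) max(2 * w[["low"]], 1) else
    (w[["low"]] + w[["high"]]) / 2
  base <- vapply(seq_len(n), function(i) {
    if (is.na(mu[i])) win_mid(tw[[min(i, length(tw))]]) else exp(mu[i])
  }, 0)
  adapted <- vapply(seq_len(n), function(i) {
    w <- cfg$windows[[i]]
    lo <- w[["low"]]; hi <- w[["high"]]
    # adaptation waits just past a raised lower bound, not to the window center
    if (base[i] < lo) lo + 0.15 * (min(hi, lo + 4) - lo)
    else if (base[i] > hi) (lo + hi) / 2
    else base[i]
  }, 0)
  list(base = base, adapted = adapted)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a press stream for one session
#'
#' Co-simulates the agent against the engine so the stream reacts to
#' contingencies the way a live animal's would: presses stop when the trial
#' errors out, time-out pressing happens during actual time-outs, and the
#' stream terminates with the session. The same `(params, cfg, seed)` always
#' yields the same stream.
#'
#' @param params An [agent_params()] policy.
#' @param cfg The stage to run (a press stage, not habituation).
#' @param seed Integer seed; the global RNG state is restored afterwards.
#' @param trained Optional `stage_config` describing the previously trained
#'   contingencies; enables perseveration and structural adaptation. Defaults
#'   to `cfg` itself (no contingency change).
#' @return A press stream data frame (`t`, `lever`) suitable for
#'   [run_session()].
#' @export
#' @examples
#' st <- generate_session(preset("perfect"), builtin_stage("LLRR_baseline"), seed = 1)
#' run_session(builtin_stage("LLRR_baseline"), st)$summary$rewards # 40
generate_session <- function(params, cfg, seed = NULL, trained = NULL) {
  if (length(cfg$target_sequence) == 0) {
    stop("cannot generate presses for habituation stage '", cfg$stage_id, "'",
         call. = FALSE)
  }
  with_seed(seed, {
    changed <- !is.null(trained)
    trained <- trained %||% cfg
    med <- policy_medians(params, cfg, trained)
    sig <- rep_len(params$interval_sigma, max(1L, length(cfg$windows)))
    cap_s <- cfg$session_cap_min * 60
    state <- new_session_state(cfg)
    t_vec <- numeric(0)
    l_vec <- character(0)
    emit <- function(t, lever) {
      if (state$ended || to_ticks(t) >= state$cap_tick) return(NULL)
      t_vec[[length(t_vec) + 1L]] <<- t
      l_vec[[length(l_vec) + 1L]] <<- lever
      res <- handle_press(state, cfg, list(t = t, lever = lever))
      state <<- res$state
      res$outcome
    }
    # transitions where the lower bound rose across a lever change: the only
    # place a bridging extra press alters sequence structure
    raised_cross <- if (changed && length(cfg$windows) == length(trained$windows)) {
      which(vapply(seq_along(cfg$windows), function(i) {
        cfg$windows[[i]][["low"]] > trained$windows[[i]][["low"]] + 1e-9 &&
          cfg$target_sequence[i] != cfg$target_sequence[i + 1]
      }, TRUE))
    } else integer(0)

    t <- round(stats::runif(1, 5, 30), 2)
    in_pause_start <- stats::runif(1) < params$pause_p
    bout_end <- if (!is.finite(params$bout_mean_s)) Inf else
      t + stats::rexp(1, 1 / params$bout_mean_s)
    if (in_pause_start && params$pause_mean_s > 0) {
      t <- t + stats::rexp(1, 1 / params$pause_mean_s)
    }

    while (!state$ended && t < cap_s) {
      if (t > bout_end && params$pause_mean_s > 0) {
        t <- t + stats::rexp(1, 1 / params$pause_mean_s)
        bout_end <- t + stats::rexp(1, 1 / params$bout_mean_s)
      }
      persev <- changed && stats::runif(1) < params$perseveration
      intended <- if (persev) trained$target_sequence else state$active_seq
      meds <- if (persev) med$base else med$adapted
      ins_at <- NA_integer_
      if (!persev && length(raised_cross) &&
          stats::runif(1) < params$structure_adapt_p) {
        ins_at <- raised_cross[1] + 1L # insert before this press
        intended <- append(intended, intended[ins_at - 1L], after = ins_at - 1L)
      }
      trial_over <- FALSE
      for (k in seq_along(intended)) {
        lever <- intended[k]
        if (stats::runif(1) < params$lever_confusion_p) lever <- other_lever(lever)
        if (k == 1L) {
          gap <- stats::runif(1, 3, 10) # approach and re-orient to the levers
        } else {
          ti <- min(k - 1L, length(cfg$windows))
          w <- cfg$windows[[ti]]
          u <- stats::runif(1)
          if (!is.na(ins_at) && k == ins_at) {
            # bridging press: quick, stereotyped, pre-change timing
            gap <- stats::rlnorm(1, log(med$base[ti]), sig[ti])
          } else if (u < params$premature_p) {
            gap <- max(TICK_S, w[["low"]] * stats::runif(1, 0.3, 0.9))
          } else if (u < params$premature_p + params$late_p) {
            gap <- w[["high"]] * stats::runif(1, 1.02, 1.4)
          } else {
            gap <- stats::rlnorm(1, log(meds[ti]), sig[ti])
          }
        }
        t <- t + max(TICK_S, round(gap, 2))
        if (t >= cap_s) { trial_over <- TRUE; break }
        out <- emit(round(t, 2), lever)
        if (is.null(out) || state$ended) { trial_over <- TRUE; break }
        if (out$role %in% c("incorrect_lever", "too_fast", "too_slow")) {
          if (params$timeout_press_rate > 0 && cfg$timeout_s > 0.2) {
            n_to <- stats::rpois(1, params$timeout_press_rate * cfg$timeout_s)
            if (n_to > 0) {
              tt <- sort(round(stats::runif(n_to, t + 0.05, t + cfg$timeout_s - 0.05), 2))
              for (x in tt) {
                if (is.null(emit(x, sample(c("L", "R"), 1, prob = c(0.7, 0.3))))) break
              }
            }
          }
          t <- t + cfg$timeout_s + stats::runif(1, 1, 4)
          trial_over <- TRUE
          break
        }
        if (out$trial_completed) {
          # a perseverative agent finishes its stereotyped sequence even when
          # the (shortened) trial already completed; the surplus press lands
          # on the next trial's contingency
          if (persev && k < length(intended)) next
          t <- t + stats::runif(1, 8, 18) # collect and eat the pellet
          trial_over <- TRUE
          break
        }
      }
      if (!trial_over) t <- t + stats::runif(1, 0.5, 2)
    }
    data.frame(t = round(to_ticks(t_vec)) * TICK_S, lever = l_vec,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a cohort through a protocol
#'
#' Runs `n_per_group` animals per preset through the given stage protocol,
#' deriving per-animal and per-session seeds deterministically from the
#' master seed. Between sessions the advancement rule is applied via
#' [check_criteria()], mirroring the study flow: animals repeat a stage until
#' they advance, and excluded animals run no further stages.
#'
#' @param presets Named list of `agent_params`, or a character vector of
#'   preset names.
#' @param n_per_group Animals per preset (the validation study used 11).
#' @param protocol Ordered list of `stage_config`s (default: the full
#'   built-in flow).
#' @param seed Master seed.
#' @param sessions_per_stage If set, run exactly this many sessions per stage
#'   instead of consulting the advancement rule (useful for probe-only
#'   designs).
#' @param trained Optional `stage_config` used as every animal's pre-change
#'   policy from the start; by default the trained policy becomes the
#'   baseline timed stage once the animal completes it.
#' @return A `cohort` object: list of animal records, each with `animal_id`,
#'   `group`, and per-stage lists of `session_log`s plus the advancement
#'   decision.
#' @export
simulate_cohort <- function(presets, n_per_group, protocol = builtin_protocol(),
                            seed = 1, sessions_per_stage = NULL, trained = NULL) {
  stopifnot(n_per_group >= 1)
  if (is.character(presets)) {
    presets <- stats::setNames(lapply(presets, preset), presets)
  }
  if (is.null(names(presets))) names(presets) <- paste0("group", seq_along(presets))
  n_total <- n_per_group * length(presets)
  animal_seeds <- with_seed(seed, sample.int(1000000L, n_total))
  animals <- list()
  idx <- 0L
  for (g in names(presets)) {
    for (a in seq_len(n_per_group)) {
      idx <- idx + 1L
      animals[[idx]] <- run_animal(
        params = presets[[g]],
        animal_id = sprintf("%s_%02d", g, a),
        group = g,
        protocol = protocol,
        base_seed = animal_seeds[idx],
        sessions_per_stage = sessions_per_stage,
        trained0 = trained
      )
    }
  }
  structure(list(animals = animals, n_per_group = n_per_group,
                 groups = names(presets), seed = seed), class = "cohort")
}

run_animal <- function(params, animal_id, group, protocol, base_seed,
                       sessions_per_stage = NULL, trained0 = NULL) {
  trained <- trained0
  stages <- list()
  sess_counter <- 0L
  excluded <- FALSE
  for (cfg in protocol) {
    if (excluded) break
    logs <- list()
    history <- list()
    decision <- "repeat"
    repeat {
      sess_counter <- sess_counter + 1L
      day <- sprintf("day%03d", sess_counter)
      if (length(cfg$target_sequence) == 0) {
        lg <- run_habituation(cfg, animal_id = animal_id, date = day)
      } else {
        st <- generate_session(params, cfg, seed = base_seed * 600L + sess_counter,
                               trained = trained)
        lg <- run_session(cfg, st, animal_id = animal_id, date = day)
      }
      logs[[length(logs) + 1L]] <- lg
      history[[length(history) + 1L]] <- lg$summary
      if (!is.null(sessions_per_stage)) {
        decision <- if (length(logs) >= sessions_per_stage) "advance" else "repeat"
      } else {
        decision <- check_criteria(history, cfg$criteria)
      }
      if (decision != "repeat") break
      if (length(logs) >= 30L) { decision <- "advance"; break } # safety stop
    }
    stages[[length(stages) + 1L]] <- list(stage_id = cfg$stage_id, logs = logs,
                                          decision = decision)
    if (decision == "exclude") excluded <- TRUE
    if (is.null(trained0) && cfg$stage_id == "LLRR_baseline" && decision == "advance") {
      trained <- cfg
    }
  }
  list(animal_id = animal_id, group = group, stages = stages, excluded = excluded)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d groups x %d animals (seed %s)\n",
              length(x$groups), x$n_per_group, format(x$seed)))
  invisible(x)
}
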