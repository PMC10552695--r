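base_cfg <- builtin_stage("LLRR_baseline")

test_that("trial categories follow the emitted prefix and failure mode", {
  # correct sequence -> LLRRP
  log <- run_session(base_cfg, press_stream(c(10, 11, 15, 16), c("L", "L", "R", "R")))
  tr <- classify_trials(log, base_cfg)
  expect_equal(tr$display, "LLRRP")
  expect_true(tr$rewarded)

  # sequence started with the wrong lever -> R
  log <- run_session(base_cfg, press_stream(10, "R"))
  expect_equal(classify_trials(log, base_cfg)$display, "R")

  # third press incorrect Left -> LLL
  log <- run_session(base_cfg, press_stream(c(10, 11, 12), c("L", "L", "L")))
  expect_equal(classify_trials(log, base_cfg)$display, "LLL")

  # second press too fast -> LL; too slow -> trailing macron
  log <- run_session(base_cfg, press_stream(c(10, 10.2), c("L", "L")))
  tr <- classify_trials(log, base_cfg)
  expect_equal(tr$category, "LL_fast2")
  expect_equal(tr$display, "LL")
  log <- run_session(base_cfg, press_stream(c(10, 16), c("L", "L")))
  tr <- classify_trials(log, base_cfg)
  expect_equal(tr$category, "LL_slow2")
  expect_equal(tr$display, "LL̄")

  # fourth press too slow -> LLRR with macron on the last press
  log <- run_session(base_cfg, press_stream(c(10, 11, 15, 21), c("L", "L", "R", "R")))
  expect_equal(classify_trials(log, base_cfg)$category, "LLRR_slow4")
})

test_that("time-out presses belong to no trial and later presses restart one", {
  # L, L-too-fast error, two time-out presses, then a full correct sequence
  st <- press_stream(c(10, 10.2, 11, 12, 20, 21, 25, 26),
                     c("L", "L", "L", "R", "L", "L", "R", "R"))
  log <- run_session(base_cfg, st)
  tr <- classify_trials(log, base_cfg)
  expect_equal(nrow(tr), 2)
  expect_equal(tr$display, c("LL", "LLRRP"))
  expect_equal(log$summary$timeout_presses, 2)
  s <- summarize_session(log, base_cfg)
  expect_equal(unname(s$category_counts[["LL"]]), 1)
  expect_equal(s$n_trials, 2)
})

test_that("summaries reproduce the engine's tallies on noisy sessions", {
  stages <- c("LLRR_baseline", "LLRR_strict", "LR", "LLRR_MIDDLE")
  for (seed in 1:4) {
    cfg <- builtin_stage(stages[seed])
    st <- generate_session(preset("control_like"), cfg, seed = seed)
    log <- run_session(cfg, st)
    s <- summarize_session(log, cfg)
    expect_equal(s$rewards, log$summary$rewards)
    expect_equal(s$completed_trials, log$summary$completed_trials)
    expect_equal(s$total_presses, log$summary$total_presses)
    expect_equal(s$timeout_presses, log$summary$timeout_presses)
    expect_equal(s$incorrect_presses, log$summary$incorrect_presses)
    expect_equal(s$n_trials, log$summary$attempts)
    # category partition: every trial in exactly one category
    expect_equal(sum(s$category_counts), s$n_trials)
    # conservation: total = correct + incorrect + time-out presses
    expect_equal(s$total_presses,
                 s$correct_presses + s$incorrect_presses + s$timeout_presses)
  }
})

test_that("interval statistics use only correct sequences and sample sd", {
  log <- run_session(base_cfg, scripted_perfect(base_cfg, 10))
  s <- summarize_session(log, base_cfg)
  expect_equal(s$interval_stats$n, rep(10L, 3))
  expect_equal(s$interval_stats$mean, c(2.75, 10.25, 2.75))
  expect_equal(s$interval_stats$cv, rep(0, 3), tolerance = 1e-10)

  # an errored trial contributes no intervals
  st <- rbind(press_stream(c(10, 10.2), c("L", "L")),
              press_stream(c(30, 31, 33, 34), c("L", "L", "R", "R")))
  s <- summarize_session(run_session(base_cfg, st), base_cfg)
  expect_equal(s$interval_stats$n, rep(1L, 3))
  expect_equal(s$interval_stats$mean, c(1, 2, 1))
})

test_that("cv is scale invariant and zero for constant intervals", {
  cfg <- builtin_stage("LLRR") # untimed windows admit scaled streams
  mk <- function(k) {
    ts <- c()
    gaps <- c(1, 2, 1.5) * k
    for (i in 0:4) {
      jitter <- 1 + 0.1 * i
      t0 <- 50 * i + 10
      ts <- c(ts, t0, t0 + cumsum(gaps * jitter))
    }
    press_stream(ts, c("L", "L", "R", "R"))
  }
  s1 <- summarize_session(run_session(cfg, mk(1)), cfg)
  s4 <- summarize_session(run_session(cfg, mk(4)), cfg)
  expect_equal(s1$interval_stats$cv, s4$interval_stats$cv, tolerance = 1e-6)
  expect_true(all(s1$interval_stats$cv > 0))
})

test_that("bout/pause detection partitions the active span", {
  log <- run_session(builtin_stage("LLRR"),
                     press_stream(c(0.1, 1, 2, 100, 101), c("L", "L", "R", "L", "L")))
  bp <- detect_bouts(log, gap_threshold_s = 30)
  expect_equal(bp$pause_durations, 98)
  expect_length(bp$bout_durations, 2)
  expect_equal(sum(bp$bout_durations) + sum(bp$pause_durations), 101 - 0.1)

  # uniform pressing: no pauses above threshold, a pause at every gap below it
  ulog <- run_session(builtin_stage("LLRR"), press_stream(1:20, "L"))
  expect_length(detect_bouts(ulog, 30)$pause_durations, 0)
  expect_length(detect_bouts(ulog, 0.5)$pause_durations, 19)

  # pause count never increases with the threshold
  nlog <- run_session(builtin_stage("LLRR_baseline"),
                      generate_session(preset("control_like"),
                                       builtin_stage("LLRR_baseline"), seed = 7))
  thresholds <- c(5, 15, 30, 60, 120)
  np <- vapply(thresholds, function(g) length(detect_bouts(nlog, g)$pause_durations), 1L)
  expect_true(all(diff(np) <= 0))
})

test_that("cumulative series are nondecreasing steps ending at the summary count", {
  log <- run_session(base_cfg, scripted_perfect(base_cfg, 60))
  cs <- cumulative_series(log, "rewards")
  expect_equal(cs$count, 0:40)
  expect_true(all(diff(cs$t) >= 0))

  empty <- run_session(base_cfg, press_stream(numeric(0), character(0)))
  expect_equal(cumulative_series(empty, "rewards")$count, 0)

  st <- generate_session(preset("control_like"), base_cfg, seed = 3)
  nlog <- run_session(base_cfg, st)
  s <- summarize_session(nlog, base_cfg)
  for (m in c("rewards", "incorrect_presses", "timeout_presses",
              "completed_trials", "correct_presses")) {
    cs <- cumulative_series(nlog, m)
    expect_equal(cs$count[nrow(cs)], s[[m]], label = m)
  }
  expect_error(cumulative_series(log, "sneezes"), "unknown metric")
})

test_that("advancement criteria implement the stage rules", {
  lr <- builtin_stage("LR")$criteria
  s40 <- list(rewards = 40, n_trials = 45)
  s30 <- list(rewards = 30, n_trials = 45)
  expect_equal(check_criteria(list(s40, s40), lr), "repeat")
  expect_equal(check_criteria(list(s30, s40, s40, s40), lr), "advance")
  expect_equal(check_criteria(list(s40, s40, s30), lr), "repeat")
  # not reaching criteria in 10 sessions excludes on pre-timed stages
  expect_equal(check_criteria(rep(list(s30), 10), lr), "exclude")

  timed <- builtin_stage("LLRR_strict")$criteria
  few <- list(rewards = 12, n_trials = 8)
  some <- list(rewards = 12, n_trials = 12)
  expect_equal(check_criteria(c(rep(list(s30), 9), list(few)), timed), "exclude")
  expect_equal(check_criteria(c(rep(list(s30), 9), list(some)), timed), "advance")
  expect_equal(check_criteria(rep(list(s30), 9), timed), "repeat")

  probe <- builtin_stage("LLRR_MIDDLE")$criteria
  expect_equal(check_criteria(list(s30), probe), "repeat")
  expect_equal(check_criteria(rep(list(s30), 3), probe), "advance")

  rebase <- builtin_stage("LLRR_rebaseline")$criteria
  expect_equal(check_criteria(list(s40), rebase), "advance")
  expect_equal(check_criteria(rep(list(s30), 3), rebase), "advance")
  expect_equal(check_criteria(c(rep(list(s30), 2), list(few)), rebase), "exclude")
})

test_that("the outlier rule is a single pass at mean +/- 2 sd", {
  r <- exclude_outliers(c(1, 1, 1, 1, 1, 200))
  expect_equal(r$excluded, 6L)
  expect_equal(r$kept, rep(1, 5))
  # with the sample sd a lone extreme value can still fall inside the band:
  # mean(c(1,1,1,1,100)) + 2 * sd = 109.35, so nothing is flagged
  expect_equal(exclude_outliers(c(1, 1, 1, 1, 100))$excluded, integer(0))
  expect_equal(exclude_outliers(rep(3, 6))$excluded, integer(0))
  v <- c(-2, -1, 0, 1, 2)
  expect_equal(exclude_outliers(v)$kept, v)
  expect_error(exclude_outliers(c(1, 2)), "at least 3")
})

test_that("probe measures count stage-specific flexibility errors", {
  # RIGHT probe: an R-R gap of 1.0 s is below the raised 1.5 s bound
  log <- probe_gap_session("LLRR_RIGHT", 3, 1.0)
  pm <- probe_measures(log, builtin_stage("LLRR_RIGHT"))
  expect_equal(pm$fourth_too_fast, 1)
  expect_equal(pm$fourth_too_slow, 0)

  # MIDDLE probe: an inserted third left press
  mid <- builtin_stage("LLRR_MIDDLE")
  log <- run_session(mid, press_stream(c(10, 11, 12), c("L", "L", "L")))
  pm <- probe_measures(log, mid)
  expect_equal(pm$third_incorrect_left, 1)
  log <- run_session(mid, press_stream(c(10, 11, 12.5), c("L", "L", "R")))
  expect_equal(probe_measures(log, mid)$third_too_fast, 1)

  # extinction: last-interval series defined for every completed trial
  ext <- builtin_stage("Extinction")
  elog <- run_session(ext, scripted_perfect(ext, 60))
  pm <- probe_measures(elog, ext)
  expect_equal(pm$completed_trials, 40)
  expect_length(pm$last_interval_s, 40)
  expect_equal(unique(pm$last_interval_s), 2.75)

  expect_error(probe_measures(elog, builtin_stage("LLRR_baseline")), "not a probe")
})

test_that("integrity errors name the divergence", {
  log <- run_session(base_cfg, press_stream(c(10, 11, 15, 16), c("L", "L", "R", "R")))
  # tamper: relabel the second press as incorrect
  log$events$code[log$events$label == "press_correct_L"][2] <- 21L
  log$events$label[log$events$label == "press_correct_L"][2] <- "press_incorrect_L"
  expect_error(classify_trials(log, base_cfg), "integrity")
})
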