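test_that("reaction-time classification respects the 100/1000 ms window", {
  expect_equal(classify_rt(99.999, TRUE), "anticipation")
  expect_equal(classify_rt(100, TRUE), "valid")
  expect_equal(classify_rt(1000, TRUE), "valid")
  expect_equal(classify_rt(1000.001, TRUE), "omission")
  expect_equal(classify_rt(99, TRUE), "anticipation")
  expect_equal(classify_rt(1001, TRUE), "omission")
  expect_equal(classify_rt(NA_real_, TRUE), "omission")
  expect_equal(classify_rt(350, FALSE), "false_alarm")
  expect_equal(classify_rt(NA_real_, FALSE), "correct_rejection")
})

test_that("ICV is the sample SD over the mean and is scale invariant", {
  expect_equal(icv(c(240, 250, 260)), 10 / 250)
  expect_equal(icv(c(5, 5, 5)), 0)
  v <- c(231, 255, 248, 301, 266)
  expect_equal(icv(v * 3.7), icv(v))
  expect_error(icv(250), "at least two")
})

test_that("reach-trial scoring applies the 0.028 m displacement correction", {
  cal <- default_cal()
  p0 <- cal$location_b
  p_touch <- p0 + c(0, 0, 0.5)
  sched <- manual_trial_row("center", 1L)
  ev <- rbind(
    ev_row(0, "stimulus_onset", "center", 1L),
    ev_row(0, "controller_sample", "center", 1L, p0),
    ev_row(300, "base_exit", "center", 1L, p0 + c(0, 0, 0.0281)),
    ev_row(500, "touch", "center", 1L, p_touch),
    ev_row(2000, "stimulus_offset", "center", 1L))
  rec <- score_log(manual_session(sched, ev, cal))
  expect_equal(rec$rt_ms, 300)
  expect_equal(rec$mt_ms, 200)
  expect_equal(rec$displacement_m, 0.472)
  expect_equal(rec$mv_mps, 0.472 / 0.2)
  expect_equal(rec$classification, "valid")
  expect_true(rec$touched)
  expect_false(rec$m_omission)
})

test_that("missing responses and no-go presses are classified from the log", {
  sched <- rbind(manual_trial_row("press_crt", 1L, color = "green", is_go = TRUE,
                                  display_ms = 260, location_index = NA),
                 manual_trial_row("press_crt", 2L, color = "blue", is_go = FALSE,
                                  display_ms = 260, location_index = NA))
  ev <- rbind(
    ev_row(0, "stimulus_onset", "press_crt", 1L),
    ev_row(260, "stimulus_offset", "press_crt", 1L),
    ev_row(2000, "stimulus_onset", "press_crt", 2L),
    ev_row(2350, "button_down", "press_crt", 2L),
    ev_row(2260, "stimulus_offset", "press_crt", 2L))
  rec <- score_log(manual_session(sched, ev))
  expect_equal(rec$classification, c("omission", "false_alarm"))
  expect_warning(s <- summarize_task(rec, "press_crt"), "no valid trials")
  expect_equal(s$omission_rate, 1)
  expect_equal(s$false_alarm_rate, 1)
})

test_that("movement times beyond 600 ms leave RT intact but drop MT/MV", {
  cal <- default_cal()
  p0 <- cal$location_b
  sched <- rbind(manual_trial_row("center", 1L), manual_trial_row("center", 2L))
  ev <- rbind(
    ev_row(0, "stimulus_onset", "center", 1L),
    ev_row(0, "controller_sample", "center", 1L, p0),
    ev_row(300, "base_exit", "center", 1L, p0),
    ev_row(901, "touch", "center", 1L, p0 + c(0, 0, 0.5)),  # mt = 601
    ev_row(2000, "stimulus_offset", "center", 1L),
    ev_row(5000, "stimulus_onset", "center", 2L),
    ev_row(5000, "controller_sample", "center", 2L, p0),
    ev_row(5250, "base_exit", "center", 2L, p0),
    ev_row(5450, "touch", "center", 2L, p0 + c(0, 0, 0.4)),
    ev_row(7000, "stimulus_offset", "center", 2L))
  rec <- score_log(manual_session(sched, ev, cal))
  expect_equal(rec$over_600, c(TRUE, FALSE))
  s <- summarize_task(rec, "center")
  expect_equal(s$over_600_rate, 0.5)
  expect_equal(s$n_valid_mt, 1)          # trial 1 excluded from MT/MV
  expect_equal(s$mt_median, 200)
  expect_equal(s$n_valid_rt, 2)          # but its RT still counts
  expect_equal(s$rt_median, 275)
})

test_that("a valid RT without a touch is a movement omission", {
  cal <- default_cal()
  sched <- manual_trial_row("spatial", 1L, location_index = 3L)
  ev <- rbind(
    ev_row(0, "stimulus_onset", "spatial", 1L),
    ev_row(0, "controller_sample", "spatial", 1L, cal$location_b),
    ev_row(350, "base_exit", "spatial", 1L, cal$location_b),
    ev_row(2000, "stimulus_offset", "spatial", 1L))
  rec <- score_log(manual_session(sched, ev, cal))
  expect_equal(rec$classification, "valid")
  expect_false(rec$touched)
  expect_true(rec$m_omission)
  expect_equal(summarize_task(rec, "spatial")$m_omission_rate, 1)
})

test_that("malformed logs are rejected with the offending trial named", {
  cal <- default_cal()
  sched <- manual_trial_row("center", 1L)
  ev <- rbind(
    ev_row(0, "stimulus_onset", "center", 1L),
    ev_row(500, "touch", "center", 1L, cal$location_b + c(0, 0, 0.5)),
    ev_row(2000, "stimulus_offset", "center", 1L))
  expect_error(score_log(manual_session(sched, ev, cal)),
               "touch without a base exit")
  sess <- manual_session(sched, ev_row(0, "stimulus_onset", "center", 1L), cal)
  sess$events <- rbind(ev_row(100, "stimulus_offset", "center", 1L),
                       ev_row(0, "stimulus_onset", "center", 1L))
  expect_error(score_log(sess), "out of time order")
})

test_that("go-trial classifications partition the go trials exactly", {
  cal <- default_cal(); g <- default_grid(cal)
  sch <- build_protocol(protocol_config(seed = 13), "both")
  p <- participant_params(lapse_p = 0.1, anticipation_p = 0.1,
                          false_alarm_p = 0.3, miss_touch_p = 0.1)
  rec <- score_log(simulate_session(p, sch, cal, g, seed = 91))
  rec <- rec[!rec$is_training & !rec$paused, ]
  for (task in unique(rec$task)) {
    go <- rec[rec$task == task & rec$is_go, ]
    counts <- table(factor(go$classification,
                           levels = c("valid", "anticipation", "omission")))
    expect_equal(sum(counts), nrow(go))
  }
  # stored MV always equals displacement / (MT in s)
  has_mv <- !is.na(rec$mv_mps)
  expect_equal(rec$mv_mps[has_mv],
               rec$displacement_m[has_mv] / (rec$mt_ms[has_mv] / 1000),
               tolerance = 1e-12)
})

test_that("task summaries agree with a naive brute-force oracle", {
  cal <- default_cal(); g <- default_grid(cal)
  for (seed in c(3, 17)) {
    sch <- build_protocol(protocol_config(seed = seed), "both")
    p <- participant_params(lapse_p = 0.08, anticipation_p = 0.08,
                            false_alarm_p = 0.2, miss_touch_p = 0.15)
    rec <- score_log(simulate_session(p, sch, cal, g, seed = seed + 100))
    for (task in unique(rec$task)) {
      s <- summarize_task(rec, task)
      o <- brute_force_summary(rec, task)
      for (field in names(o))
        expect_equal(s[[field]], o[[field]], tolerance = 1e-12,
                     label = paste(task, field))
    }
  }
})

test_that("RT-Diff is the componentwise CRT minus SRT subtraction", {
  d <- rt_diff(c(median = 360.91, mean = 369.55),
               c(median = 239.42, mean = 244.85))
  expect_equal(d$diff_median, 121.49)
  expect_equal(d$diff_mean, 124.70)
  same <- rt_diff(c(median = 300, mean = 310), c(median = 300, mean = 310))
  expect_equal(same$diff_median, 0)
  expect_equal(same$diff_mean, 0)
  # also accepts summary rows
  cal <- default_cal(); g <- default_grid(cal)
  sch <- build_protocol(protocol_config(seed = 4), "com")
  rec <- score_log(simulate_session(clean_params(), sch, cal, g, seed = 9))
  srt <- summarize_task(rec, "com_srt"); crt <- summarize_task(rec, "com_crt")
  d2 <- rt_diff(crt, srt)
  expect_equal(d2$diff_median, crt$rt_median - srt$rt_median)
})
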