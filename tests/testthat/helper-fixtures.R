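# Shared fixtures and independent oracles for the test suite.

default_cal <- function() calibrate(c(0, 1.2, 0), c(0, 1.2, 0.5))

default_grid <- function(cal = default_cal()) build_grid(cal)

# Brute-force grid oracle: each direction built by explicit rotation
# matrices, elevation about the lateral (x) axis then azimuth about the
# vertical (y) axis, applied to the forward unit vector.
rotation_grid_oracle <- function(cal, elevation_deg = 30, azimuth_deg = 35) {
  rot_x <- function(a) matrix(c(1, 0, 0,
                                0, cos(a), sin(a),
                                0, -sin(a), cos(a)), 3, 3)
  rot_y <- function(a) matrix(c(cos(a), 0, -sin(a),
                                0, 1, 0,
                                sin(a), 0, cos(a)), 3, 3)
  elevs <- c(30, 30, 30, 0, 0, 0, -30, -30, -30) / 30 * elevation_deg
  azims <- c(-35, 0, 35, -35, 0, 35, -35, 0, 35) / 35 * azimuth_deg
  t(vapply(1:9, function(i) {
    e <- elevs[i] * pi / 180
    a <- azims[i] * pi / 180
    dir <- rot_y(a) %*% rot_x(-e) %*% c(0, 0, 1)
    cal$location_b + cal$distance_d * as.numeric(dir)
  }, numeric(3)))
}

# Build a minimal hand-crafted reach session: one schedule data frame plus an
# explicit event table (columns t, kind, task, trial_index, x, y, z).
manual_session <- function(schedule, events, cal = default_cal()) {
  ev <- events[order(events$t), , drop = FALSE]
  rownames(ev) <- NULL
  sched_list <- split(schedule, schedule$task)
  structure(list(
    header = list(version = "1.0", participant = "manual",
                  calibration = list(location_b = cal$location_b,
                                     location_r = cal$location_r,
                                     distance_d = cal$distance_d),
                  seed = 0L, schedules = sched_list),
    events = ev), class = "rt_session")
}

manual_trial_row <- function(task, index, color = "green", is_go = TRUE,
                             display_ms = 2000, isi_ms = 3000,
                             location_index = 5L) {
  data.frame(task = task, index = index, is_training = FALSE, color = color,
             is_go = is_go, display_ms = display_ms, isi_ms = isi_ms,
             location_index = location_index, speed = NA_real_,
             origin_index = NA_integer_, target_index = NA_integer_,
             stringsAsFactors = FALSE)
}

ev_row <- function(t, kind, task, idx, p = c(NA_real_, NA_real_, NA_real_)) {
  data.frame(t = t, kind = kind, task = task, trial_index = idx,
             x = p[1], y = p[2], z = p[3], stringsAsFactors = FALSE)
}

# Naive re-computation of a task summary from per-trial records: explicit
# loops, no reuse of the summarize_task code path.
brute_force_summary <- function(records, task) {
  rs <- list()
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (r$task == task && !r$is_training && !r$paused) rs[[length(rs) + 1]] <- r
  }
  valid_rt <- c(); mt_vals <- c(); mv_vals <- c()
  n_go <- 0; n_nogo <- 0; n_ant <- 0; n_om <- 0; n_fa <- 0
  n_mom <- 0; n_over <- 0; n_all <- length(rs)
  for (r in rs) {
    if (r$is_go) {
      n_go <- n_go + 1
      if (r$classification == "anticipation") n_ant <- n_ant + 1
      if (r$classification == "omission") n_om <- n_om + 1
      if (r$classification == "valid") valid_rt <- c(valid_rt, r$rt_ms)
    } else {
      n_nogo <- n_nogo + 1
      if (r$classification == "false_alarm") n_fa <- n_fa + 1
    }
    if (isTRUE(r$m_omission)) n_mom <- n_mom + 1
    if (isTRUE(r$over_600)) n_over <- n_over + 1
    if (isTRUE(r$touched) && !is.na(r$mt_ms) && r$mt_ms <= 600) {
      mt_vals <- c(mt_vals, r$mt_ms)
      mv_vals <- c(mv_vals, r$mv_mps)
    }
  }
  naive_sd <- function(v) sqrt(sum((v - mean(v))^2) / (length(v) - 1))
  list(rt_median = if (length(valid_rt)) stats::median(valid_rt) else NA_real_,
       rt_mean = if (length(valid_rt)) mean(valid_rt) else NA_real_,
       rt_icv = if (length(valid_rt) > 1) naive_sd(valid_rt) / mean(valid_rt) else NA_real_,
       mt_median = if (length(mt_vals)) stats::median(mt_vals) else NA_real_,
       mt_mean = if (length(mt_vals)) mean(mt_vals) else NA_real_,
       mv_median = if (length(mv_vals)) stats::median(mv_vals) else NA_real_,
       anticipation_rate = if (n_go) n_ant / n_go else NA_real_,
       omission_rate = if (n_go) n_om / n_go else NA_real_,
       false_alarm_rate = if (n_nogo) n_fa / n_nogo else NA_real_,
       m_omission_rate = if (n_all) n_mom / n_all else NA_real_,
       over_600_rate = if (n_all) n_over / n_all else NA_real_,
       n_valid_rt = length(valid_rt))
}

# Fast participant with clean behavior (no error processes) for pipeline
# consistency checks.
clean_params <- function(...) {
  participant_params(lapse_p = 0, anticipation_p = 0, false_alarm_p = 0,
                     miss_touch_p = 0, ...)
}
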