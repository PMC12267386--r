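# Synthetic-participant event-log generator with controllable latent
# structure: ex-Gaussian response latencies per task family, an additive
# VR-vs-computer latency offset, a choice cost, minimum-jerk reach
# trajectories, and explicit error processes (anticipations, lapses, false
# alarms, failures to touch).

# --- ex-Gaussian latency family ------------------------------------------

#' Ex-Gaussian distribution helpers
#'
#' The ex-Gaussian (Gaussian + exponential convolution) is the standard
#' descriptive family for response latencies: `mu` and `sigma` describe the
#' Gaussian core, `tau` the exponential right tail. Mean is `mu + tau`.
#'
#' @param n Number of draws.
#' @param q Quantile, ms.
#' @param mu,sigma,tau Ex-Gaussian parameters, ms (`sigma`, `tau` > 0).
#' @return `rexgauss` returns draws; `pexgauss` the CDF; `exgauss_median` the
#'   distribution median (by root-finding on the closed-form CDF).
#' @export
rexgauss <- function(n, mu, sigma, tau) {
  stats::rnorm(n, mu, sigma) + stats::rexp(n, rate = 1 / tau)
}

#' @rdname rexgauss
#' @export
pexgauss <- function(q, mu, sigma, tau) {
  u <- (q - mu) / sigma
  stats::pnorm(u) - exp(sigma^2 / (2 * tau^2) - (q - mu) / tau) *
    stats::pnorm(u - sigma / tau)
}

#' @rdname rexgauss
#' @export
exgauss_median <- function(mu, sigma, tau) {
  lo <- mu - 6 * sigma
  hi <- mu + 6 * sigma + 12 * tau
  stats::uniroot(function(x) pexgauss(x, mu, sigma, tau) - 0.5,
                 c(lo, hi), tol = 1e-9)$root
}

# mu that puts the ex-Gaussian median at a target value
exgauss_mu_for_median <- function(target_median, sigma, tau) {
  target_median - exgauss_median(0, sigma, tau)
}

# --- participant parameters ----------------------------------------------

#' Parameters of a synthetic participant
#'
#' Latent structure of one simulated participant. Latencies for a trial are
#' `mu[family] + latent_speed + vr_bias (VR tasks) + choice_cost (CRT) +
#' Normal(0, sigma) + Exp(tau)`, resampled if non-positive. Default family
#' medians are calibrated to group-mean medians observed with the instrument
#' (button press 239.4 ms; Center/Spatial/Dynamic reaches 341.4/386.0/344.8 ms
#' including the VR offset), with `vr_bias` 32.44 ms and `choice_cost`
#' 121.49 ms. Reach durations (movement times) are lognormal around
#' task-specific medians (187.4/191.3/147.1 ms), scaled by `mt_scale`.
#'
#' @param latent_speed Participant-level latency offset shared across both
#'   tests, ms.
#' @param vr_bias Systematic latency added to every VR task, ms.
#' @param choice_cost Latency added in choice (CRT) phases, ms.
#' @param sigma,tau Gaussian SD and exponential tail of the latency family,
#'   ms (shared across families by default).
#' @param rt_medians Named target medians (ms) for the four task families
#'   `press`, `center`, `spatial`, `dynamic`, exclusive of `vr_bias` and
#'   `choice_cost`; the family `mu` is solved from these.
#' @param mt_medians Named lognormal medians (ms) of movement time for the
#'   reach tasks `center`, `spatial`, `dynamic`.
#' @param mt_sdlog Lognormal log-SD of movement time.
#' @param mt_scale Unitless multiplier on all reach durations.
#' @param lapse_p,anticipation_p,false_alarm_p,miss_touch_p Error-process
#'   probabilities: omitted response, anticipation (< 100 ms), response to a
#'   no-go stimulus, and failure to touch a reached-for stimulus.
#' @param touch_noise_sd Gaussian endpoint scatter of the touch point, m.
#' @param dynamic_aim_noise Per-(m/s) multiplier widening the endpoint
#'   scatter in the dynamic task; faster cubes are harder to intercept, which
#'   yields the dynamic task's higher miss rate without hard-coding it.
#' @param sample_rate Controller sampling rate, Hz.
#' @return A list of class `rt_participant`.
#' @export
participant_params <- function(latent_speed = 0, vr_bias = 32.44,
                               choice_cost = 121.49, sigma = 20, tau = 60,
                               rt_medians = c(press = 239.42,
                                              center = 341.38 - 32.44,
                                              spatial = 386.00 - 32.44,
                                              dynamic = 344.77 - 32.44),
                               mt_medians = c(center = 187.41,
                                              spatial = 191.30,
                                              dynamic = 147.06),
                               mt_sdlog = 0.30, mt_scale = 1,
                               lapse_p = 0.01, anticipation_p = 0.01,
                               false_alarm_p = 0.08, miss_touch_p = 0.01,
                               touch_noise_sd = 0.015, dynamic_aim_noise = 0.9,
                               sample_rate = 72) {
  stopifnot(sigma > 0, tau > 0, sample_rate > 0, mt_scale > 0)
  probs <- c(lapse_p, anticipation_p, false_alarm_p, miss_touch_p)
  if (any(probs < 0 | probs > 1))
    stop("error probabilities must lie in [0, 1]", call. = FALSE)
  mus <- vapply(rt_medians, exgauss_mu_for_median, 0, sigma = sigma, tau = tau)
  structure(list(latent_speed = latent_speed, vr_bias = vr_bias,
                 choice_cost = choice_cost, sigma = sigma, tau = tau,
                 mu = mus, rt_medians = rt_medians, mt_medians = mt_medians,
                 mt_sdlog = mt_sdlog, mt_scale = mt_scale,
                 lapse_p = lapse_p, anticipation_p = anticipation_p,
                 false_alarm_p = false_alarm_p, miss_touch_p = miss_touch_p,
                 touch_noise_sd = touch_noise_sd,
                 dynamic_aim_noise = dynamic_aim_noise,
                 sample_rate = sample_rate),
            class = "rt_participant")
}

task_family <- function(task) {
  switch(task,
         com_srt = , com_crt = , press_srt = , press_crt = "press",
         center = "center", spatial = "spatial", dynamic = "dynamic",
         stop("unknown task: ", task, call. = FALSE))
}

is_vr_task <- function(task) task != "com_srt" && task != "com_crt"
is_crt_task <- function(task) grepl("_crt$", task)
is_press_task <- function(task) grepl("^(com|press)_", task)

#' Draw a decision latency
#'
#' One ex-Gaussian latency draw for the given task, including the
#' participant's latent offset, the VR bias (VR tasks), and the choice cost
#' (CRT phases). Non-positive draws are resampled.
#'
#' @param params An `rt_participant`.
#' @param task Task name (`com_srt`, `com_crt`, `press_srt`, `press_crt`,
#'   `center`, `spatial`, `dynamic`).
#' @param is_go Whether the trial is a go trial (no-go draws use the same
#'   family; the caller decides whether a response is emitted at all).
#' @param n Number of draws.
#' @return Latencies in ms.
#' @export
sample_decision_time <- function(params, task, is_go = TRUE, n = 1) {
  fam <- task_family(task)
  shift <- params$mu[[fam]] + params$latent_speed +
    (if (is_vr_task(task)) params$vr_bias else 0) +
    (if (is_crt_task(task)) params$choice_cost else 0)
  draws <- shift + rexgauss(n, 0, params$sigma, params$tau)
  bad <- which(draws <= 0)
  while (length(bad)) {
    draws[bad] <- shift + rexgauss(length(bad), 0, params$sigma, params$tau)
    bad <- bad[draws[bad] <= 0]
  }
  draws
}

#' Minimum-jerk reach trajectory
#'
#' Samples a straight-line reach whose normalized path fraction follows the
#' minimum-jerk profile `10 s^3 - 15 s^4 + 6 s^5`, so velocity is zero at both
#' endpoints and the endpoint is exactly the target.
#'
#' @param start,target Length-3 positions, meters.
#' @param duration_ms Movement duration, ms (> 0).
#' @param sample_rate Sampling rate, Hz.
#' @return Data frame with columns `t_ms` (time since movement start), `x`,
#'   `y`, `z`. The final row is at `duration_ms` at the target.
#' @export
simulate_reach <- function(start, target, duration_ms, sample_rate = 72) {
  stopifnot(duration_ms > 0, sample_rate > 0)
  start <- as_vec3(start); target <- as_vec3(target)
  step <- 1000 / sample_rate
  t <- seq(0, duration_ms, by = step)
  if (t[length(t)] < duration_ms) t <- c(t, duration_ms)
  s <- t / duration_ms
  frac <- 10 * s^3 - 15 * s^4 + 6 * s^5
  data.frame(t_ms = t,
             x = start[1] + (target[1] - start[1]) * frac,
             y = start[2] + (target[2] - start[2]) * frac,
             z = start[3] + (target[3] - start[3]) * frac)
}

# uniform draw inside a sphere (rejection-free via radius transform)
runif_sphere <- function(center, radius) {
  u <- stats::rnorm(3)
  u <- u / sqrt(sum(u^2))
  center + radius * stats::runif(1)^(1 / 3) * u
}

event_row <- function(t, kind, task, trial_index, p = c(NA_real_, NA_real_, NA_real_)) {
  list(t = t, kind = kind, task = task, trial_index = trial_index,
       x = p[1], y = p[2], z = p[3])
}

short_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# --- session simulation --------------------------------------------------

#' Simulate a full session event log
#'
#' Plays the given schedules against a synthetic participant and emits the
#' time-stamped event stream a real session would record: stimulus
#' onsets/offsets, button presses (press tasks), and controller samples,
#' base exits and touches (reach tasks). Error processes: with probability
#' `anticipation_p` a trial gets a response under 100 ms; with `lapse_p` no
#' response; no-go CRT trials are responded to with probability
#' `false_alarm_p`; reach trials fail to touch with probability
#' `miss_touch_p`, when the endpoint scatter leaves the touch volume
#' (dynamic task), or when the planned touch would land after stimulus
#' offset. Dynamic-task touches aim at the cube's linearly predicted position
#' at the planned arrival time.
#'
#' @param params An `rt_participant`.
#' @param schedules Named list of `rt_schedule` objects (from
#'   [build_protocol()] or the individual builders).
#' @param cal An `rt_calibration`.
#' @param grid An `rt_grid` built from `cal`.
#' @param seed Integer seed; identical seeds give identical logs.
#' @param participant Participant identifier stored in the header.
#' @return An `rt_session`: list with `header` (version, participant,
#'   calibration, grid angles, schedules, seed, params and a params hash) and
#'   `events` (data frame `t`, `kind`, `task`, `trial_index`, `x`, `y`, `z`,
#'   time-ordered, ms from session start).
#' @export
simulate_session <- function(params, schedules, cal, grid, seed = 1L,
                             participant = "sim") {
  stopifnot(inherits(params, "rt_participant"),
            inherits(cal, "rt_calibration"), inherits(grid, "rt_grid"))
  if (vnorm(grid$calibration$location_b - cal$location_b) > 1e-9 ||
      abs(grid$calibration$distance_d - cal$distance_d) > 1e-9)
    stop("grid was built from a different calibration", call. = FALSE)
  if (!length(schedules)) stop("no schedules supplied", call. = FALSE)
  if (inherits(schedules, "rt_schedule")) schedules <- list(schedules)
  events <- vector("list", 4096L); n_ev <- 0L
  push <- function(e) {
    n_ev <<- n_ev + 1L
    if (n_ev > length(events)) length(events) <<- 2L * n_ev
    events[[n_ev]] <<- e
  }
  withr::with_seed(as.integer(seed), {
    clock <- 0
    for (sched in schedules) {
      task <- schedule_task(sched)
      for (i in seq_len(nrow(sched))) {
        tr <- sched[i, ]
        onset <- clock + tr$isi_ms
        offset <- onset + tr$display_ms
        push(event_row(onset, "stimulus_onset", task, tr$index))
        if (is_press_task(task)) {
          respond <- if (tr$is_go) stats::runif(1) >= params$lapse_p
                     else stats::runif(1) < params$false_alarm_p
          if (respond) {
            rt <- if (tr$is_go && stats::runif(1) < params$anticipation_p)
              stats::runif(1, 10, 95) else sample_decision_time(params, task)
            push(event_row(onset + rt, "button_down", task, tr$index))
          }
        } else {
          p_onset <- runif_sphere(cal$location_b, 0.5 * 0.028)
          push(event_row(onset, "controller_sample", task, tr$index, p_onset))
          if (stats::runif(1) >= params$lapse_p) {
            rt <- if (stats::runif(1) < params$anticipation_p)
              stats::runif(1, 10, 95) else sample_decision_time(params, task)
            mt <- params$mt_scale *
              stats::rlnorm(1, log(params$mt_medians[[task_family(task)]]),
                            params$mt_sdlog)
            loc_idx <- tr$location_index
            if (task == "dynamic") {
              motion <- motion_spec(tr$origin_index, tr$target_index, tr$speed)
              cube_at_touch <- cube_position_at(grid, motion, (rt + mt) / 1000)
            } else {
              cube_at_touch <- grid$locations[loc_idx, ]
            }
            cube <- cube_stimulus(cube_at_touch, color = tr$color)
            inward <- cube_at_touch - cal$location_b
            w <- inward / vnorm(inward)
            lat <- c(w[3], 0, -w[1])
            lat <- if (vnorm(lat) > 1e-9) lat / vnorm(lat) else c(1, 0, 0)
            vert <- c(w[2] * lat[3] - w[3] * lat[2],
                      w[3] * lat[1] - w[1] * lat[3],
                      w[1] * lat[2] - w[2] * lat[1])
            # aim half an edge into the cube; endpoint scatter widens with
            # cube speed in the dynamic task, which is what drives its higher
            # miss rate
            sd_eff <- params$touch_noise_sd *
              (1 + if (task == "dynamic") params$dynamic_aim_noise * tr$speed else 0)
            aim <- cube_at_touch + (cube$edge / 2) * w +
              stats::rnorm(1, 0, sd_eff) * lat +
              stats::rnorm(1, 0, sd_eff) * vert +
              stats::rnorm(1, 0, 0.01) * w
            hits <- cube_contains(aim, cube, inward) &&
              (onset + rt + mt) <= offset &&
              stats::runif(1) >= params$miss_touch_p
            exit_dir <- (aim - cal$location_b)
            exit_dir <- exit_dir / vnorm(exit_dir)
            p_exit <- cal$location_b + 1.0000001 * 0.028 * exit_dir
            push(event_row(onset + rt, "base_exit", task, tr$index, p_exit))
            path <- simulate_reach(p_exit, aim, mt, params$sample_rate)
            for (k in seq_len(nrow(path))[-1]) {
              push(event_row(onset + rt + path$t_ms[k], "controller_sample",
                             task, tr$index,
                             c(path$x[k], path$y[k], path$z[k])))
            }
            if (hits)
              push(event_row(onset + rt + mt, "touch", task, tr$index, aim))
          }
        }
        push(event_row(offset, "stimulus_offset", task, tr$index))
        clock <- offset
      }
    }
  })
  lst <- events[seq_len(n_ev)]
  ev <- data.frame(t = vapply(lst, `[[`, 0, "t"),
                   kind = vapply(lst, `[[`, "", "kind"),
                   task = vapply(lst, `[[`, "", "task"),
                   trial_index = vapply(lst, function(e) as.integer(e$trial_index), 0L),
                   x = vapply(lst, `[[`, 0, "x"),
                   y = vapply(lst, `[[`, 0, "y"),
                   z = vapply(lst, `[[`, 0, "z"),
                   stringsAsFactors = FALSE)
  ev <- ev[order(ev$t, method = "radix"), , drop = FALSE]
  rownames(ev) <- NULL
  header <- list(version = "1.0", participant = participant,
                 calibration = list(location_b = cal$location_b,
                                    location_r = cal$location_r,
                                    distance_d = cal$distance_d),
                 grid = list(elevation_deg = grid$elevation_deg,
                             azimuth_deg = grid$azimuth_deg),
                 seed = as.integer(seed),
                 params = unclass(params),
                 params_hash = short_hash(unclass(params)),
                 schedules = lapply(schedules, as.data.frame))
  names(header$schedules) <- vapply(schedules, schedule_task, "")
  structure(list(header = header, events = ev), class = "rt_session")
}

#' @export
print.rt_session <- function(x, ...) {
  cat(sprintf("Session '%s': %d events over %d tasks (%.1f s, seed %d)\n",
              x$header$participant, nrow(x$events),
              length(x$header$schedules),
              max(x$events$t) / 1000, x$header$seed))
  invisible(x)
}

#' Simulate a cohort of paired computer + VR sessions
#'
#' Draws `n` participants with latent speeds `Normal(0, s_between)` and
#' simulates both tests for each, recording the ground-truth parameters so
#' downstream agreement statistics can be checked against known values.
#'
#' @param n Number of participants (>= 2).
#' @param s_between Between-participant SD of the latent speed, ms.
#' @param vr_bias Systematic VR latency offset injected into every
#'   participant, ms.
#' @param cfg An `rt_protocol_config`; per-participant schedule seeds are
#'   derived from `seed`.
#' @param seed Integer master seed.
#' @param tasks Optional character vector of schedule names to simulate
#'   (subset of `com_srt`, `com_crt`, `press_srt`, `press_crt`, `center`,
#'   `spatial`, `dynamic`); `NULL` simulates all seven.
#' @param ... Further arguments passed to [participant_params()] (shared by
#'   all participants).
#' @return List with `sessions` (per participant: `id`, `com` and `vr`
#'   `rt_session`s, `params`) and `manifest` (data frame of ground-truth
#'   parameters per participant).
#' @export
simulate_cohort <- function(n, s_between = 18, vr_bias = 32.44,
                            cfg = protocol_config(), seed = 1L,
                            tasks = NULL, ...) {
  stopifnot(n >= 2)
  seed <- as.integer(seed)
  out <- vector("list", n)
  withr::with_seed(seed, {
    latents <- stats::rnorm(n, 0, s_between)
    arm_d <- stats::runif(n, 0.45, 0.62)
    sub_seeds <- sample.int(2147480000L, n)
  })
  for (i in seq_len(n)) {
    params <- participant_params(latent_speed = latents[i], vr_bias = vr_bias, ...)
    cal <- calibrate(c(0, 1.2, 0), c(0, 1.2, arm_d[i]))
    grid <- build_grid(cal)
    pcfg <- cfg
    pcfg$seed <- (cfg$seed + 37L * i) %% 2147480000L
    scheds <- build_protocol(pcfg, "both")
    if (!is.null(tasks)) scheds <- scheds[intersect(names(scheds), tasks)]
    com_names <- intersect(names(scheds), c("com_srt", "com_crt"))
    vr_names <- setdiff(names(scheds), com_names)
    id <- sprintf("p%03d", i)
    com <- if (length(com_names))
      simulate_session(params, scheds[com_names], cal, grid,
                       seed = sub_seeds[i], participant = id)
    vr <- if (length(vr_names))
      simulate_session(params, scheds[vr_names], cal, grid,
                       seed = (sub_seeds[i] + 1L) %% 2147480000L,
                       participant = id)
    out[[i]] <- list(id = id, com = com, vr = vr, params = params)
  }
  manifest <- data.frame(id = vapply(out, `[[`, "", "id"),
                         latent_speed = latents, vr_bias = vr_bias,
                         s_between = s_between, arm_d = arm_d,
                         stringsAsFactors = FALSE)
  list(sessions = out, manifest = manifest)
}
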