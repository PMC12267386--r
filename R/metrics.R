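# Scoring of session event logs into per-trial records and per-task
# summaries, implementing the instrument's validity cutoffs:
#   RT valid in [100, 1000] ms (below: anticipation; above or absent:
#   omission on go trials); movement times above 600 ms excluded from MT/MV
#   central values; movement displacement corrected by the 0.028 m base
#   radius.

RT_MIN_MS <- 100
RT_MAX_MS <- 1000
MT_CUTOFF_MS <- 600
BASE_RADIUS_M <- 0.028

#' Classify a reaction time
#'
#' Applies the validity window. On go trials: below 100 ms the response is an
#' anticipation (a guess); above 1000 ms, or absent, an omission; otherwise
#' valid. Both endpoints are inclusive for validity. On no-go trials any
#' response is a false alarm and no response a correct rejection.
#'
#' @param rt_ms Reaction time in ms, or `NA` for no response.
#' @param is_go Whether the trial required a response.
#' @return One of `"valid"`, `"anticipation"`, `"omission"`, `"false_alarm"`,
#'   `"correct_rejection"`.
#' @export
classify_rt <- function(rt_ms, is_go = TRUE) {
  if (!is_go) return(if (is.na(rt_ms)) "correct_rejection" else "false_alarm")
  if (is.na(rt_ms)) return("omission")
  if (rt_ms < RT_MIN_MS) return("anticipation")
  if (rt_ms > RT_MAX_MS) return("omission")
  "valid"
}

#' Intra-individual coefficient of variation
#'
#' Within-participant variability of a measure: sample standard deviation
#' (n - 1 denominator) divided by the mean.
#'
#' @param values Numeric vector, at least two values, nonzero mean.
#' @return The ICV (unitless ratio).
#' @examples
#' icv(c(240, 250, 260))  # 0.04
#' @export
icv <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2)
    stop("ICV needs at least two values", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("ICV undefined for zero mean", call. = FALSE)
  stats::sd(values) / m
}

#' Score a session event log into per-trial records
#'
#' Walks every scheduled trial and extracts its metrics from the event
#' stream. In press tasks RT is the first button press after stimulus onset.
#' In reach tasks RT is the moment the controller left the base sphere;
#' movement time (MT) runs from base exit to touch; movement displacement is
#' the Euclidean gap between the controller position at stimulus onset and at
#' touch minus the 0.028 m base radius (movement is only measured once the
#' controller has left the base sphere); movement velocity MV is
#' displacement / MT. Trials where the controller left the base before onset
#' are flagged `paused` and excluded from summary denominators.
#'
#' @param session An `rt_session` (from [simulate_session()] or
#'   [read_session()]).
#' @return Data frame, one row per scheduled trial (training included,
#'   flagged): `task`, `index`, `is_training`, `color`, `is_go`,
#'   `location_index`, `rt_ms`, `classification`, `mt_ms`, `displacement_m`,
#'   `mv_mps`, `touched`, `over_600`, `m_omission`, `paused`.
#' @export
score_log <- function(session) {
  stopifnot(inherits(session, "rt_session") || is.list(session))
  ev <- session$events
  if (nrow(ev) && is.unsorted(ev$t))
    stop("malformed log: events out of time order", call. = FALSE)
  key <- paste(ev$kind, ev$task, ev$trial_index, sep = "\r")
  recs <- vector("list", sum(vapply(session$header$schedules, nrow, 0L)))
  n <- 0L
  for (sched_name in names(session$header$schedules)) {
    sched <- session$header$schedules[[sched_name]]
    task <- if (!is.null(sched$task[1])) sched$task[1] else sched_name
    for (i in seq_len(nrow(sched))) {
      tr <- sched[i, ]
      sel <- ev$task == task & ev$trial_index == tr$index
      te <- ev[sel, , drop = FALSE]
      onset_i <- which(te$kind == "stimulus_onset")
      if (!length(onset_i))
        stop(sprintf("malformed log: trial %s/%d has no stimulus onset",
                     task, tr$index), call. = FALSE)
      onset <- te$t[onset_i[1]]
      rec <- list(task = task, index = tr$index,
                  is_training = isTRUE(tr$is_training), color = tr$color,
                  is_go = isTRUE(tr$is_go),
                  location_index = if (is.null(tr$location_index)) NA_integer_ else tr$location_index,
                  rt_ms = NA_real_, classification = NA_character_,
                  mt_ms = NA_real_, displacement_m = NA_real_,
                  mv_mps = NA_real_, touched = NA, over_600 = NA,
                  m_omission = NA, paused = FALSE)
      if (is_press_task(task)) {
        presses <- te$t[te$kind == "button_down" & te$t >= onset]
        if (length(presses)) rec$rt_ms <- presses[1] - onset
        rec$classification <- classify_rt(rec$rt_ms, rec$is_go)
      } else {
        exits <- which(te$kind == "base_exit")
        touches <- which(te$kind == "touch")
        if (length(touches) && !length(exits))
          stop(sprintf("malformed log: trial %s/%d has a touch without a base exit",
                       task, tr$index), call. = FALSE)
        if (length(exits) && te$t[exits[1]] < onset) {
          rec$paused <- TRUE
          exits <- exits[te$t[exits] >= onset]
        }
        if (length(exits)) rec$rt_ms <- te$t[exits[1]] - onset
        rec$classification <- classify_rt(rec$rt_ms, is_go = TRUE)
        rec$touched <- length(touches) > 0
        if (rec$touched) {
          t_exit <- te$t[exits[1]]
          t_touch <- te$t[touches[1]]
          if (t_touch < t_exit)
            stop(sprintf("malformed log: trial %s/%d touch precedes base exit",
                         task, tr$index), call. = FALSE)
          rec$mt_ms <- t_touch - t_exit
          samp <- which(te$kind == "controller_sample" & te$t <= onset)
          if (length(samp)) {
            p_onset <- c(te$x[samp[length(samp)]], te$y[samp[length(samp)]],
                         te$z[samp[length(samp)]])
            p_touch <- c(te$x[touches[1]], te$y[touches[1]], te$z[touches[1]])
            rec$displacement_m <- vnorm(p_touch - p_onset) - BASE_RADIUS_M
            rec$mv_mps <- rec$displacement_m / (rec$mt_ms / 1000)
          }
          rec$over_600 <- rec$mt_ms > MT_CUTOFF_MS
        } else {
          rec$over_600 <- FALSE
        }
        rec$m_omission <- rec$classification == "valid" && !rec$touched
      }
      n <- n + 1L
      recs[[n]] <- rec
    }
  }
  if (n == 0L)
    return(data.frame(task = character(), index = integer(),
                      is_training = logical(), color = character(),
                      is_go = logical(), location_index = integer(),
                      rt_ms = numeric(), classification = character(),
                      mt_ms = numeric(), displacement_m = numeric(),
                      mv_mps = numeric(), touched = logical(),
                      over_600 = logical(), m_omission = logical(),
                      paused = logical(), stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(recs[seq_len(n)], function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

summary_stats <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 1)
    return(list(median = NA_real_, mean = NA_real_, icv = NA_real_, n = 0L))
  list(median = stats::median(values), mean = mean(values),
       icv = if (length(values) >= 2) icv(values) else NA_real_,
       n = length(values))
}

#' Summarize scored trials of one task
#'
#' Central tendency, variability and error rates for one task, computed as
#' the instrument defines them: RT summaries over valid RTs only; MT and MV
#' summaries over touched trials with MT at or below 600 ms; the over-600 and
#' M-omission rates over all (non-paused) test trials; anticipation and
#' omission rates over go trials; the false-alarm rate over no-go trials.
#' Training and paused trials are excluded throughout (paused trials are
#' counted in `n_paused`).
#'
#' @param records Data frame from [score_log()].
#' @param task Task name to summarize; defaults to the single task present.
#' @return One-row data frame: `task`, `n_test`, `n_paused`,
#'   `rt_median`, `rt_mean`, `rt_icv`, `n_valid_rt`, `mt_median`, `mt_mean`,
#'   `mt_icv`, `mv_median`, `mv_mean`, `mv_icv`, `n_valid_mt`,
#'   `anticipation_rate`, `omission_rate`, `false_alarm_rate`,
#'   `m_omission_rate`, `over_600_rate`, `flag_no_valid`.
#' @export
summarize_task <- function(records, task = NULL) {
  if (is.null(task)) {
    task <- unique(records$task)
    if (length(task) != 1)
      stop("records span several tasks; name one", call. = FALSE)
  }
  r <- records[records$task == task & !records$is_training, , drop = FALSE]
  n_paused <- sum(r$paused)
  r <- r[!r$paused, , drop = FALSE]
  n_test <- nrow(r)
  go <- r[r$is_go, , drop = FALSE]
  nogo <- r[!r$is_go, , drop = FALSE]
  rt <- summary_stats(r$rt_ms[r$classification == "valid"])
  mt_ok <- !is.na(r$mt_ms) & r$mt_ms <= MT_CUTOFF_MS & !is.na(r$touched) & r$touched
  mt <- summary_stats(r$mt_ms[mt_ok])
  mv <- summary_stats(r$mv_mps[mt_ok])
  if (rt$n == 0 && n_test > 0)
    warning(sprintf("task '%s' has no valid trials", task), call. = FALSE)
  data.frame(task = task, n_test = n_test, n_paused = n_paused,
             rt_median = rt$median, rt_mean = rt$mean, rt_icv = rt$icv,
             n_valid_rt = rt$n,
             mt_median = mt$median, mt_mean = mt$mean, mt_icv = mt$icv,
             mv_median = mv$median, mv_mean = mv$mean, mv_icv = mv$icv,
             n_valid_mt = mt$n,
             anticipation_rate = if (nrow(go)) mean(go$classification == "anticipation") else NA_real_,
             omission_rate = if (nrow(go)) mean(go$classification == "omission") else NA_real_,
             false_alarm_rate = if (nrow(nogo)) mean(nogo$classification == "false_alarm") else NA_real_,
             m_omission_rate = if (n_test) mean(r$m_omission %in% TRUE) else NA_real_,
             over_600_rate = if (n_test) mean(r$over_600 %in% TRUE) else NA_real_,
             flag_no_valid = rt$n == 0,
             stringsAsFactors = FALSE)
}

#' Summarize every task of a scored session
#'
#' @param records Data frame from [score_log()].
#' @return Data frame with one [summarize_task()] row per task, in the order
#'   the tasks appear.
#' @export
summarize_session <- function(records) {
  out <- do.call(rbind, lapply(unique(records$task), summarize_task,
                               records = records))
  rownames(out) <- NULL
  out
}

#' Choice-minus-simple reaction-time difference
#'
#' RT-Diff indexes the added cost of the choice/inhibition component: the CRT
#' summary minus the SRT summary, computed separately for the median-based
#' and mean-based values.
#'
#' @param crt,srt Either one-row summaries from [summarize_task()] (their
#'   `rt_median` / `rt_mean` columns are used) or numeric vectors
#'   `c(median = , mean = )`.
#' @return List with `diff_median` and `diff_mean`, ms.
#' @examples
#' rt_diff(c(median = 360.91, mean = 369.55), c(median = 239.42, mean = 244.85))
#' @export
rt_diff <- function(crt, srt) {
  pick <- function(x) {
    if (is.data.frame(x)) c(median = x$rt_median[1], mean = x$rt_mean[1])
    else if (!is.null(names(x))) c(median = unname(x["median"]), mean = unname(x["mean"]))
    else c(median = x[1], mean = if (length(x) > 1) x[2] else x[1])
  }
  a <- pick(crt); b <- pick(srt)
  list(diff_median = unname(a["median"] - b["median"]),
       diff_mean = unname(a["mean"] - b["mean"]))
}
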