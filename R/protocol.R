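# Randomized trial schedules for the computerized phases (SRT, CRT) and the
# four virtual-reality tasks (Press, Center, Spatial, Dynamic).

RT_COLORS <- c("yellow", "green", "blue", "red")
CRT_GO_COLORS <- c("green", "yellow")     # no-go: blue, red

#' Protocol configuration
#'
#' Bundles every tunable constant of the two-test protocol. The defaults are
#' the instrument's published constants: 260 ms stimulus display with
#' 1000-2000 ms inter-stimulus intervals (ISI) in the button-press phases,
#' 2000 ms display with 3000-4500 ms ISIs in the reach tasks, 20 test trials
#' per stimulus category in the SRT/CRT phases, 20/18/27 test trials in the
#' Center/Spatial/Dynamic tasks, and staged dynamic-cube speeds of
#' 0.6, 0.75 and 0.9 m/s.
#'
#' @param trials_per_type Test trials per stimulus category (go, and no-go in
#'   CRT) in the SRT/CRT phases. Interpreted per category by default; set
#'   `per_color = TRUE` to read it as trials per color (so an SRT phase has
#'   `4 * trials_per_type` test trials).
#' @param per_color Whether `trials_per_type` counts per color rather than per
#'   go/no-go category.
#' @param training_phase1 Training trials in each SRT/CRT phase (default 4).
#' @param training_vr Training trials in each reach task (default 2).
#' @param display_phase1_ms,display_vr_ms Stimulus display durations, ms.
#' @param isi_phase1_ms,isi_vr_ms Length-2 closed ISI ranges, ms; draws are
#'   continuous uniform.
#' @param center_trials,spatial_trials,dynamic_trials Test-trial counts for
#'   the three reach tasks.
#' @param speeds Dynamic-task cube speeds, m/s, applied in order to successive
#'   blocks of `dynamic_trials / length(speeds)` test trials.
#' @param seed Integer seed from which all schedule randomization flows.
#' @return A list of class `rt_protocol_config`.
#' @export
protocol_config <- function(trials_per_type = 20, per_color = FALSE,
                            training_phase1 = 4, training_vr = 2,
                            display_phase1_ms = 260, display_vr_ms = 2000,
                            isi_phase1_ms = c(1000, 2000),
                            isi_vr_ms = c(3000, 4500),
                            center_trials = 20, spatial_trials = 18,
                            dynamic_trials = 27,
                            speeds = c(0.6, 0.75, 0.9),
                            seed = 1L) {
  cfg <- list(trials_per_type = as.integer(trials_per_type),
              per_color = isTRUE(per_color),
              training_phase1 = as.integer(training_phase1),
              training_vr = as.integer(training_vr),
              display_phase1_ms = display_phase1_ms,
              display_vr_ms = display_vr_ms,
              isi_phase1_ms = as.numeric(isi_phase1_ms),
              isi_vr_ms = as.numeric(isi_vr_ms),
              center_trials = as.integer(center_trials),
              spatial_trials = as.integer(spatial_trials),
              dynamic_trials = as.integer(dynamic_trials),
              speeds = as.numeric(speeds),
              seed = as.integer(seed))
  validate_protocol_config(cfg)
  structure(cfg, class = "rt_protocol_config")
}

validate_protocol_config <- function(cfg) {
  stopifnot(cfg$trials_per_type >= 1, cfg$display_phase1_ms > 0,
            cfg$display_vr_ms > 0, length(cfg$isi_phase1_ms) == 2,
            length(cfg$isi_vr_ms) == 2)
  if (cfg$isi_phase1_ms[1] >= cfg$isi_phase1_ms[2] ||
      cfg$isi_vr_ms[1] >= cfg$isi_vr_ms[2])
    stop("ISI ranges must have min < max", call. = FALSE)
  if (any(cfg$speeds <= 0)) stop("speeds must be positive", call. = FALSE)
  if (cfg$dynamic_trials %% 9 != 0)
    stop("dynamic test-trial count must allocate equally over 9 origins",
         call. = FALSE)
  invisible(cfg)
}

new_schedule <- function(task, trials, seed) {
  rownames(trials) <- NULL
  structure(trials, task = task, rng_seed = seed,
            class = c("rt_schedule", "data.frame"))
}

schedule_task <- function(x) attr(x, "task")

#' @export
print.rt_schedule <- function(x, ...) {
  cat(sprintf("Task schedule '%s': %d training + %d test trials (seed %d)\n",
              attr(x, "task"), sum(x$is_training), sum(!x$is_training),
              attr(x, "rng_seed")))
  print.data.frame(utils::head(as.data.frame(x), 8))
  if (nrow(x) > 8) cat(sprintf("... %d more trials\n", nrow(x) - 8))
  invisible(x)
}

# A counterbalanced, shuffled color deck: each color appears floor(n/4) or
# ceiling(n/4) times; exact equality requires 4 | n.
color_deck <- function(n, colors = RT_COLORS) {
  deck <- rep(colors, ceiling(n / length(colors)))[seq_len(n)]
  sample(deck)
}

trial_frame <- function(task, n_train, n_test, color, is_go, display_ms,
                        isi_range, location_index = NA_integer_,
                        speed = NA_real_, origin_index = NA_integer_,
                        target_index = NA_integer_) {
  n <- n_train + n_test
  data.frame(task = task, index = seq_len(n),
             is_training = rep(c(TRUE, FALSE), c(n_train, n_test)),
             color = color, is_go = is_go, display_ms = display_ms,
             isi_ms = stats::runif(n, isi_range[1], isi_range[2]),
             location_index = location_index, speed = speed,
             origin_index = origin_index, target_index = target_index,
             stringsAsFactors = FALSE)
}

phase1_params <- function(cfg, mode) {
  mode <- match.arg(mode, c("computer", "press"))
  # the VR Press phase mirrors the computerized protocol exactly
  list(prefix = if (mode == "computer") "com" else "press",
       display = cfg$display_phase1_ms, isi = cfg$isi_phase1_ms)
}

#' Build a simple-reaction-time phase schedule
#'
#' The SRT phase presents stimuli of all four colors, all requiring a
#' response. Test trials are counterbalanced over colors (exactly equal
#' counts, 25% each), shuffled, displayed for 260 ms with ISIs drawn uniformly
#' from 1000-2000 ms. Training trials precede test trials and use the same
#' generative rules.
#'
#' @param cfg An `rt_protocol_config`.
#' @param mode `"computer"` (keyboard space bar) or `"press"` (the controller
#'   button task of the VR test's first phase, which mirrors the computerized
#'   protocol).
#' @param seed Optional integer overriding `cfg$seed`.
#' @return An `rt_schedule` data frame, one row per trial.
#' @export
build_srt_phase <- function(cfg, mode = c("computer", "press"), seed = NULL) {
  mode <- match.arg(mode)
  pp <- phase1_params(cfg, mode)
  seed <- if (is.null(seed)) cfg$seed else as.integer(seed)
  n_test <- if (cfg$per_color) 4L * cfg$trials_per_type else cfg$trials_per_type
  if (n_test %% 4L != 0L)
    stop("SRT test-trial count must be divisible by the 4 colors", call. = FALSE)
  withr::with_seed(seed, {
    colors <- c(color_deck(cfg$training_phase1), color_deck(n_test))
    trials <- trial_frame(paste0(pp$prefix, "_srt"), cfg$training_phase1,
                          n_test, colors, is_go = TRUE,
                          display_ms = pp$display, isi_range = pp$isi)
  })
  new_schedule(paste0(pp$prefix, "_srt"), trials, seed)
}

#' Build a choice-reaction-time phase schedule
#'
#' The CRT phase mixes go stimuli (green, yellow) with no-go stimuli (blue,
#' red) at equal counts per category and per color; participants respond only
#' to go colors. Timing matches the SRT phase.
#'
#' @inheritParams build_srt_phase
#' @return An `rt_schedule`.
#' @export
build_crt_phase <- function(cfg, mode = c("computer", "press"), seed = NULL) {
  mode <- match.arg(mode)
  pp <- phase1_params(cfg, mode)
  seed <- if (is.null(seed)) cfg$seed + 1L else as.integer(seed)
  per_cat <- if (cfg$per_color) 2L * cfg$trials_per_type else cfg$trials_per_type
  if (per_cat %% 2L != 0L)
    stop("CRT per-category count must be divisible by the 2 colors per category",
         call. = FALSE)
  withr::with_seed(seed, {
    test_colors <- sample(c(rep(CRT_GO_COLORS, per_cat / 2L),
                            rep(setdiff(RT_COLORS, CRT_GO_COLORS), per_cat / 2L)))
    colors <- c(color_deck(cfg$training_phase1), test_colors)
    trials <- trial_frame(paste0(pp$prefix, "_crt"), cfg$training_phase1,
                          2L * per_cat, colors,
                          is_go = colors %in% CRT_GO_COLORS,
                          display_ms = pp$display, isi_range = pp$isi)
  })
  new_schedule(paste0(pp$prefix, "_crt"), trials, seed)
}

#' Build the Center reach-task schedule
#'
#' Cubes appear over the fixation point at location 5; every stimulus is
#' reached for (a simple-RT reach task). Colors are counterbalanced exactly;
#' display is 2000 ms with ISIs uniform on 3000-4500 ms.
#'
#' @inheritParams build_srt_phase
#' @return An `rt_schedule`.
#' @export
build_center_task <- function(cfg, seed = NULL) {
  seed <- if (is.null(seed)) cfg$seed + 2L else as.integer(seed)
  withr::with_seed(seed, {
    colors <- c(color_deck(cfg$training_vr), color_deck(cfg$center_trials))
    trials <- trial_frame("center", cfg$training_vr, cfg$center_trials,
                          colors, is_go = TRUE,
                          display_ms = cfg$display_vr_ms,
                          isi_range = cfg$isi_vr_ms, location_index = 5L)
  })
  new_schedule("center", trials, seed)
}

#' Build the Spatial reach-task schedule
#'
#' Cubes appear at one of the nine grid locations; each location receives
#' exactly two test trials, one in a color previously used as a go stimulus
#' (yellow or green) and one in a formerly no-go color (blue or red). All
#' stimuli are reached for. Presentation order is randomized.
#'
#' @inheritParams build_srt_phase
#' @return An `rt_schedule`.
#' @export
build_spatial_task <- function(cfg, seed = NULL) {
  seed <- if (is.null(seed)) cfg$seed + 3L else as.integer(seed)
  if (cfg$spatial_trials != 18L)
    stop("the spatial task pairs one former-go and one former-no-go color at each of 9 locations (18 trials)",
         call. = FALSE)
  withr::with_seed(seed, {
    test <- data.frame(location_index = rep(1:9, each = 2L),
                       color = as.vector(vapply(1:9, function(i)
                         c(sample(CRT_GO_COLORS, 1), sample(setdiff(RT_COLORS, CRT_GO_COLORS), 1)),
                         character(2))),
                       stringsAsFactors = FALSE)
    test <- test[sample(nrow(test)), ]
    colors <- c(color_deck(cfg$training_vr), test$color)
    locs <- c(sample(1:9, cfg$training_vr, replace = TRUE), test$location_index)
    trials <- trial_frame("spatial", cfg$training_vr, cfg$spatial_trials,
                          colors, is_go = TRUE,
                          display_ms = cfg$display_vr_ms,
                          isi_range = cfg$isi_vr_ms, location_index = locs)
  })
  new_schedule("spatial", trials, seed)
}

#' Build the Dynamic reach-task schedule
#'
#' Cubes appear at one of the nine locations while translating toward one of
#' the other eight, chosen uniformly. Each location is the origin of exactly
#' three test trials. Cube speed is staged by test-trial position: the first
#' nine repetitions at 0.6 m/s, the next nine at 0.75 m/s, and the final nine
#' at 0.9 m/s (the configured `speeds`, in order). Colors come from a shuffled
#' near-balanced deck (27 trials over 4 colors gives counts 7/7/7/6).
#'
#' @inheritParams build_srt_phase
#' @return An `rt_schedule`.
#' @export
build_dynamic_task <- function(cfg, seed = NULL) {
  seed <- if (is.null(seed)) cfg$seed + 4L else as.integer(seed)
  n_test <- cfg$dynamic_trials
  per_origin <- n_test / 9L
  block <- n_test / length(cfg$speeds)
  withr::with_seed(seed, {
    origins <- sample(rep(1:9, per_origin))
    targets <- vapply(origins, function(o) sample(setdiff(1:9, o), 1L), 0L)
    # speed staging is by test-trial position, deterministic across seeds
    speeds <- rep(cfg$speeds, each = block)[seq_len(n_test)]
    tr_origin <- sample(1:9, cfg$training_vr, replace = TRUE)
    tr_target <- vapply(tr_origin, function(o) sample(setdiff(1:9, o), 1L), 0L)
    colors <- c(color_deck(cfg$training_vr), color_deck(n_test))
    trials <- trial_frame("dynamic", cfg$training_vr, n_test, colors,
                          is_go = TRUE, display_ms = cfg$display_vr_ms,
                          isi_range = cfg$isi_vr_ms,
                          location_index = c(tr_origin, origins),
                          speed = c(rep(cfg$speeds[1], cfg$training_vr), speeds),
                          origin_index = c(tr_origin, origins),
                          target_index = c(tr_target, targets))
  })
  new_schedule("dynamic", trials, seed)
}

#' Build every schedule of one or both tests
#'
#' @param cfg An `rt_protocol_config`.
#' @param test `"com"` for the computerized test (SRT + CRT phases), `"vr"`
#'   for the VR test (Press SRT/CRT + Center + Spatial + Dynamic), or
#'   `"both"`.
#' @return Named list of `rt_schedule` objects in administration order.
#' @export
build_protocol <- function(cfg, test = c("both", "com", "vr")) {
  test <- match.arg(test)
  com <- list(com_srt = build_srt_phase(cfg, "computer", seed = cfg$seed),
              com_crt = build_crt_phase(cfg, "computer", seed = cfg$seed + 1L))
  vr <- list(press_srt = build_srt_phase(cfg, "press", seed = cfg$seed + 10L),
             press_crt = build_crt_phase(cfg, "press", seed = cfg$seed + 11L),
             center = build_center_task(cfg, seed = cfg$seed + 12L),
             spatial = build_spatial_task(cfg, seed = cfg$seed + 13L),
             dynamic = build_dynamic_task(cfg, seed = cfg$seed + 14L))
  switch(test, com = com, vr = vr, both = c(com, vr))
}
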