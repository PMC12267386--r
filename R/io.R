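# Session file format (JSONL: one header object, then one event per line),
# run configuration (YAML), and CSV emitters.

SESSION_SCHEMA_VERSION <- "1.0"

#' Write a session event log to a JSONL file
#'
#' Line 1 is the session header (schema version, participant, calibration,
#' grid angles, schedules, seed, simulation parameters and their hash); every
#' following line is one event object. Timestamps (ms) and positions (m) are
#' written at full double precision so a read round-trips exactly.
#'
#' @param session An `rt_session`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(is.list(session), !is.null(session$header))
  header <- session$header
  header$version <- SESSION_SCHEMA_VERSION
  con <- file(path, "w")
  on.exit(close(con))
  # digits = 17 decimal places: doubles survive the text round trip exactly
  writeLines(jsonlite::toJSON(header, auto_unbox = TRUE, digits = 17,
                              dataframe = "rows", na = "null"), con)
  ev <- session$events
  if (!is.null(ev) && nrow(ev)) {
    jsonlite::stream_out(ev, con, digits = 17, na = "null", verbose = FALSE)
  }
  invisible(path)
}

#' Read a session event log from a JSONL file
#'
#' Parses and validates a file written by [write_session()] (or an external
#' logger following the same schema). The schema version is checked, and the
#' event stream must be non-decreasing in time; a malformed line raises a
#' parse error naming the last valid line.
#'
#' @param path Input file path.
#' @return An `rt_session`.
#' @export
read_session <- function(path) {
  if (!file.exists(path)) stop("no such session file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty session file: ", path, call. = FALSE)
  header <- tryCatch(jsonlite::fromJSON(lines[1], simplifyVector = TRUE),
                     error = function(e)
                       stop("parse error in header (line 1): ", conditionMessage(e),
                            call. = FALSE))
  if (is.null(header$version) || header$version != SESSION_SCHEMA_VERSION)
    stop(sprintf("unsupported session schema version '%s' (expected %s)",
                 header$version, SESSION_SCHEMA_VERSION), call. = FALSE)
  ev_lines <- lines[-1]
  ev_lines <- ev_lines[nzchar(ev_lines)]
  if (length(ev_lines)) {
    events <- tryCatch(
      jsonlite::stream_in(textConnection(ev_lines), verbose = FALSE),
      error = function(e) {
        last_ok <- 1
        for (i in seq_along(ev_lines)) {
          ok <- tryCatch({ jsonlite::fromJSON(ev_lines[i]); TRUE },
                         error = function(e) FALSE)
          if (!ok) break
          last_ok <- i + 1
        }
        stop(sprintf("parse error after line %d of %s", last_ok, path),
             call. = FALSE)
      })
    for (col in c("t", "x", "y", "z"))
      if (!is.null(events[[col]])) events[[col]] <- as.numeric(events[[col]])
    if (is.unsorted(events$t))
      stop("malformed session: event timestamps decrease", call. = FALSE)
  } else {
    events <- data.frame(t = numeric(), kind = character(),
                         task = character(), trial_index = integer(),
                         x = numeric(), y = numeric(), z = numeric(),
                         stringsAsFactors = FALSE)
  }
  if (is.null(header$schedules)) header$schedules <- list()
  structure(list(header = header, events = events), class = "rt_session")
}

#' Default run configuration
#'
#' All defaults reproduce the instrument's protocol constants: 260 / 2000 ms
#' displays, 1000-2000 and 3000-4500 ms ISI ranges, 0.6/0.75/0.9 m/s dynamic
#' speeds, 30/35 degree grid angles, the 0.028 m base radius, 0.10 m cubes,
#' and the 100/1000/600 ms scoring cutoffs.
#'
#' @param seed Master seed.
#' @param cohort_n Cohort size for simulation (default 48, the instrument's
#'   analyzed sample size).
#' @return Nested list (`protocol`, `population`, `geometry`, `scoring`,
#'   `cohort_n`, `seed`).
#' @export
default_run_config <- function(seed = 1L, cohort_n = 48L) {
  list(protocol = unclass(protocol_config(seed = seed)),
       population = list(s_between = 18, vr_bias = 32.44),
       geometry = list(elevation_deg = 30, azimuth_deg = 35,
                       base_radius_m = BASE_RADIUS_M, cube_edge_m = 0.10),
       scoring = list(rt_min_ms = RT_MIN_MS, rt_max_ms = RT_MAX_MS,
                      mt_cutoff_ms = MT_CUTOFF_MS),
       cohort_n = as.integer(cohort_n), seed = as.integer(seed))
}

#' Read a YAML run configuration
#'
#' Values present in the file override the defaults of
#' [default_run_config()]; everything else keeps its default.
#'
#' @param path YAML file path.
#' @return Config list as in [default_run_config()].
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- default_run_config()
  merge_lists <- function(a, b) {
    for (nm in names(b)) {
      a[[nm]] <- if (is.list(a[[nm]]) && is.list(b[[nm]]))
        merge_lists(a[[nm]], b[[nm]]) else b[[nm]]
    }
    a
  }
  cfg <- merge_lists(base, user)
  cfg$protocol <- do.call(protocol_config, cfg$protocol)
  cfg$protocol <- unclass(cfg$protocol)
  cfg
}

#' Write a run configuration to YAML
#'
#' @param cfg Config list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}
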