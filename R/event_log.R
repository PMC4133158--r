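#' Light/dark cycle schedule
#'
#' Describes the daily illumination cycle of the recording environment.
#' The period is fixed at 24 hours; animals housed on a 12 h/12 h
#' light/dark cycle correspond to the default `light_hours = 12`.
#'
#' @param light_onset Clock hour (0-24) at which the light cycle begins.
#' @param light_hours Hours of light per day; must lie strictly between 0
#'   and the period.
#' @param period Cycle period in hours; fixed at 24.
#' @return An object of class `cycle_schedule`.
#' @export
#' @examples
#' cycle_schedule(light_onset = 8)
cycle_schedule <- function(light_onset = 8, light_hours = 12, period = 24) {
  stopifnot(is.numeric(light_onset), length(light_onset) == 1L,
            is.numeric(light_hours), length(light_hours) == 1L)
  if (period != 24) stop("cycle period is fixed at 24 hours")
  if (light_hours <= 0 || light_hours >= period)
    stop("light_hours must lie strictly between 0 and the period")
  structure(list(light_onset = light_onset %% period,
                 light_hours = light_hours, period = period),
            class = "cycle_schedule")
}

#' Construct a validated choice event log
#'
#' The central container: one record per lever press, with time in seconds
#' from session start and the identity of the chosen option. Timestamps
#' must be strictly increasing and every option must belong to the
#' declared option set.
#'
#' @param time Numeric vector of event times, seconds from session start
#'   (non-negative, strictly increasing).
#' @param option Vector (character or factor) of chosen-option identifiers,
#'   one per event.
#' @param schedule A [cycle_schedule()].
#' @param options The declared option set; defaults to the distinct values
#'   observed, in order of first appearance.
#' @param duration Total recorded seconds; defaults to the last timestamp.
#'   Must be at least the last timestamp.
#' @param session_start Clock hour at which recording began; defaults to
#'   the light onset. Used to convert timestamps to clock time.
#' @param labels Optional named character vector of per-option metadata
#'   (e.g. flavor or lever location).
#' @return An object of class `event_log`.
#' @export
event_log <- function(time, option, schedule = cycle_schedule(),
                      options = NULL, duration = NULL,
                      session_start = schedule$light_onset, labels = NULL) {
  time <- as.numeric(time)
  n <- length(time)
  if (n == 0L) stop("empty log: no events")
  if (length(option) != n)
    stop("`time` and `option` must have equal length")
  if (anyNA(time)) stop("timestamps contain missing values")
  if (any(time < 0)) stop("timestamps must be non-negative")
  if (n > 1L && any(diff(time) <= 0))
    stop("timestamps must be strictly increasing (violation at event ",
         which(diff(time) <= 0)[1L] + 1L, ")")
  option <- as.character(option)
  if (is.null(options)) options <- unique(option)
  if (!all(option %in% options))
    stop("options outside the declared option set: ",
         paste(setdiff(option, options), collapse = ", "))
  if (is.null(duration)) duration <- time[n]
  if (duration < time[n]) stop("duration must be >= the last timestamp")
  stopifnot(inherits(schedule, "cycle_schedule"))
  structure(list(time = time, option = option, options = options,
                 schedule = schedule, duration = as.numeric(duration),
                 session_start = session_start %% 24, labels = labels),
            class = "event_log")
}

#' @export
print.event_log <- function(x, ...) {
  cat("<event_log> ", length(x$time), " events, ",
      length(x$options), " options, ",
      sprintf("%.2f", x$duration / 86400), " days\n", sep = "")
  cat("  options: ", paste(x$options, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.event_log <- function(x, ...) {
  data.frame(time_s = x$time, option = x$option,
             stringsAsFactors = FALSE)
}

#' Number of events in a log
#' @param log An [event_log()].
#' @return Integer event count.
#' @export
n_events <- function(log) {
  stopifnot(inherits(log, "event_log"))
  length(log$time)
}

#' Read a choice event log from CSV
#'
#' Expects a header `time_s,option`; extra columns (e.g. `day`, `flavor`,
#' `location`) are ignored. Rows must parse as (numeric time, option) and
#' times must be strictly increasing.
#'
#' @param path Path to the CSV file.
#' @param schedule A [cycle_schedule()].
#' @param ... Passed on to [event_log()] (e.g. `duration`, `options`).
#' @return An [event_log()].
#' @export
read_event_log <- function(path, schedule = cycle_schedule(), ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  info <- file.info(path)
  if (info$size == 0) stop("empty log file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty log file (header only): ", path)
  if (!all(c("time_s", "option") %in% names(df)))
    stop("missing required columns `time_s`, `option` in ", path)
  time <- suppressWarnings(as.numeric(df$time_s))
  if (anyNA(time))
    stop("malformed time at line ", which(is.na(time))[1L] + 1L,
         " of ", path)
  event_log(time, df$option, schedule = schedule, ...)
}

#' Write a choice event log to CSV
#'
#' Writes the canonical two-column `time_s,option` format; reading the
#' result back with [read_event_log()] reproduces the records.
#'
#' @param log An [event_log()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(log, path) {
  stopifnot(inherits(log, "event_log"))
  utils::write.csv(as.data.frame(log), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Clock hour of timestamps
#'
#' Converts seconds-from-session-start to clock hour of day, using the
#' session's recorded start hour.
#'
#' @param log An [event_log()].
#' @param time Times in seconds; defaults to the log's event times.
#' @return Numeric clock hours in `[0, 24)`.
#' @export
clock_hour <- function(log, time = log$time) {
  (log$session_start + time / 3600) %% 24
}

#' Label events by light/dark cycle
#'
#' Each event is labeled by the cycle containing its clock time. Cycle
#' intervals are half-open: an event exactly at light onset is "light".
#'
#' @param log An [event_log()].
#' @param time Times in seconds; defaults to the log's event times.
#' @return Factor with levels `light`, `dark`, one per time.
#' @export
#' @examples
#' log <- event_log(c(3600, 13 * 3600), c("A", "B"),
#'                  cycle_schedule(light_onset = 8))
#' assign_cycle_labels(log)
assign_cycle_labels <- function(log, time = log$time) {
  stopifnot(inherits(log, "event_log"))
  sch <- log$schedule
  since_onset <- (clock_hour(log, time) - sch$light_onset) %% sch$period
  factor(ifelse(since_onset < sch$light_hours, "light", "dark"),
         levels = c("light", "dark"))
}
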