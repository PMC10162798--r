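#' Behavioral event kinds
#'
#' The fixed vocabulary of timestamped events an operant session can emit.
#' At equal times events sort deterministically: extensions first, then
#' presses, retractions, cues, and rewards last, so that e.g. the press that
#' triggers a lever exchange is logged before the retraction it causes.
#'
#' @return Character vector of the recognized event kinds.
#' @export
event_kinds <- function() {
  c("lever_extend_left", "lever_extend_right",
    "press_left", "press_right",
    "lever_retract_left", "lever_retract_right",
    "cue_on", "cue_off",
    "reward")
}

# rank used to break ties at identical timestamps
kind_rank <- function(kind) {
  rank <- c(lever_extend_left = 1, lever_extend_right = 1,
            press_left = 2, press_right = 2,
            lever_retract_left = 3, lever_retract_right = 3,
            cue_on = 4, cue_off = 4,
            reward = 5)
  unname(rank[kind])
}

#' Construct an event log
#'
#' An event log is the alignment source for all downstream analysis: an
#' ordered table of `(time_s, kind)` rows plus session metadata. Events are
#' sorted by time with the deterministic tie order described in
#' [event_kinds()].
#'
#' @param time_s Numeric vector of event times, seconds from session start.
#' @param kind Character vector of event kinds, same length as `time_s`.
#' @param duration Session duration in seconds.
#' @param task_label Identifier for the task that produced the log.
#' @param schedule_ratio Fixed-ratio requirement, or `NA` for tasks without
#'   one.
#' @param seed Integer seed the simulator used (or `NA` for real data).
#' @return An object of class `event_log`: a list with elements `events`
#'   (data.frame `time_s`, `kind`), `duration`, `task_label`,
#'   `schedule_ratio`, `seed`.
#' @export
event_log <- function(time_s, kind, duration, task_label = "unknown",
                      schedule_ratio = NA_integer_, seed = NA_integer_) {
  if (length(time_s) != length(kind))
    stop_invalid("`time_s` and `kind` must have equal length")
  if (!all(kind %in% event_kinds()))
    stop_invalid(sprintf("unrecognized event kind(s): %s",
                         paste(setdiff(unique(kind), event_kinds()),
                               collapse = ", ")))
  check_positive_scalar(duration, "duration")
  if (length(time_s) && (min(time_s) < 0 || max(time_s) > duration))
    stop_invalid("event times must lie within [0, duration]")
  ord <- order(time_s, kind_rank(kind))
  structure(
    list(events = data.frame(time_s = as.numeric(time_s)[ord],
                             kind = as.character(kind)[ord],
                             stringsAsFactors = FALSE),
         duration = as.numeric(duration),
         task_label = task_label,
         schedule_ratio = schedule_ratio,
         seed = seed),
    class = "event_log")
}

#' @export
print.event_log <- function(x, ...) {
  cat(sprintf("<event_log> task=%s, duration=%.1f s, %d events\n",
              x$task_label, x$duration, nrow(x$events)))
  tab <- table(x$events$kind)
  for (k in names(tab)) cat(sprintf("  %-20s %d\n", k, tab[[k]]))
  invisible(x)
}

#' Extract event times of one kind
#'
#' @param log An [event_log()].
#' @param kind One or more event kinds; `"press_any"` selects both press
#'   kinds, `"extension_any"` both extensions.
#' @return Numeric vector of event times in seconds, sorted.
#' @export
event_times <- function(log, kind) {
  stopifnot(inherits(log, "event_log"))
  if (identical(kind, "press_any")) kind <- c("press_left", "press_right")
  if (identical(kind, "extension_any"))
    kind <- c("lever_extend_left", "lever_extend_right")
  log$events$time_s[log$events$kind %in% kind]
}

#' Check the internal invariants of an event log
#'
#' Verifies ordering, time bounds, and (for fixed-ratio logs) reinforcement
#' conservation: at every instant the cumulative reward count equals
#' `floor(cumulative presses on the active lever / ratio)`.
#'
#' @param log An [event_log()].
#' @return `TRUE` invisibly; signals an error when an invariant is violated.
#' @export
validate_event_log <- function(log) {
  stopifnot(inherits(log, "event_log"))
  ev <- log$events
  if (nrow(ev)) {
    if (is.unsorted(ev$time_s)) stop_invalid("events not sorted by time")
    if (min(ev$time_s) < 0 || max(ev$time_s) > log$duration)
      stop_invalid("event times outside [0, duration]")
    key <- order(ev$time_s, kind_rank(ev$kind))
    if (!identical(key, seq_len(nrow(ev))))
      stop_invalid("tie order violated at equal timestamps")
  }
  if (!is.na(log$schedule_ratio)) {
    n <- nrow(ev)
    presses <- cumsum(ev$kind %in% c("press_left", "press_right"))
    rewards <- cumsum(ev$kind == "reward")
    # conservation checked after each event; rewards may lag presses only by
    # an in-flight dispense, never lead them
    expected <- floor(presses / log$schedule_ratio)
    if (any(rewards > expected))
      stop_invalid("reward count exceeds floor(presses/ratio)")
    if (n && rewards[n] != expected[n] &&
        expected[n] - rewards[n] > 1)
      stop_invalid("rewards lag presses by more than one in-flight dispense")
  }
  invisible(TRUE)
}

#' Write / read an event log as CSV with a JSON sidecar
#'
#' The CSV holds `time_s,kind`; session metadata (task label, duration,
#' ratio, seed) lives in `<path>.json` next to it.
#'
#' @param log An [event_log()].
#' @param path CSV file path.
#' @return `write_event_log` returns `path` invisibly; `read_event_log`
#'   returns the reconstructed `event_log`.
#' @export
write_event_log <- function(log, path) {
  stopifnot(inherits(log, "event_log"))
  utils::write.csv(log$events, path, row.names = FALSE, quote = FALSE)
  meta <- list(task_label = log$task_label, duration = log$duration,
               schedule_ratio = log$schedule_ratio, seed = log$seed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  ratio <- meta$schedule_ratio
  event_log(ev$time_s, ev$kind, meta$duration, meta$task_label,
            if (is.null(ratio) || is.na(ratio)) NA_integer_ else ratio,
            if (is.null(meta$seed)) NA_integer_ else meta$seed)
}
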