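#' Event logs and replay
#'
#' Every engine interaction is expressible as an event: a laboratory result,
#' an acknowledgment, a silencing change, or a clock tick. The engine state
#' is a deterministic function of the event log, so [replay()] rebuilds it
#' from scratch; this is the event-sourcing contract that makes incremental
#' operation auditable and testable.
#'
#' @name events
NULL

.iso <- function(ts) format(ts, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
.from_iso <- function(x) as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S",
                                    tz = "UTC")

#' Convert a result set to result events
#' @param results `lab_result` data.frame.
#' @return list of result events, in row order.
#' @export
events_from_results <- function(results) {
  lapply(seq_len(nrow(results)), function(i) {
    r <- results[i, ]
    list(type = "result", measured_at = .iso(r$measured_at),
         patient_id = r$patient_id, case_id = r$case_id,
         order_id = r$order_id, parameter = r$parameter, value = r$value,
         units = r$raw_units, source = r$source)
  })
}

#' Tick / acknowledgment / silence event constructors
#' @param at POSIXct event time.
#' @return event list.
#' @export
event_tick <- function(at) list(type = "tick", at = .iso(at))

#' @rdname event_tick
#' @param patient_id patient identifier.
#' @param actor acknowledging actor.
#' @export
event_ack <- function(patient_id, actor, at) {
  list(type = "ack", patient_id = patient_id, actor = actor, at = .iso(at))
}

#' @rdname event_tick
#' @param algorithm_id algorithm id or "ALL".
#' @param flag TRUE to silence.
#' @export
event_silence <- function(patient_id, algorithm_id = "ALL", flag = TRUE,
                          at = NULL) {
  list(type = "silence", patient_id = patient_id,
       algorithm_id = algorithm_id, flag = flag,
       at = if (is.null(at)) NULL else .iso(at))
}

#' Rebuild an engine state from an event log
#'
#' Applies the events in order to a fresh engine. Serves as the
#' from-scratch oracle for incremental operation: for any time-ordered log,
#' `replay(log)` equals the state built by stepwise [ingest()]/[tick()]
#' calls, and replaying a log with a duplicated suffix equals replaying the
#' log itself.
#'
#' @param events list of events (see [events_from_results()],
#'   [event_tick()]).
#' @param rules,config engine construction arguments.
#' @return the resulting `engine_state`.
#' @export
replay <- function(events, rules = build_default_rulesets(),
                   config = engine_config()) {
  state <- engine_new(rules, config)
  for (ev in events) {
    state <- switch(ev$type,
      result = {
        r <- lab_result(.from_iso(ev$measured_at), ev$patient_id,
                        ev$case_id, ev$order_id, ev$parameter, ev$value,
                        ev$units %||% "", ev$source %||% "LAB")
        ingest(state, r)$state
      },
      tick = {
        at <- .from_iso(ev$at)
        # a re-delivered (stale) tick is a no-op during replay: everything
        # due at that time has already been processed
        if (!is.na(state$clock) && at < state$clock) state
        else tick(state, at)$state
      },
      ack = acknowledge(state, ev$patient_id, ev$actor, .from_iso(ev$at)),
      silence = set_silence(state, ev$patient_id,
                            ev$algorithm_id %||% "ALL",
                            isTRUE(ev$flag)),
      stop("unknown event type: ", ev$type)
    )
  }
  state
}

#' Write an event log as JSON lines
#' @param events list of events.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(events, path) {
  lines <- vapply(events, function(ev) {
    jsonlite::toJSON(ev, auto_unbox = TRUE, digits = NA)
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a JSON-lines event log
#' @param path input path.
#' @return list of events.
#' @export
read_event_log <- function(path) {
  if (!file.exists(path)) stop("event log not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(l) jsonlite::fromJSON(l, simplifyVector = TRUE))
}

#' Export a notification log
#' @param state an `engine_state`.
#' @param path output path (.csv or .jsonl by extension).
#' @param include_suppressed include suppressed audit entries.
#' @return `path`, invisibly.
#' @export
write_notification_log <- function(state, path,
                                   include_suppressed = FALSE) {
  n <- notification_log(state, include_suppressed)
  n$created_at <- .iso(n$created_at)
  n$trigger_measured_at <- .iso(n$trigger_measured_at)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    utils::write.csv(n, path, row.names = FALSE)
  } else {
    writeLines(vapply(seq_len(nrow(n)), function(i) {
      jsonlite::toJSON(as.list(n[i, ]), auto_unbox = TRUE, digits = NA)
    }, character(1)), path)
  }
  invisible(path)
}
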