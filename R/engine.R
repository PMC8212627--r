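#' The surveillance engine
#'
#' The engine is the stateful reactive core: it ingests validated
#' laboratory results, maintains one alert episode per patient and
#' algorithm, runs time-to-control (TTC) escalation timers, and emits
#' auditable notifications. Control-arm patients (odd trailing patient-ID
#' digit) are fully evaluated but their notifications are suppressed from
#' the output channel; silenced patients/algorithms likewise. All state
#' transitions are deterministic functions of the event log, so the engine
#' can be rebuilt exactly by [replay()].
#'
#' @name engine
NULL

#' Engine configuration
#'
#' @param arm_suppression suppress control-arm notifications from the
#'   output channel (they remain in the audit log).
#' @param retention_days results older than this relative to the engine
#'   clock are rejected.
#' @param max_skew_hours allowed forward clock skew at ingest.
#' @param tick_seconds daemon tick cadence used by the CLI (the engine
#'   itself only advances on explicit [tick()] calls).
#' @param aki_mapping AKI stage to severity mapping, see
#'   [severity_for_aki()].
#' @return list of class `engine_config`.
#' @export
engine_config <- function(arm_suppression = TRUE, retention_days = 30,
                          max_skew_hours = 24, tick_seconds = 60,
                          aki_mapping = c(`0` = "GREEN", `1` = "YELLOW",
                                          `2` = "RED", `3` = "RED")) {
  structure(list(arm_suppression = arm_suppression,
                 retention_days = retention_days,
                 max_skew_hours = max_skew_hours,
                 tick_seconds = tick_seconds,
                 aki_mapping = aki_mapping),
            class = "engine_config")
}

.empty_notifications <- function() {
  data.frame(notification_id = character(), created_at = as.POSIXct(character(), tz = "UTC"),
             patient_id = character(), case_id = character(),
             algorithm_id = character(), kind = character(),
             severity = character(), message = character(),
             dedup_key = character(), arm = character(),
             suppressed = logical(), trigger_measured_at = as.POSIXct(character(), tz = "UTC"),
             stringsAsFactors = FALSE)
}

.empty_audit <- function() {
  data.frame(at = as.POSIXct(character(), tz = "UTC"), type = character(),
             detail = character(), stringsAsFactors = FALSE)
}

#' Create an empty engine state
#'
#' @param rules named list of `lab_rule` objects
#'   (default [build_default_rulesets()]).
#' @param config an [engine_config()].
#' @return object of class `engine_state`.
#' @export
engine_new <- function(rules = build_default_rulesets(),
                       config = engine_config()) {
  structure(list(
    rules = rules, config = config,
    history = cbind(empty_results(), seq = integer()),
    seq = 0L,
    open = list(),          # key -> open episode
    closed = list(),        # archived episodes, in closing order
    status = list(),        # key -> current severity
    notifications = .empty_notifications(),
    audit = .empty_audit(),
    acks = list(),          # patient -> list(actor, at)
    silenced = character(), # keys "patient||ALL" or "patient||algorithm"
    calls = .empty_calls(),
    clock = as.POSIXct(NA),
    seen_results = character(),
    seen_notifications = character(),
    episode_counter = 0L, notification_counter = 0L
  ), class = "engine_state")
}

.key <- function(patient_id, algorithm_id) {
  paste(patient_id, algorithm_id, sep = "||")
}

.is_silenced <- function(state, patient_id, algorithm_id) {
  any(c(.key(patient_id, "ALL"), .key(patient_id, algorithm_id)) %in%
        state$silenced)
}

.patient_known <- function(state, patient_id) {
  patient_id %in% state$history$patient_id
}

.audit <- function(state, at, type, detail) {
  state$audit <- rbind(state$audit, data.frame(
    at = at, type = type, detail = detail, stringsAsFactors = FALSE))
  state
}

.new_episode <- function(state, rule, r, severity, annotation) {
  state$episode_counter <- state$episode_counter + 1L
  deadline <- if (identical(rule$ttc_hours, "immediate")) as.POSIXct(NA)
              else r$measured_at + rule$ttc_hours * 3600
  ep <- list(episode_id = sprintf("E%06d", state$episode_counter),
             patient_id = r$patient_id, case_id = r$case_id,
             algorithm_id = rule$algorithm_id, severity = severity,
             trigger_result = r, ttc_deadline = deadline,
             controlled = FALSE, control_result = NULL,
             escalated = FALSE, annotation = annotation,
             opened_at = r$measured_at)
  list(state = state, episode = ep)
}

.emit <- function(state, kind, ep, created_at, message, severity) {
  dedup <- paste(ep$patient_id, ep$algorithm_id,
                 format(ep$trigger_result$measured_at, "%Y%m%d%H%M%S"),
                 kind, sep = "|")
  if (dedup %in% state$seen_notifications) return(state)
  state$seen_notifications <- c(state$seen_notifications, dedup)
  arm <- assign_arm(ep$patient_id)
  suppressed <- (arm == "CONTROL" && state$config$arm_suppression) ||
    .is_silenced(state, ep$patient_id, ep$algorithm_id)
  state$notification_counter <- state$notification_counter + 1L
  state$notifications <- rbind(state$notifications, data.frame(
    notification_id = sprintf("N%06d", state$notification_counter),
    created_at = created_at, patient_id = ep$patient_id,
    case_id = ep$case_id, algorithm_id = ep$algorithm_id, kind = kind,
    severity = severity, message = message, dedup_key = dedup, arm = arm,
    suppressed = suppressed, trigger_measured_at = ep$trigger_result$measured_at,
    stringsAsFactors = FALSE))
  state
}

# severity of `r` under `rule`, given the engine history (AKI needs it)
.severity_for <- function(state, rule, r) {
  if (rule$kind == "aki") {
    hist <- state$history
    hist <- hist[hist$patient_id == r$patient_id &
                   hist$parameter == "CREATININE" &
                   hist$measured_at <= r$measured_at, , drop = FALSE]
    hist <- hist[order(hist$measured_at, hist$seq), , drop = FALSE]
    a <- classify_aki(hist[, c("measured_at", "value")])
    list(severity = severity_for_aki(a, state$config$aki_mapping),
         annotation = if (a$stage > 0) paste0("AKIN ", a$stage)
                      else NA_character_,
         assessment = a)
  } else {
    sev <- evaluate_threshold_rule(rule, r)
    list(severity = sev,
         annotation = if (sev == "RED") annotate_value(rule, r$value)
                      else NA_character_,
         assessment = NULL)
  }
}

.alert_message <- function(rule, r, info) {
  units <- stats::setNames(parameter_table()$canonical_units,
                           parameter_table()$code)
  extra <- if (!is.null(info$assessment)) {
    sprintf(" [AKIN %d, baseline %.1f]", info$assessment$stage,
            info$assessment$baseline_value)
  } else if (!is.na(info$annotation)) {
    sprintf(" [%s]", info$annotation)
  } else ""
  sprintf("%s: patient %s, %s = %g %s at %s%s",
          rule$diagnosis, r$patient_id, r$parameter, r$value,
          unname(units[r$parameter]),
          format(r$measured_at, "%Y-%m-%d %H:%M", tz = "UTC"), extra)
}

# core per-(patient, algorithm) transition for one result
.apply_result_to_key <- function(state, rule, r) {
  key <- .key(r$patient_id, rule$algorithm_id)
  info <- .severity_for(state, rule, r)
  ep <- state$open[[key]]
  if (!is.null(ep)) {
    # any subsequent watched measurement controls the open episode
    ep$controlled <- TRUE
    ep$control_result <- r
    state$closed[[length(state$closed) + 1L]] <- ep
    state$open[[key]] <- NULL
  }
  state$status[[key]] <- info$severity
  if (info$severity == "RED") {
    ne <- .new_episode(state, rule, r, "RED", info$annotation)
    state <- ne$state
    state$open[[key]] <- ne$episode
    state$acks[[r$patient_id]] <- NULL  # fresh critical clears the checkmark
    state <- .emit(state, "CRITICAL_VALUE", ne$episode, r$measured_at,
                   .alert_message(rule, r, info), "RED")
  }
  state
}

# rebuild one (patient, algorithm) lane from the sorted history, preserving
# already-emitted notifications (out-of-order correction path)
.rebuild_key <- function(state, rule, patient_id) {
  key <- .key(patient_id, rule$algorithm_id)
  state$open[[key]] <- NULL
  state$status[[key]] <- NULL
  state$closed <- Filter(function(e) {
    !(e$patient_id == patient_id && e$algorithm_id == rule$algorithm_id)
  }, state$closed)
  hist <- state$history
  lane <- hist[hist$patient_id == patient_id &
                 hist$parameter %in% rule$parameters, , drop = FALSE]
  lane <- lane[order(lane$measured_at, lane$seq), , drop = FALSE]
  for (i in seq_len(nrow(lane))) {
    r <- lane[i, , drop = FALSE]
    class(r) <- c("lab_result", "data.frame")
    state <- .apply_result_to_key(state, rule, r)
  }
  # an escalation already in the log marks the rebuilt episode escalated
  ep <- state$open[[key]]
  if (!is.null(ep)) {
    dedup <- paste(ep$patient_id, ep$algorithm_id,
                   format(ep$trigger_result$measured_at, "%Y%m%d%H%M%S"),
                   "TTC_OVERDUE", sep = "|")
    if (dedup %in% state$seen_notifications) {
      ep$escalated <- TRUE
      state$open[[key]] <- ep
    }
  }
  state
}

#' Ingest one laboratory result
#'
#' Appends the result to the history, re-evaluates every active rule set
#' watching its parameter, opens/controls episodes and emits notifications.
#' An exact duplicate (same patient, parameter, time, value) is a no-op, so
#' replayed or resubmitted messages cannot double-alert. A result older
#' than the retention horizon is rejected. Out-of-order arrivals trigger a
#' per-lane rebuild from the sorted history; already-emitted notifications
#' are never retracted, but a correcting audit event is recorded.
#'
#' @param state an `engine_state`.
#' @param result one-row `lab_result`.
#' @return list with `state` (updated) and `events` (data.frame of
#'   notifications emitted by this call).
#' @export
ingest <- function(state, result) {
  stopifnot(inherits(state, "engine_state"), nrow(result) == 1)
  validate_results(result,
                   ingest_clock = if (is.na(state$clock)) NULL
                                  else state$clock,
                   max_skew_hours = state$config$max_skew_hours)
  if (!is.na(state$clock) &&
      result$measured_at <
        state$clock - state$config$retention_days * 86400) {
    stop("result rejected: older than the ", state$config$retention_days,
         "-day retention horizon")
  }
  dedup <- paste(result$patient_id, result$parameter,
                 format(result$measured_at, "%Y%m%d%H%M%S"), result$value,
                 sep = "|")
  n_before <- nrow(state$notifications)
  if (dedup %in% state$seen_results) {
    return(list(state = state, events = .empty_notifications()))
  }
  state$seen_results <- c(state$seen_results, dedup)
  state$seq <- state$seq + 1L

  out_of_order <- any(state$history$parameter == result$parameter &
                        state$history$patient_id == result$patient_id &
                        state$history$measured_at > result$measured_at)
  state$history <- rbind(state$history, cbind(as.data.frame(result),
                                              seq = state$seq))
  ord <- order(state$history$measured_at, state$history$seq)
  state$history <- state$history[ord, , drop = FALSE]
  rownames(state$history) <- NULL
  state$clock <- max(state$clock, result$measured_at, na.rm = TRUE)

  for (rule in state$rules) {
    if (!rule$active || !result$parameter %in% rule$parameters) next
    if (out_of_order) {
      state <- .rebuild_key(state, rule, result$patient_id)
      state <- .audit(state, result$measured_at, "out_of_order_correction",
                      .key(result$patient_id, rule$algorithm_id))
    } else {
      state <- .apply_result_to_key(state, rule, result)
    }
  }
  events <- state$notifications[seq_len(nrow(state$notifications)) >
                                  n_before, , drop = FALSE]
  list(state = state, events = events)
}

#' Ingest a whole result set in timestamp order
#'
#' @param state an `engine_state`.
#' @param results `lab_result` data.frame.
#' @return list with `state` and `events` (all notifications emitted).
#' @export
process_results <- function(state, results) {
  events <- .empty_notifications()
  if (nrow(results) > 0) {
    ord <- order(results$measured_at)
    for (i in ord) {
      r <- results[i, , drop = FALSE]
      class(r) <- c("lab_result", "data.frame")
      step <- ingest(state, r)
      state <- step$state
      events <- rbind(events, step$events)
    }
  }
  list(state = state, events = events)
}

#' Advance the engine clock and fire due escalations
#'
#' For every open, uncontrolled, not-yet-escalated episode whose TTC
#' deadline is at or before `now`, exactly one TTC_OVERDUE notification is
#' emitted and the episode is marked escalated. Rules with immediate TTC
#' have no deadline and never escalate. Silenced and control-arm episodes
#' are marked escalated with a suppressed log entry, preserving the audit
#' trail without emitting to the output channel.
#'
#' @param state an `engine_state`.
#' @param now POSIXct; must not be before the engine clock.
#' @return list with `state` and `events` (escalation notifications).
#' @export
tick <- function(state, now) {
  now <- as.POSIXct(now, tz = "UTC")
  if (!is.na(state$clock) && now < state$clock) {
    stop("clock regression: tick at ", format(now), " before engine clock ",
         format(state$clock))
  }
  state$clock <- now
  n_before <- nrow(state$notifications)
  for (key in names(state$open)) {
    ep <- state$open[[key]]
    if (ep$escalated || is.na(ep$ttc_deadline) || ep$ttc_deadline > now) next
    rule <- state$rules[[ep$algorithm_id]]
    msg <- sprintf("%s: patient %s uncontrolled for >= %g h (trigger %s)",
                   rule$diagnosis, ep$patient_id, rule$ttc_hours,
                   format(ep$trigger_result$measured_at, "%Y-%m-%d %H:%M",
                          tz = "UTC"))
    state <- .emit(state, "TTC_OVERDUE", ep, now, msg, ep$severity)
    ep$escalated <- TRUE
    state$open[[key]] <- ep
  }
  events <- state$notifications[seq_len(nrow(state$notifications)) >
                                  n_before, , drop = FALSE]
  list(state = state, events = events)
}

#' Record a clinician acknowledgment (checkmark)
#'
#' Marks the patient as attended to. Colours are unchanged; the checkmark
#' is cleared again when a new critical trigger arrives for the patient.
#'
#' @param state an `engine_state`.
#' @param patient_id known patient.
#' @param actor who acknowledged.
#' @param at POSIXct acknowledgment time.
#' @return updated `engine_state`.
#' @export
acknowledge <- function(state, patient_id, actor, at) {
  if (!.patient_known(state, patient_id)) {
    stop("unknown patient: ", patient_id)
  }
  state$acks[[patient_id]] <- list(actor = actor,
                                   at = as.POSIXct(at, tz = "UTC"))
  .audit(state, as.POSIXct(at, tz = "UTC"), "acknowledge",
         paste(patient_id, actor, sep = "|"))
}

#' Silence or unsilence a patient or one of their algorithms
#'
#' Silenced lanes are still evaluated and logged (audit trail preserved,
#' display colour still computed) but emit nothing to the output channel.
#' Intended for, e.g., patients in palliative care.
#'
#' @param state an `engine_state`.
#' @param patient_id known patient.
#' @param algorithm_id algorithm id or "ALL".
#' @param flag TRUE to silence, FALSE to lift.
#' @return updated `engine_state`.
#' @export
set_silence <- function(state, patient_id, algorithm_id = "ALL",
                        flag = TRUE) {
  if (!.patient_known(state, patient_id)) {
    stop("unknown patient: ", patient_id)
  }
  if (!identical(algorithm_id, "ALL") &&
      !algorithm_id %in% names(state$rules)) {
    stop("unknown algorithm: ", algorithm_id)
  }
  key <- .key(patient_id, algorithm_id)
  if (flag) state$silenced <- union(state$silenced, key)
  else state$silenced <- setdiff(state$silenced, key)
  .audit(state, state$clock, if (flag) "silence" else "unsilence", key)
}

#' Summarize a patient's traffic-light state
#'
#' One status per active algorithm (GREEN when never evaluated); the
#' summary colour is the maximum severity under GREEN < YELLOW < RED.
#' Unknown patients yield an all-GREEN empty summary.
#'
#' @param state an `engine_state`.
#' @param patient_id patient identifier.
#' @return list with `patient_id`, `summary` (severity), `checkmark`,
#'   `statuses` (named severity vector per active algorithm), `silenced`
#'   (named logical vector).
#' @export
summarize_patient <- function(state, patient_id) {
  algs <- names(Filter(function(r) r$active, state$rules))
  statuses <- vapply(algs, function(a) {
    state$status[[.key(patient_id, a)]] %||% "GREEN"
  }, "")
  list(patient_id = patient_id,
       summary = severity_max(statuses),
       checkmark = !is.null(state$acks[[patient_id]]),
       statuses = statuses,
       silenced = vapply(algs, function(a) {
         .is_silenced(state, patient_id, a)
       }, TRUE))
}

#' Open (uncontrolled) episodes
#' @param state an `engine_state`.
#' @return list of open episode records.
#' @export
open_episodes <- function(state) unname(state$open)

#' All episodes ever opened, including controlled/closed ones
#' @param state an `engine_state`.
#' @return list of episode records (closed first, then open).
#' @export
all_episodes <- function(state) c(state$closed, unname(state$open))

#' The notification output channel
#'
#' Suppressed entries (control arm, silenced) are excluded; they remain in
#' `state$notifications` for audit.
#'
#' @param state an `engine_state`.
#' @param include_suppressed include suppressed audit entries.
#' @return notifications data.frame.
#' @export
notification_log <- function(state, include_suppressed = FALSE) {
  n <- state$notifications
  if (!include_suppressed) n <- n[!n$suppressed, , drop = FALSE]
  rownames(n) <- NULL
  n
}

#' @export
print.engine_state <- function(x, ...) {
  cat(sprintf(paste0("<engine_state> %d results, %d patients, %d open ",
                     "episodes, %d notifications (%d in channel)\n"),
              nrow(x$history), length(unique(x$history$patient_id)),
              length(x$open), nrow(x$notifications),
              sum(!x$notifications$suppressed)))
  invisible(x)
}
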