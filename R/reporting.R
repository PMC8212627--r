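#' Reporting: ward overview, patient reports, phone list, call records
#'
#' Pure renderings of the engine state (no mutation except
#' [record_call()]): a traffic-light ward overview with staleness
#' substitution, a per-patient per-algorithm report carrying the
#' research-use caveat, and the manual phone-list workflow with call
#' documentation and the two feedback questions ("Has the therapy started
#' (based on laboratory findings)?", "Do you think the notification helped
#' in treating the patient?").
#'
#' @name reporting
NULL

#' Default terminal poll interval in seconds
#' @export
DEFAULT_POLL_SECONDS <- 600

REPORT_CAVEAT <- paste("Automated analysis by an ongoing research project;",
                       "results should be used with caution.")

.empty_calls <- function() {
  data.frame(call_id = character(), notification_id = character(),
             call_time = as.POSIXct(character(), tz = "UTC"),
             phone_number = character(), callee_name = character(),
             therapy_started = character(),
             notification_helped = character(),
             stringsAsFactors = FALSE)
}

#' Render the ward overview
#'
#' One row per patient with the summary colour from [summarize_patient()]
#' and the checkmark. When the last successful refresh is older than
#' `stale_factor` times the poll interval the colour is substituted by
#' "STALE" (the display column stays empty on connection failure).
#'
#' @param state an `engine_state`.
#' @param patient_ids patients to list, in display order.
#' @param now POSIXct rendering time.
#' @param last_refresh POSIXct of the last successful terminal refresh
#'   (default `now`).
#' @param poll_seconds terminal poll interval (default 600 s).
#' @param stale_factor staleness threshold as a multiple of the poll
#'   interval (default 2).
#' @return data.frame with columns `patient_id`, `summary_color`,
#'   `checkmark`, `last_refresh`.
#' @export
render_ward_overview <- function(state, patient_ids, now,
                                 last_refresh = now,
                                 poll_seconds = DEFAULT_POLL_SECONDS,
                                 stale_factor = 2) {
  now <- as.POSIXct(now, tz = "UTC")
  stale <- as.numeric(now) - as.numeric(last_refresh) >
    stale_factor * poll_seconds
  rows <- lapply(patient_ids, function(p) {
    s <- summarize_patient(state, p)
    data.frame(patient_id = p,
               summary_color = if (stale) "STALE" else s$summary,
               checkmark = s$checkmark,
               last_refresh = as.POSIXct(last_refresh, tz = "UTC"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(list(data.frame(patient_id = character(),
                                          summary_color = character(),
                                          checkmark = logical(),
                                          last_refresh = as.POSIXct(character(), tz = "UTC"),
                                          stringsAsFactors = FALSE)), rows))
  rownames(out) <- NULL
  out
}

#' Render the full per-patient report
#'
#' One line per active algorithm with current severity, trigger value, TTC
#' status, diagnosis and silencing flag, plus the research-use caveat
#' banner. Unknown patients yield all-GREEN lines.
#'
#' @param state an `engine_state`.
#' @param patient_id patient identifier.
#' @return list with `patient_id`, `caveat`, `summary`, `checkmark`, and
#'   `lines` (data.frame: algorithm_id, diagnosis, severity, annotation,
#'   trigger_value, ttc_status, silenced, text).
#' @export
render_patient_report <- function(state, patient_id) {
  s <- summarize_patient(state, patient_id)
  algs <- names(s$statuses)
  lines <- do.call(rbind, lapply(algs, function(a) {
    rule <- state$rules[[a]]
    ep <- state$open[[.key(patient_id, a)]]
    sev <- s$statuses[[a]]
    trigger_value <- NA_real_
    annotation <- NA_character_
    ttc_status <- "-"
    if (!is.null(ep)) {
      trigger_value <- ep$trigger_result$value
      annotation <- ep$annotation
      ttc_status <- if (is.na(ep$ttc_deadline)) "immediate"
                    else if (ep$escalated) "overdue"
                    else paste0("due ", format(ep$ttc_deadline,
                                               "%Y-%m-%d %H:%M",
                                               tz = "UTC"))
    }
    text <- paste(c(rule$diagnosis,
                    if (!is.na(annotation)) annotation, sev),
                  collapse = " — ")
    data.frame(algorithm_id = a, diagnosis = rule$diagnosis,
               severity = sev, annotation = annotation,
               trigger_value = trigger_value, ttc_status = ttc_status,
               silenced = s$silenced[[a]], text = text,
               stringsAsFactors = FALSE)
  }))
  rownames(lines) <- NULL
  list(patient_id = patient_id, caveat = REPORT_CAVEAT,
       summary = s$summary, checkmark = s$checkmark, lines = lines)
}

#' Export the phone list
#'
#' All intervention-arm, unsuppressed notifications created at or after
#' `since` that have no call record yet, oldest first. Together with the
#' called set this partitions the output channel.
#'
#' @param state an `engine_state`.
#' @param since POSIXct lower bound (default: beginning of time).
#' @return data.frame with columns `notification_id`, `created_at`,
#'   `patient_id`, `algorithm_id`, `severity`, `kind`, `message`.
#' @export
export_phone_list <- function(state,
                              since = as.POSIXct("1970-01-01",
                                                 tz = "UTC")) {
  n <- notification_log(state, include_suppressed = FALSE)
  n <- n[n$arm == "INTERVENTION" & n$created_at >= since &
           !n$notification_id %in% state$calls$notification_id, ,
         drop = FALSE]
  n <- n[order(n$created_at, n$notification_id),
         c("notification_id", "created_at", "patient_id", "algorithm_id",
           "severity", "kind", "message"), drop = FALSE]
  rownames(n) <- NULL
  n
}

#' Document a notification phone call
#'
#' Records call time, phone number and callee plus the two feedback
#' answers, each of which may remain unanswered. A notification can be
#' called at most once; recording removes it from the phone list.
#'
#' @param state an `engine_state`.
#' @param notification_id id of an existing, not-yet-called notification.
#' @param call_time POSIXct.
#' @param phone_number,callee_name call documentation.
#' @param therapy_started,notification_helped TRUE/FALSE/NA (unanswered).
#' @return updated `engine_state`.
#' @export
record_call <- function(state, notification_id, call_time, phone_number,
                        callee_name, therapy_started = NA,
                        notification_helped = NA) {
  if (!notification_id %in% state$notifications$notification_id) {
    stop("unknown notification: ", notification_id)
  }
  if (notification_id %in% state$calls$notification_id) {
    stop("notification ", notification_id, " already has a call record")
  }
  tri <- function(x) if (is.na(x)) "unanswered" else
    if (isTRUE(x)) "yes" else "no"
  state$calls <- rbind(state$calls, data.frame(
    call_id = sprintf("C%06d", nrow(state$calls) + 1L),
    notification_id = notification_id,
    call_time = as.POSIXct(call_time, tz = "UTC"),
    phone_number = phone_number, callee_name = callee_name,
    therapy_started = tri(therapy_started),
    notification_helped = tri(notification_helped),
    stringsAsFactors = FALSE))
  .audit(state, as.POSIXct(call_time, tz = "UTC"), "call", notification_id)
}

#' Export the phone list or call log as CSV
#' @param state an `engine_state`.
#' @param path output path.
#' @param what "phone_list" or "calls".
#' @param since passed to [export_phone_list()].
#' @return `path`, invisibly.
#' @export
write_reporting_csv <- function(state, path, what = c("phone_list",
                                                      "calls"),
                                since = as.POSIXct("1970-01-01",
                                                   tz = "UTC")) {
  what <- match.arg(what)
  df <- if (what == "phone_list") export_phone_list(state, since)
        else state$calls
  tcol <- intersect(c("created_at", "call_time"), names(df))
  for (cc in tcol) df[[cc]] <- .iso(df[[cc]])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
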