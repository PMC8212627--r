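# shared fixtures and independent test oracles

T0 <- as.POSIXct("2021-03-01 08:00:00", tz = "UTC")

# a result `hours` after T0
res_at <- function(hours, patient, parameter, value,
                   case = paste0("C", patient),
                   order = sprintf("O%03d", as.integer(hours * 10) %% 1000),
                   units = "", source = "LAB") {
  lab_result(T0 + hours * 3600, patient, case, order, parameter, value,
             units, source)
}

# --- independent AKI oracle -------------------------------------------------
# brute force: enumerate every (prior point, criterion) pair instead of
# computing a single baseline/minimum up front
oracle_aki_stage <- function(values, hours) {
  n <- length(values)
  latest_v <- values[n]
  latest_h <- hours[n]
  stages <- 0L
  has_acute <- FALSE
  for (i in seq_len(n - 1)) {
    dt <- latest_h - hours[i]
    if (dt <= 0) next
    if (dt <= 48 && latest_v - values[i] >= 26.5) {
      stages <- c(stages, 1L)
      has_acute <- TRUE
    }
  }
  in7d <- which(hours[-n] >= latest_h - 7 * 24 & hours[-n] < latest_h)
  if (length(in7d) > 0) {
    b <- min(values[in7d])
    r <- latest_v / b
    if (r > 3.0) stages <- c(stages, 3L)
    else if (r > 2.0) stages <- c(stages, 2L)
    else if (r >= 1.5) stages <- c(stages, 1L)
  }
  if (latest_v >= 354 && has_acute) stages <- c(stages, 3L)
  max(stages)
}

aki_history <- function(values, hours) {
  data.frame(measured_at = T0 + hours * 3600, value = values)
}

# --- independent escalation oracle ------------------------------------------
# expected TTC_OVERDUE events computed directly from the result log and tick
# times, without the engine state machine: a critical result escalates iff
# the first tick at/after its deadline happens before the next measurement
# of the same (patient, parameter) lane (deadlines are sampled at ticks)
oracle_expected_escalations <- function(results, tick_times, rules) {
  out <- 0L
  for (rule in rules) {
    if (!rule$active || rule$kind != "threshold") next
    if (!is.numeric(rule$ttc_hours)) next
    for (p in rule$parameters) {
      lane_all <- results[results$parameter == p, , drop = FALSE]
      for (patient in unique(lane_all$patient_id)) {
        lane <- lane_all[lane_all$patient_id == patient, , drop = FALSE]
        lane <- lane[order(lane$measured_at), , drop = FALSE]
        for (j in seq_len(nrow(lane))) {
          r <- lane[j, , drop = FALSE]
          class(r) <- c("lab_result", "data.frame")
          if (evaluate_threshold_rule(rule, r) != "RED") next
          deadline <- r$measured_at + rule$ttc_hours * 3600
          due_ticks <- tick_times[tick_times >= deadline]
          if (length(due_ticks) == 0) next
          first_tick <- min(due_ticks)
          controlled_first <- j < nrow(lane) &&
            lane$measured_at[j + 1] < first_tick
          if (!controlled_first) out <- out + 1L
        }
      }
    }
  }
  out
}

# --- random small event streams for property tests --------------------------
random_stream <- function(seed) {
  set.seed(seed)
  n_pat <- sample(1:3, 1)
  patients <- sprintf("%d", sample(1000:1019, n_pat))
  params <- sample(c("K", "NA", "LACTATE", "CA_IONIZED"),
                   sample(1:3, 1))
  n_ev <- sample(5:12, 1)
  events <- list()
  t <- 0
  for (i in seq_len(n_ev)) {
    t <- t + stats::runif(1, 0.2, 5)
    if (stats::runif(1) < 0.25) {
      events[[length(events) + 1L]] <- event_tick(T0 + t * 3600)
    } else {
      p <- sample(params, 1)
      crit <- stats::runif(1) < 0.4
      v <- switch(p,
        K = if (crit) stats::runif(1, 1.6, 2.4) else
          stats::runif(1, 3.6, 4.8),
        `NA` = if (crit) stats::runif(1, 111, 119) else
          stats::runif(1, 136, 144),
        LACTATE = if (crit) stats::runif(1, 4.2, 9) else
          stats::runif(1, 0.6, 1.9),
        CA_IONIZED = if (crit) stats::runif(1, 2.05, 2.4) else
          stats::runif(1, 1.16, 1.29))
      pat <- sample(patients, 1)
      r <- lab_result(T0 + t * 3600, pat, paste0("C", pat),
                      sprintf("O%04d", i), p, round(v, 2), "", "LAB")
      events[[length(events) + 1L]] <- events_from_results(r)[[1]]
    }
  }
  # final tick so pending deadlines can fire
  events[[length(events) + 1L]] <- event_tick(T0 + (t + 13) * 3600)
  events
}

# comparable fingerprint of engine state for oracle-equivalence checks
state_fingerprint <- function(state) {
  list(
    notifications = notification_log(state, include_suppressed = TRUE),
    status = if (length(state$status) == 0) list()
             else state$status[order(names(state$status))],
    open_keys = sort(names(state$open)),
    escalated = sort(vapply(state$open, function(e) {
      paste(e$patient_id, e$algorithm_id, e$escalated)
    }, "")),
    n_closed = length(state$closed),
    history = state$history[, c("measured_at", "patient_id", "parameter",
                                "value")]
  )
}

# apply an event list incrementally (the non-replay route)
apply_incremental <- function(events, rules = build_default_rulesets(),
                              config = engine_config()) {
  state <- engine_new(rules, config)
  for (ev in events) {
    state <- switch(ev$type,
      result = ingest(state, lab_result(
        as.POSIXct(ev$measured_at, format = "%Y-%m-%dT%H:%M:%S",
                   tz = "UTC"),
        ev$patient_id, ev$case_id, ev$order_id, ev$parameter, ev$value,
        ev$units, ev$source))$state,
      tick = tick(state, as.POSIXct(ev$at, format = "%Y-%m-%dT%H:%M:%S",
                                    tz = "UTC"))$state,
      ack = acknowledge(state, ev$patient_id, ev$actor,
                        as.POSIXct(ev$at, tz = "UTC")),
      silence = set_silence(state, ev$patient_id, ev$algorithm_id,
                            isTRUE(ev$flag)))
  }
  state
}
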