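test_that("a critical result opens an episode and notifies", {
  st <- engine_new()
  # patient 1002: even trailing integer -> intervention arm
  step <- ingest(st, res_at(0, "1002", "K", 2.3))
  st <- step$state
  expect_equal(nrow(step$events), 1)
  expect_equal(step$events$kind, "CRITICAL_VALUE")
  expect_equal(step$events$severity, "RED")
  expect_false(step$events$suppressed)
  expect_length(open_episodes(st), 1)
  ep <- open_episodes(st)[[1]]
  expect_equal(ep$algorithm_id, "hypokalemia")
  expect_equal(ep$ttc_deadline, T0 + 6 * 3600)
  expect_false(ep$controlled)
  expect_equal(summarize_patient(st, "1002")$summary, "RED")
})

test_that("exact duplicates are a no-op (resubmission safety)", {
  st <- engine_new()
  r <- res_at(0, "1002", "K", 2.3)
  st <- ingest(st, r)$state
  fp <- state_fingerprint(st)
  step <- ingest(st, r)
  expect_equal(nrow(step$events), 0)
  expect_equal(state_fingerprint(step$state), fp)
})

test_that("a follow-up measurement controls the episode", {
  st <- engine_new()
  st <- ingest(st, res_at(0, "1002", "K", 2.3))$state
  st <- ingest(st, res_at(3, "1002", "K", 4.0))$state
  expect_length(open_episodes(st), 0)
  closed <- all_episodes(st)[[1]]
  expect_true(closed$controlled)
  expect_equal(closed$control_result$value, 4.0)
  expect_equal(summarize_patient(st, "1002")$summary, "GREEN")
  # no escalation ever fires
  step <- tick(st, T0 + 10 * 3600)
  expect_equal(nrow(step$events), 0)
})

test_that("a still-critical follow-up restarts the TTC clock", {
  st <- engine_new()
  st <- ingest(st, res_at(0, "1002", "K", 2.3))$state
  st <- ingest(st, res_at(3, "1002", "K", 2.2))$state
  expect_length(open_episodes(st), 1)
  ep <- open_episodes(st)[[1]]
  expect_equal(ep$trigger_result$value, 2.2)
  expect_equal(ep$ttc_deadline, T0 + 9 * 3600)  # 3 h trigger + 6 h TTC
  expect_equal(length(all_episodes(st)), 2)
  # the first episode was controlled (re-measured), archived
  expect_true(all_episodes(st)[[1]]$controlled)
})

test_that("escalation fires exactly at the deadline, once", {
  st <- engine_new()
  st <- ingest(st, res_at(0, "1002", "K", 2.3))$state
  step <- tick(st, T0 + 5 * 3600 + 59 * 60)
  expect_equal(nrow(step$events), 0)
  step <- tick(step$state, T0 + 6 * 3600)
  expect_equal(nrow(step$events), 1)
  expect_equal(step$events$kind, "TTC_OVERDUE")
  # never twice
  step2 <- tick(step$state, T0 + 20 * 3600)
  expect_equal(nrow(step2$events), 0)
  n <- notification_log(step2$state)
  expect_equal(sum(n$kind == "TTC_OVERDUE"), 1)
})

test_that("immediate-TTC rules never produce TTC_OVERDUE", {
  st <- engine_new()
  st <- ingest(st, res_at(0, "1002", "CREATININE", 100))$state
  st <- ingest(st, res_at(24, "1002", "CREATININE", 290))$state
  expect_length(open_episodes(st), 1)
  expect_true(is.na(open_episodes(st)[[1]]$ttc_deadline))
  step <- tick(st, T0 + 1000 * 3600)
  expect_equal(nrow(step$events), 0)
  n <- notification_log(step$state)
  expect_equal(unique(n$kind), "CRITICAL_VALUE")
})

test_that("AKI episodes carry the stage annotation", {
  st <- engine_new()
  st <- ingest(st, res_at(0, "1002", "CREATININE", 100))$state
  st <- ingest(st, res_at(24, "1002", "CREATININE", 210))$state  # ratio 2.1
  ep <- open_episodes(st)[[1]]
  expect_equal(ep$algorithm_id, "acute_kidney_injury")
  expect_equal(ep$annotation, "AKIN 2")
  expect_equal(summarize_patient(st, "1002")$statuses[["acute_kidney_injury"]],
               "RED")
})

test_that("clock regression is rejected", {
  st <- engine_new()
  st <- ingest(st, res_at(0, "1002", "K", 4))$state
  expect_error(tick(st, T0 - 3600), "clock regression")
})

test_that("stale results are rejected at the retention horizon", {
  st <- engine_new(config = engine_config(retention_days = 7))
  st <- ingest(st, res_at(0, "1002", "K", 4))$state
  expect_error(ingest(st, res_at(-8 * 24, "1002", "K", 4)),
               "retention")
})

test_that("acknowledgment sets the checkmark without changing colours", {
  st <- engine_new()
  st <- ingest(st, res_at(0, "1002", "K", 2.3))$state
  st <- acknowledge(st, "1002", "Dr A", T0 + 600)
  s <- summarize_patient(st, "1002")
  expect_true(s$checkmark)
  expect_equal(s$summary, "RED")
  # a new critical trigger clears the checkmark
  st <- ingest(st, res_at(2, "1002", "K", 2.1))$state
  expect_false(summarize_patient(st, "1002")$checkmark)
  # acknowledging an all-GREEN patient is recorded, colours untouched
  st2 <- engine_new()
  st2 <- ingest(st2, res_at(0, "1002", "K", 4.2))$state
  st2 <- acknowledge(st2, "1002", "Dr B", T0 + 60)
  s2 <- summarize_patient(st2, "1002")
  expect_true(s2$checkmark)
  expect_equal(s2$summary, "GREEN")
  expect_error(acknowledge(st2, "nobody", "x", T0), "unknown patient")
})

test_that("silencing suppresses the channel but keeps the audit trail", {
  st <- engine_new()
  st <- ingest(st, res_at(0, "1002", "K", 4.0))$state
  st <- set_silence(st, "1002", "ALL", TRUE)
  step <- ingest(st, res_at(1, "1002", "LACTATE", 6.0))
  st <- step$state
  expect_equal(nrow(step$events[!step$events$suppressed, ]), 0)
  expect_equal(nrow(notification_log(st)), 0)
  expect_equal(nrow(notification_log(st, include_suppressed = TRUE)), 1)
  expect_length(open_episodes(st), 1)  # episode still exists
  expect_equal(summarize_patient(st, "1002")$summary, "RED")  # colour kept

  # silencing one algorithm leaves the others audible
  st <- set_silence(st, "1002", "ALL", FALSE)
  st <- set_silence(st, "1002", "hypokalemia", TRUE)
  step <- ingest(st, res_at(2, "1002", "K", 2.0))
  expect_true(all(step$events$suppressed))
  step <- ingest(step$state, res_at(2.5, "1002", "NA", 112))
  expect_false(any(step$events$suppressed))
  st <- step$state

  # unsilencing restores notifications
  st <- set_silence(st, "1002", "hypokalemia", FALSE)
  st <- ingest(st, res_at(3, "1002", "K", 4.0))$state  # control old episode
  step <- ingest(st, res_at(4, "1002", "K", 2.0))
  expect_false(any(step$events$suppressed))

  expect_error(set_silence(st, "1002", "nonexistent", TRUE),
               "unknown algorithm")
  expect_error(set_silence(st, "nobody", "ALL", TRUE), "unknown patient")
})

test_that("control-arm episodes exist but never reach the channel", {
  st <- engine_new()
  # patient 1001: odd trailing integer -> control arm
  st <- ingest(st, res_at(0, "1001", "K", 2.3))$state
  st <- tick(st, T0 + 7 * 3600)$state
  expect_length(open_episodes(st), 1)
  expect_equal(nrow(notification_log(st)), 0)
  audit <- notification_log(st, include_suppressed = TRUE)
  expect_equal(nrow(audit), 2)  # critical + escalation, both suppressed
  expect_true(all(audit$arm == "CONTROL"))
  expect_true(all(audit$suppressed))

  # with suppression disabled both arms reach the channel
  st2 <- engine_new(config = engine_config(arm_suppression = FALSE))
  st2 <- ingest(st2, res_at(0, "1001", "K", 2.3))$state
  expect_equal(nrow(notification_log(st2)), 1)
})

test_that("patient summary follows the colour hierarchy", {
  st <- engine_new()
  st <- ingest(st, res_at(0, "1002", "K", 2.7))$state      # YELLOW
  expect_equal(summarize_patient(st, "1002")$summary, "YELLOW")
  st <- ingest(st, res_at(0.5, "1002", "LACTATE", 6))$state # RED
  expect_equal(summarize_patient(st, "1002")$summary, "RED")
  # unknown patient -> all-GREEN empty summary
  s <- summarize_patient(st, "ghost")
  expect_equal(s$summary, "GREEN")
  expect_false(s$checkmark)
  expect_true(all(s$statuses == "GREEN"))
})

test_that("out-of-order arrival converges to the sorted-log state", {
  mk <- function(hours, values) {
    lapply(seq_along(hours), function(i) {
      res_at(hours[i], "1002", "K", values[i],
             order = sprintf("O%02d", i))
    })
  }
  rs <- mk(c(0, 3, 5), c(2.3, 4.0, 2.2))
  in_order <- engine_new()
  for (r in rs) in_order <- ingest(in_order, r)$state
  shuffled <- engine_new()
  for (r in rs[c(1, 3, 2)]) shuffled <- ingest(shuffled, r)$state
  expect_equal(shuffled$status, in_order$status)
  expect_equal(sort(names(shuffled$open)), sort(names(in_order$open)))
  expect_equal(length(shuffled$closed), length(in_order$closed))
  # the correction is audited and notifications are never retracted
  expect_true("out_of_order_correction" %in% shuffled$audit$type)
  n1 <- notification_log(in_order, include_suppressed = TRUE)
  n2 <- notification_log(shuffled, include_suppressed = TRUE)
  expect_true(all(n1$dedup_key %in% n2$dedup_key))
})
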