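test_that("default rule sets match the published table", {
  rules <- build_default_rulesets()
  expect_length(rules, 7)
  active <- Filter(function(r) r$active, rules)
  expect_named(active, c("hypokalemia", "hypercalcemia", "hyponatremia",
                         "hyperlactatemia", "acute_kidney_injury"))
  expect_length(active, 5)

  hk <- rules$hypokalemia
  expect_equal(hk$critical$K, list(op = "<", threshold = 2.5))
  expect_equal(hk$ttc_hours, 6)
  expect_equal(hk$diagnosis, "Hypokalemia")

  hc <- rules$hypercalcemia
  expect_equal(hc$critical$CA_TOTAL, list(op = ">", threshold = 3.5))
  expect_equal(hc$critical$CA_IONIZED, list(op = ">", threshold = 2.0))
  expect_equal(hc$ttc_hours, 12)

  expect_equal(rules$hyponatremia$critical$`NA`,
               list(op = "<", threshold = 120))
  expect_equal(rules$hyponatremia$ttc_hours, 12)
  expect_equal(rules$hyperlactatemia$critical$LACTATE,
               list(op = ">", threshold = 4))
  expect_equal(rules$hyperlactatemia$ttc_hours, 6)

  expect_identical(rules$acute_kidney_injury$ttc_hours, "immediate")
  expect_false(rules$sepsis$active)
  expect_false(rules$myocardial_infarction$active)
})

test_that("threshold evaluation honours printed strict inequalities", {
  rules <- build_default_rulesets()
  ev <- function(rule, p, v) {
    evaluate_threshold_rule(rules[[rule]], res_at(0, "1002", p, v))
  }
  expect_equal(ev("hypokalemia", "K", 2.4), "RED")
  expect_false(ev("hypokalemia", "K", 2.5) == "RED")  # strict "<"
  expect_equal(ev("hypokalemia", "K", 2.5), "YELLOW")
  expect_equal(ev("hypercalcemia", "CA_IONIZED", 2.1), "RED")
  expect_equal(ev("hyponatremia", "NA", 140), "GREEN")

  # boundary sweep: severity flips exactly at the printed threshold
  eps <- 1e-9
  cases <- list(
    list("hypokalemia", "K", 2.5, "low"),
    list("hyponatremia", "NA", 120, "low"),
    list("hypercalcemia", "CA_TOTAL", 3.5, "high"),
    list("hypercalcemia", "CA_IONIZED", 2.0, "high"),
    list("hyperlactatemia", "LACTATE", 4, "high"))
  for (cs in cases) {
    thr <- cs[[3]]
    if (cs[[4]] == "low") {
      expect_equal(ev(cs[[1]], cs[[2]], thr - eps), "RED",
                   label = paste(cs[[1]], "below threshold"))
      expect_false(ev(cs[[1]], cs[[2]], thr) == "RED",
                   label = paste(cs[[1]], "at threshold"))
    } else {
      expect_equal(ev(cs[[1]], cs[[2]], thr + eps), "RED",
                   label = paste(cs[[1]], "above threshold"))
      expect_false(ev(cs[[1]], cs[[2]], thr) == "RED",
                   label = paste(cs[[1]], "at threshold"))
    }
  }
})

test_that("severity is monotone in extremity and rules are pure", {
  rules <- build_default_rulesets()
  set.seed(11)
  # hypokalemia / hyponatremia: non-increasing in the value
  for (cs in list(c("hypokalemia", "K", 1, 6),
                  c("hyponatremia", "NA", 100, 150))) {
    v <- sort(runif(50, as.numeric(cs[3]), as.numeric(cs[4])))
    sev <- vapply(v, function(x) severity_level(evaluate_threshold_rule(
      rules[[cs[1]]], res_at(0, "1002", cs[2], x))), 1L)
    expect_true(all(diff(sev) <= 0), label = cs[1])
  }
  # hypercalcemia / hyperlactatemia: non-decreasing
  for (cs in list(c("hypercalcemia", "CA_TOTAL", 2, 5),
                  c("hyperlactatemia", "LACTATE", 0.5, 10))) {
    v <- sort(runif(50, as.numeric(cs[3]), as.numeric(cs[4])))
    sev <- vapply(v, function(x) severity_level(evaluate_threshold_rule(
      rules[[cs[1]]], res_at(0, "1002", cs[2], x))), 1L)
    expect_true(all(diff(sev) >= 0), label = cs[1])
  }
  # purity: identical inputs, identical outputs
  r <- res_at(0, "1002", "K", 2.2)
  expect_identical(evaluate_threshold_rule(rules$hypokalemia, r),
                   evaluate_threshold_rule(rules$hypokalemia, r))
})

test_that("threshold evaluation rejects bad inputs", {
  rules <- build_default_rulesets()
  expect_error(evaluate_threshold_rule(rules$hypokalemia,
                                       res_at(0, "1002", "NA", 140)),
               "parameter mismatch")
  r <- res_at(0, "1002", "K", 3)
  r$value <- NaN
  expect_error(evaluate_threshold_rule(rules$hypokalemia, r), "finite")
  expect_error(evaluate_threshold_rule(rules$acute_kidney_injury,
                                       res_at(0, "1002", "CREATININE",
                                              100)),
               "not a simple threshold")
})

test_that("severe hypokalemia sub-bands annotate but never reclassify", {
  rules <- build_default_rulesets()
  expect_identical(annotate_value(rules$hypokalemia, 2.3), NA_character_)
  expect_identical(annotate_value(rules$hypokalemia, 2.0), "severe")
  expect_identical(annotate_value(rules$hypokalemia, 1.8),
                   "life_threatening")
  for (v in c(2.3, 2.0, 1.8)) {
    expect_equal(evaluate_threshold_rule(rules$hypokalemia,
                                         res_at(0, "1002", "K", v)), "RED")
  }
})

test_that("AKI staging reproduces the worked examples", {
  # ratio 1.6 after two days -> stage 1
  a <- classify_aki(aki_history(c(100, 160), c(0, 48)))
  expect_equal(a$stage, 1L)
  expect_equal(a$criterion, "RATIO")
  expect_equal(a$baseline_value, 100)

  # +30 umol/L within 36 h -> stage 1 by the 48-h delta
  a <- classify_aki(aki_history(c(80, 110), c(0, 36)))
  expect_equal(a$stage, 1L)
  expect_equal(a$criterion, "DELTA_48H")

  # ratio 3.1 -> stage 3
  a <- classify_aki(aki_history(c(100, 310), c(0, 72)))
  expect_equal(a$stage, 3L)
  expect_equal(a$criterion, "RATIO")

  # constant creatinine -> stage 0
  a <- classify_aki(aki_history(rep(90, 5), (0:4) * 24))
  expect_equal(a$stage, 0L)
  expect_equal(a$criterion, "NONE")

  # absolute criterion: >= 354 with an acute rise, ratio below 2
  a <- classify_aki(aki_history(c(300, 200, 360), c(-240, -24, 0)))
  expect_equal(a$stage, 3L)
  expect_equal(a$criterion, "ABSOLUTE")

  # first-ever value cannot trigger
  a <- classify_aki(aki_history(500, 0))
  expect_equal(a$stage, 0L)
  expect_equal(a$baseline_value, 500)

  expect_error(classify_aki(aki_history(numeric(), numeric())), "empty")
  expect_error(classify_aki(aki_history(c(100, -5), c(0, 24))), "> 0")
})

test_that("AKI staging agrees with the brute-force oracle", {
  set.seed(23)
  for (i in 1:300) {
    n <- sample(1:6, 1)
    hours <- sort(runif(n, 0, 10 * 24))
    values <- round(runif(n, 40, 420))
    a <- classify_aki(aki_history(values, hours))
    expect_equal(a$stage, oracle_aki_stage(values, hours),
                 label = sprintf("case %d (values %s, hours %s)", i,
                                 paste(values, collapse = ","),
                                 paste(round(hours), collapse = ",")))
  }
})

test_that("AKI stage maps to severity with a configurable mapping", {
  mk <- function(stage) structure(list(stage = stage), class = "aki_assessment")
  expect_equal(severity_for_aki(mk(0L)), "GREEN")
  expect_equal(severity_for_aki(mk(1L)), "YELLOW")
  expect_equal(severity_for_aki(mk(2L)), "RED")
  expect_equal(severity_for_aki(mk(3L)), "RED")
  strict <- c(`0` = "GREEN", `1` = "RED", `2` = "RED", `3` = "RED")
  expect_equal(severity_for_aki(mk(1L), strict), "RED")
})

test_that("rules round-trip through the config file format", {
  shipped <- system.file("extdata", "rules_default.yaml",
                         package = "labsentry")
  expect_equal(read_rules_config(shipped), build_default_rulesets())

  # a modified configuration survives write -> read, YAML and JSON alike
  rules <- build_default_rulesets()
  rules$hypokalemia$critical$K$threshold <- 2.2
  rules$hyperlactatemia$active <- FALSE
  for (ext in c("yaml", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_rules_config(rules, path)
    expect_equal(read_rules_config(path), rules, label = ext)
  }
})

test_that("severity helpers implement the colour hierarchy", {
  expect_equal(severity_max(c("RED", "GREEN", "GREEN")), "RED")
  expect_equal(severity_max(c("YELLOW", "GREEN")), "YELLOW")
  expect_equal(severity_max(character()), "GREEN")
  expect_error(severity_level("PURPLE"), "unknown severity")
})
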