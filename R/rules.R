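#' @title Critical-value rule sets
#' @description
#' A rule set ("algorithm") binds one or more laboratory parameters to a
#' critical predicate, an optional warning band, a time-to-control (TTC)
#' allowance, and a diagnosis label. Simple threshold rules are pure
#' value -> severity functions; the creatinine rule is a complex rule that
#' stages acute kidney injury from the patient's creatinine history.
#' @name rules
NULL

#' Construct a rule set
#'
#' @param algorithm_id short identifier, e.g. "hypokalemia".
#' @param kind "threshold", "aki" or "stub".
#' @param parameters character vector of parameter codes watched.
#' @param critical named list (by parameter code) of `list(op, threshold)`
#'   where `op` is "<" or ">" and thresholds are in canonical units.
#'   Disjunction over parameters: any satisfied predicate is critical.
#' @param warning named list (by parameter code) of `c(lo, hi)` bands in
#'   canonical units, adjacent to the critical threshold on the safe side.
#'   Warning bands are a local configuration default, not part of the
#'   published rule table; they are fully overridable.
#' @param ttc_hours numeric hours, or the string "immediate" for rules whose
#'   critical notification is the terminal event (no escalation timer).
#' @param diagnosis diagnosis label documented on alerts.
#' @param active whether the rule is evaluated.
#' @param annotations optional named numeric vector of sub-band thresholds
#'   annotated on alerts (e.g. severe hypokalemia at <= 2.0 mmol/L); these
#'   never change the severity level.
#' @return object of class `lab_rule`.
#' @export
rule_set <- function(algorithm_id, kind, parameters, critical = list(),
                     warning = list(), ttc_hours = "immediate",
                     diagnosis = algorithm_id, active = TRUE,
                     annotations = NULL) {
  stopifnot(kind %in% c("threshold", "aki", "stub"))
  if (!identical(ttc_hours, "immediate")) {
    stopifnot(is.numeric(ttc_hours), ttc_hours > 0)
  }
  if (kind == "threshold") {
    stopifnot(length(critical) > 0,
              all(names(critical) %in% parameters))
    for (p in names(warning)) {
      cr <- critical[[p]]
      wb <- warning[[p]]
      stopifnot(length(wb) == 2, wb[1] < wb[2])
      # critical must be strictly more extreme than the warning band
      if (cr$op == "<") stopifnot(wb[1] >= cr$threshold)
      if (cr$op == ">") stopifnot(wb[2] <= cr$threshold)
    }
  }
  structure(
    list(algorithm_id = algorithm_id, kind = kind, parameters = parameters,
         critical = critical, warning = warning, ttc_hours = ttc_hours,
         diagnosis = diagnosis, active = active, annotations = annotations),
    class = "lab_rule"
  )
}

#' @export
print.lab_rule <- function(x, ...) {
  ttc <- if (identical(x$ttc_hours, "immediate")) "immediate"
         else paste0(x$ttc_hours, " h")
  cat(sprintf("<lab_rule> %s [%s]%s: %s; TTC %s; %s\n",
              x$algorithm_id, paste(x$parameters, collapse = ","),
              if (x$active) "" else " (inactive)",
              if (x$kind == "threshold") {
                paste(vapply(names(x$critical), function(p) {
                  sprintf("%s %s %g", p, x$critical[[p]]$op,
                          x$critical[[p]]$threshold)
                }, ""), collapse = " or ")
              } else x$kind,
              ttc, x$diagnosis))
  invisible(x)
}

#' Default rule sets
#'
#' The shipped configuration: five active algorithms (hypokalemia,
#' hypercalcemia, hyponatremia, hyperlactatemia, acute kidney injury) and
#' two inactive prerelease stubs (sepsis/procalcitonin, myocardial
#' infarction/troponin T, no rule logic published). Thresholds and TTC:
#' K < 2.5 mmol/L (6 h); total Ca > 3.5 or ionized Ca > 2.0 mmol/L (12 h);
#' Na < 120 mmol/L (12 h); lactate > 4 mmol/L (6 h); creatinine complex
#' staging, immediate. Warning bands are non-published local defaults.
#'
#' @return named, ordered list of `lab_rule` objects.
#' @export
build_default_rulesets <- function() {
  rules <- list(
    hypokalemia = rule_set(
      "hypokalemia", "threshold", "K",
      critical = list(K = list(op = "<", threshold = 2.5)),
      warning = list(K = c(2.5, 3.0)),
      ttc_hours = 6, diagnosis = "Hypokalemia",
      annotations = c(severe = 2.0, life_threatening = 1.9)
    ),
    hypercalcemia = rule_set(
      "hypercalcemia", "threshold", c("CA_TOTAL", "CA_IONIZED"),
      critical = list(CA_TOTAL = list(op = ">", threshold = 3.5),
                      CA_IONIZED = list(op = ">", threshold = 2.0)),
      warning = list(CA_TOTAL = c(3.0, 3.5), CA_IONIZED = c(1.6, 2.0)),
      ttc_hours = 12, diagnosis = "Hypercalcemia"
    ),
    hyponatremia = rule_set(
      "hyponatremia", "threshold", "NA",
      critical = list(`NA` = list(op = "<", threshold = 120)),
      warning = list(`NA` = c(120, 125)),
      ttc_hours = 12, diagnosis = "Hyponatremia"
    ),
    hyperlactatemia = rule_set(
      "hyperlactatemia", "threshold", "LACTATE",
      critical = list(LACTATE = list(op = ">", threshold = 4)),
      warning = list(LACTATE = c(2.5, 4)),
      ttc_hours = 6, diagnosis = "Hyperlactatemia"
    ),
    acute_kidney_injury = rule_set(
      "acute_kidney_injury", "aki", "CREATININE",
      ttc_hours = "immediate", diagnosis = "Acute kidney injury"
    ),
    sepsis = rule_set(
      "sepsis", "stub", "PCT", ttc_hours = "immediate",
      diagnosis = "Sepsis", active = FALSE
    ),
    myocardial_infarction = rule_set(
      "myocardial_infarction", "stub", "TROPONIN_T",
      ttc_hours = "immediate", diagnosis = "Myocardial infarction",
      active = FALSE
    )
  )
  rules
}

#' Evaluate a simple threshold rule on one result
#'
#' RED if the critical predicate holds, YELLOW if only the warning band
#' holds, GREEN otherwise. Inequalities are strict exactly as printed in the
#' rule table; the warning band is closed on the critical-threshold side so
#' a boundary value (e.g. K = 2.5) is YELLOW, never RED.
#'
#' @param rule a threshold `lab_rule`.
#' @param result a `lab_result` (see [lab_result()]), value in canonical
#'   units.
#' @return severity string.
#' @export
evaluate_threshold_rule <- function(rule, result) {
  if (rule$kind != "threshold") {
    stop("evaluate_threshold_rule: rule '", rule$algorithm_id,
         "' is not a simple threshold rule")
  }
  p <- result$parameter
  if (!p %in% rule$parameters) {
    stop("parameter mismatch: rule '", rule$algorithm_id,
         "' does not watch ", p)
  }
  v <- result$value
  if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
    stop("invalid result value for ", p, ": must be a finite number")
  }
  cr <- rule$critical[[p]]
  critical <- switch(cr$op,
                     "<" = v < cr$threshold,
                     ">" = v > cr$threshold,
                     stop("unknown comparator: ", cr$op))
  if (critical) return("RED")
  wb <- rule$warning[[p]]
  if (!is.null(wb)) {
    in_warning <- if (cr$op == "<") (v >= wb[1] && v < wb[2])
                  else              (v > wb[1] && v <= wb[2])
    if (in_warning) return("YELLOW")
  }
  "GREEN"
}

#' Sub-band annotation for a critical value
#'
#' Returns the most extreme matching annotation label (e.g.
#' "life_threatening" for K <= 1.9 mmol/L), or NA. Annotations ride on the
#' alert; they do not alter the three-level severity.
#'
#' @param rule a `lab_rule` with annotations.
#' @param value numeric value in canonical units.
#' @return annotation label or NA_character_.
#' @export
annotate_value <- function(rule, value) {
  ann <- rule$annotations
  if (is.null(ann)) return(NA_character_)
  hit <- ann[value <= ann]
  if (length(hit) == 0) return(NA_character_)
  names(hit)[which.min(hit)]
}

# ---- acute kidney injury staging ------------------------------------------

AKI_DELTA_UMOL <- 26.5      # 0.3 mg/dL rise within 48 h
AKI_RATIO_STAGE1 <- 1.5
AKI_RATIO_STAGE2 <- 2.0
AKI_RATIO_STAGE3 <- 3.0
AKI_ABSOLUTE_UMOL <- 354    # 4 mg/dL with an acute rise
AKI_BASELINE_DAYS <- 7

#' Stage acute kidney injury from a creatinine history
#'
#' Staging from the latest creatinine relative to a short-horizon baseline:
#' baseline is the minimum value in the 7 days preceding the latest result
#' (latest excluded). A first-ever value has no baseline and cannot trigger.
#' Stage >= 1 if the rise within 48 h is >= 26.5 umol/L or latest/baseline
#' >= 1.5; stage >= 2 if the ratio exceeds 2.0; stage 3 if the ratio exceeds
#' 3.0 or latest >= 354 umol/L with an acute 48-h rise >= 26.5 umol/L.
#'
#' @param history data.frame with columns `measured_at` (POSIXct, ascending)
#'   and `value` (umol/L, > 0).
#' @param now clock timestamp; results after `now` are ignored.
#' @return object of class `aki_assessment`: list with `stage` (0-3),
#'   `baseline_value`, `trigger_value`, `criterion` (one of NONE, DELTA_48H,
#'   RATIO, ABSOLUTE).
#' @export
classify_aki <- function(history, now = NULL) {
  if (is.null(history) || nrow(history) == 0) {
    stop("classify_aki: empty creatinine history")
  }
  stopifnot(all(c("measured_at", "value") %in% names(history)))
  if (any(!is.finite(history$value)) || any(history$value <= 0)) {
    stop("classify_aki: creatinine values must be finite and > 0")
  }
  if (is.unsorted(as.numeric(history$measured_at))) {
    stop("classify_aki: history timestamps must be ascending")
  }
  if (!is.null(now)) {
    history <- history[history$measured_at <= now, , drop = FALSE]
    if (nrow(history) == 0) stop("classify_aki: empty creatinine history")
  }
  n <- nrow(history)
  latest_t <- history$measured_at[n]
  latest_v <- history$value[n]

  prior <- history[-n, , drop = FALSE]
  base_win <- prior[prior$measured_at >= latest_t - AKI_BASELINE_DAYS * 86400 &
                    prior$measured_at < latest_t, , drop = FALSE]
  if (nrow(base_win) == 0) {
    return(structure(list(stage = 0L, baseline_value = latest_v,
                          trigger_value = latest_v, criterion = "NONE"),
                     class = "aki_assessment"))
  }
  baseline <- min(base_win$value)

  win48 <- prior[prior$measured_at >= latest_t - 48 * 3600 &
                 prior$measured_at < latest_t, , drop = FALSE]
  delta48 <- if (nrow(win48) > 0) latest_v - min(win48$value) else -Inf
  acute_rise <- delta48 >= AKI_DELTA_UMOL

  ratio <- latest_v / baseline
  stage_ratio <- if (ratio > AKI_RATIO_STAGE3) 3L
                 else if (ratio > AKI_RATIO_STAGE2) 2L
                 else if (ratio >= AKI_RATIO_STAGE1) 1L
                 else 0L
  stage_delta <- if (acute_rise) 1L else 0L
  stage_abs <- if (latest_v >= AKI_ABSOLUTE_UMOL && acute_rise) 3L else 0L

  stage <- max(stage_ratio, stage_delta, stage_abs)
  criterion <- if (stage == 0L) "NONE"
               else if (stage_ratio == stage) "RATIO"
               else if (stage_abs == stage) "ABSOLUTE"
               else "DELTA_48H"
  structure(list(stage = stage, baseline_value = baseline,
                 trigger_value = latest_v, criterion = criterion),
            class = "aki_assessment")
}

#' Map an AKI stage to a traffic-light severity
#'
#' Default mapping: stage 0 GREEN, stage 1 YELLOW, stages 2-3 RED (a full
#' alert report is raised at stage 2).
#'
#' @param assessment an `aki_assessment`.
#' @param mapping named character vector keyed by stage "0".."3".
#' @return severity string.
#' @export
severity_for_aki <- function(assessment,
                             mapping = c(`0` = "GREEN", `1` = "YELLOW",
                                         `2` = "RED", `3` = "RED")) {
  sev <- unname(mapping[as.character(assessment$stage)])
  if (is.na(sev)) stop("no severity mapping for stage ", assessment$stage)
  sev
}
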