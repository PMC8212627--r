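---
title: "Critical-value surveillance: model, rules and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Critical-value surveillance: model, rules and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(labsentry)
```

## The problem

Laboratory results are among the most standardized and consequential inputs
to clinical decision making, but the interval between a result becoming
available and a clinician acting on it is a real patient-safety risk: a
potassium of 2.0 mmol/L that nobody re-checks for hours carries a
documented risk of fatal arrhythmia. labsentry implements a laboratory
clinical decision support engine for this problem: it watches a stream of
results, classifies each patient into a traffic-light state, and escalates
when a critical finding goes unchecked past its *time to control* (TTC) —
the maximum interval within which a critical value must be re-measured.

The package is self-contained: it has no hospital-system integration and
instead consumes simplified HL7 v2 ORU^R01 messages, a CSV fixture format,
or the output of a built-in seeded ward simulator.

## The rule model

A *rule set* (one "algorithm") binds parameters to a critical predicate,
an optional warning band, a TTC and a diagnosis label. The five shipped
active algorithms are:

| Algorithm | Critical predicate | TTC | Severity source |
|---|---|---|---|
| hypokalemia | K < 2.5 mmol/L | 6 h | threshold |
| hypercalcemia | total Ca > 3.5 or ionized Ca > 2.0 mmol/L | 12 h | threshold |
| hyponatremia | Na < 120 mmol/L | 12 h | threshold |
| hyperlactatemia | lactate > 4 mmol/L | 6 h | threshold |
| acute kidney injury | creatinine staging (below) | immediate | complex |

Two further algorithms (sepsis/procalcitonin, myocardial
infarction/troponin T) ship as inactive stubs: they are listed in the rule
table but no rule logic for them is published, so they are declared and
never evaluated.

Inequalities are strict exactly as printed: K = 2.5 mmol/L is *not*
critical. Severities form the total order GREEN < YELLOW < RED and a
patient's summary colour is the maximum over their per-algorithm statuses
(one RED makes the patient RED; otherwise one YELLOW makes them YELLOW).

**Warning (YELLOW) bands are a local default, not published rules.** The
source rule table defines only critical thresholds; the shipped bands
(K 2.5–3.0, Na 120–125, total Ca 3.0–3.5, ionized Ca 1.6–2.0, lactate
2.5–4.0 mmol/L) are conventional near-critical ranges, flagged as such in
the config file and fully overridable. The band is closed on the
critical-threshold side, so a boundary value is YELLOW, never RED.

The sub-bands of severe (≤ 2.0 mmol/L) and acutely life-threatening
(≤ 1.9 mmol/L) hypokalemia are recorded as *annotations* on the alert, not
extra severity levels: the published system has exactly three colours, and
how the finer potassium grades alter behaviour is not specified.

## Acute kidney injury staging

The creatinine algorithm is published only as a "complex rule set" whose
report screenshots name AKIN stages, so this package implements AKIN-style
staging as a documented stand-in:

* **Baseline**: the minimum creatinine in the 7 days preceding the latest
  result, the latest result excluded. A first-ever value has no baseline
  and cannot trigger — a deliberately conservative choice that avoids
  alerting on stable chronic elevation.
* **Stage 1**: rise ≥ 26.5 µmol/L (0.3 mg/dL) within 48 h, or
  latest/baseline ≥ 1.5.
* **Stage 2**: ratio > 2.0. **Stage 3**: ratio > 3.0, or latest
  ≥ 354 µmol/L (4 mg/dL) together with an acute 48-h rise ≥ 26.5 µmol/L.
* Severity mapping (configurable): stage 0 GREEN, stage 1 YELLOW,
  stages 2–3 RED.

Creatinine is carried in µmol/L; mg/dL input is converted at ingest with
the factor 88.4. Unit conversion happens only at ingest — rules never see
non-canonical units.

## Episode semantics and escalation

A RED finding opens an *episode* carrying the trigger result and, for
non-immediate rules, a TTC deadline of trigger time + TTC. The engine's
transitions:

* **Control** = any subsequent measurement of a watched parameter for the
  same patient and algorithm — re-measurement, not normalization, because
  the escalation question is "has this been checked", not "has it
  resolved".
* A controlled episode closes. If the controlling value is itself
  critical, a fresh episode opens with a fresh TTC clock.
* `tick(now)` fires exactly one TTC_OVERDUE per open episode whose
  deadline has passed, on the first tick at or after the deadline.
  Immediate-TTC rules (creatinine) have no deadline and never escalate:
  the critical notification is their terminal event.
* Exact duplicates (same patient, parameter, time, value) are no-ops, so
  the documented failure mode of communication servers resubmitting a full
  previous day of messages cannot double-alert.
* Out-of-order arrivals trigger a per-lane rebuild from the sorted
  history; emitted notifications are never retracted (append-only log) but
  a correcting audit event is recorded.

Acknowledgment (the clinician checkmark) is per patient and clears when a
new critical trigger arrives. Silencing — intended for palliative care —
may target one algorithm or the whole patient; silenced lanes are still
evaluated, coloured and audited but emit nothing to the output channel.
During replay of a persisted event log, a tick older than the engine clock
is treated as a no-op rather than a clock regression: everything due at
that time has already been processed, which is what makes a log with a
duplicated suffix replay to the identical state.

## Trial arms

Patients are assigned by ID parity: odd trailing integer = control, even =
intervention. Both arms are fully evaluated, but control-arm notifications
are suppressed from the output channel (phone list) while remaining in the
audit log — the design that lets the deployment quantify its own benefit.
Non-numeric IDs are hashed to an integer with a stable 31-ary polynomial
hash first; the published design covers numeric IDs only.

## Latency model

End-to-end delay is modelled as a chain of polling hops with maxima
15 min (communication server), 60 min (warehouse database poll) and 10 min
(terminal refresh), giving an 85-minute worst case. The ward terminal
polls every 600 s; an overview column goes STALE (empty) when the last
refresh is older than twice the poll interval — the 2× factor is this
package's choice, since the source only states that the column remains
empty on connection failure.

`attribute_delay()` implements the checkbox protocol: per-hop timestamps
are differenced, hops exceeding their configured maximum are flagged, and
the dominant component is the largest lag (ties to the earliest hop). A
fourth, engine-internal interval (engine to notification) defaults to a
0-minute allowance, so any positive engine-internal lag is flagged — both
timestamps are assigned by the same component, so lag between them is
never polling.

`simulate_polling_delay()` draws each hop uniformly on [0, max] — the
phase of a measurement within a polling cycle is uniform — so the
end-to-end mean converges to half the worst case (42.5 min at defaults).
The separately reported ~36-minute mean *operational* notification time
mixes machine and human latency and is deliberately not a target of this
model.

## The simulator: what it emulates, and what not

`simulate_stream()` generates per-patient, per-parameter Poisson
measurement schedules (default 2/day over 7 days for 20 patients), makes
each scheduled measurement critical with probability
`critical_prevalence` (default 0.05), and schedules a follow-up after each
critical value with a log-normal clinician response delay: control median
4 h, intervention median 1.5 h, sdlog 0.5. Values are uniform within
reference intervals (normal) or within a bounded critical band (critical);
critical creatinine is generated as a 2.2–3.5× rise over the previous
value, since the AKI rule is history-based. Follow-up results carry an
"F"-prefixed order ID so parameter-recovery tests can separate scheduled
Bernoulli draws from response measurements.

Defaults that are *stated* upstream: the parity arm split, the direction
of the arm effect (the notified arm responds faster — reported only
qualitatively, so no magnitude is asserted). Defaults that are this
package's modelling choices, chosen once as clinically plausible:
measurement rate, prevalence, the log-normal response-delay family and its
medians, uniform value bands.

What the simulator does **not** emulate: circadian ordering patterns,
correlated multi-analyte panels, analytic error and repeat-on-delta
policies, ward transfers, or any published effect size. A green simulator
test therefore establishes internal consistency (parameter recovery,
determinism, effect direction), not clinical performance.

## Numerical and design choices

* Timestamps are zone-naive wall-clock, stored as UTC; HL7 TS format
  `YYYYMMDDHHMMSS`; ordering ties broken by ingest sequence.
* Severity boundary behaviour is exact (strict `<`/`>` as printed), tested
  by ±1e-9 sweeps and bisection to 60 iterations.
* The engine clock is monotone; direct `tick()` calls into the past are
  errors (replay is the sanctioned path for stale events).
* Episode identity for deduplication is (patient, algorithm, trigger time,
  notification kind); at most one notification ever exists per identity.
* Hypercalcemia is one algorithm over two parameters; either parameter can
  trigger or control the single episode lane.
* Rule configuration is YAML (JSON accepted); the shipped
  `rules_default.yaml` reproduces the built-in defaults bit-exactly and is
  the template for local overrides.

## Known limitations

* The AKI implementation is a stand-in for an unpublished production rule
  set; staging thresholds follow the AKIN convention.
* Whether a YELLOW state alone should ever produce a phone-list item is
  unspecified upstream; labsentry emits none.
* The checkmark is per patient (per-algorithm acknowledgment is not
  modelled beyond clearing on new triggers).
* No persistence beyond flat files, no transport (MLLP/HTTP), no GUI.

## A worked example

```{r example, eval = FALSE}
st <- engine_new()
st <- ingest(st, lab_result("2021-03-01 08:00:00", "1002", "C1002", "O1",
                            "K", 2.3, "mmol/L"))$state
tick(st, as.POSIXct("2021-03-01 14:00:00", tz = "UTC"))$events$message
#> "Hypokalemia: patient 1002 uncontrolled for >= 6 h (trigger 2021-03-01 08:00)"
summarize_patient(st, "1002")$summary
#> "RED"
```
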