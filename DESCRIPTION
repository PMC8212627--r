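Package: labsentry
Title: Rule-Based Critical-Value Surveillance for Laboratory Results
Version: 0.1.0
Authors@R:
    person("labsentry", "Maintainers", email = "maintainers@labsentry.invalid",
           role = c("aut", "cre"))
Description: A self-contained clinical decision support engine for laboratory
    diagnostics. Consumes streams of laboratory results (simplified HL7 v2
    ORU^R01 messages, CSV fixtures, or a built-in seeded ward simulator),
    applies explicit critical-value rule sets with time-to-control escalation
    timers, maintains traffic-light patient states with acknowledgment and
    silencing, and emits auditable notifications, phone lists, and ward
    overview reports. Includes acute-kidney-injury staging from creatinine
    histories, a dataflow-hop latency model with per-hop delay attribution,
    and per-arm time-to-control outcome statistics for control/intervention
    trial designs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
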