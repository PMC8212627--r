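#' Read a rule configuration file
#'
#' Rules are configured as a YAML (or JSON) document with one entry per
#' algorithm: `algorithm_id`, `rule` ("threshold", "AKIN" or "stub"),
#' `parameters`, `critical` (list of parameter/op/threshold/units),
#' optional `warning` bands, `ttc_hours` (number or "immediate"),
#' `diagnosis`, `active`, optional `annotations`. The shipped default file
#' (`system.file("extdata", "rules_default.yaml", package = "labsentry")`)
#' reproduces [build_default_rulesets()] exactly.
#'
#' @param path path to a .yaml/.yml or .json rules file.
#' @return named list of `lab_rule` objects, in file order.
#' @export
read_rules_config <- function(path) {
  if (!file.exists(path)) stop("rules file not found: ", path)
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  entries <- doc$rules
  if (is.null(entries)) stop("rules file has no top-level 'rules' key: ", path)
  rules <- lapply(entries, .rule_from_entry)
  names(rules) <- vapply(rules, function(r) r$algorithm_id, "")
  rules
}

.rule_from_entry <- function(e) {
  kind <- switch(tolower(e$rule %||% "threshold"),
                 threshold = "threshold", akin = "aki", aki = "aki",
                 stub = "stub",
                 stop("unknown rule kind: ", e$rule))
  critical <- list()
  for (cr in e$critical %||% list()) {
    critical[[cr$parameter]] <- list(op = cr$op,
                                     threshold = as.numeric(cr$threshold))
  }
  warning_bands <- list()
  for (wb in e$warning %||% list()) {
    warning_bands[[wb$parameter]] <- c(as.numeric(wb$lo), as.numeric(wb$hi))
  }
  ann <- NULL
  if (!is.null(e$annotations)) {
    ann <- unlist(e$annotations)
    storage.mode(ann) <- "double"
  }
  ttc <- e$ttc_hours
  if (!identical(ttc, "immediate")) ttc <- as.numeric(ttc)
  rule_set(e$algorithm_id, kind,
           parameters = as.character(unlist(e$parameters)),
           critical = critical, warning = warning_bands,
           ttc_hours = ttc, diagnosis = e$diagnosis %||% e$algorithm_id,
           active = isTRUE(e$active %||% TRUE), annotations = ann)
}

#' Write a rule configuration file
#'
#' Inverse of [read_rules_config()]: `read_rules_config(write_rules_config(r,
#' p))` reproduces `r`.
#'
#' @param rules named list of `lab_rule` objects.
#' @param path output path (.yaml or .json decides the format).
#' @return `path`, invisibly.
#' @export
write_rules_config <- function(rules, path) {
  param_units <- stats::setNames(parameter_table()$canonical_units,
                                 parameter_table()$code)
  entries <- lapply(rules, function(r) {
    e <- list(algorithm_id = r$algorithm_id,
              rule = if (r$kind == "aki") "AKIN" else r$kind,
              parameters = as.list(r$parameters))
    if (length(r$critical) > 0) {
      e$critical <- lapply(names(r$critical), function(p) {
        list(parameter = p, op = r$critical[[p]]$op,
             threshold = r$critical[[p]]$threshold,
             units = unname(param_units[p]))
      })
    }
    if (length(r$warning) > 0) {
      e$warning <- lapply(names(r$warning), function(p) {
        list(parameter = p, lo = r$warning[[p]][1], hi = r$warning[[p]][2])
      })
    }
    e$ttc_hours <- r$ttc_hours
    e$diagnosis <- r$diagnosis
    e$active <- r$active
    if (!is.null(r$annotations)) e$annotations <- as.list(r$annotations)
    e
  })
  doc <- list(rules = unname(entries))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(doc, path)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
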