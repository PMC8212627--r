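#' Laboratory result records
#'
#' A `LabResult` is one timestamped measurement of one parameter for one
#' patient/case/order. Results are represented as rows of a data.frame with
#' the six core fields (measurement time, patient ID, case ID, order ID,
#' parameter, result value) plus the units as received and the source
#' channel. Values are stored in canonical units (see [parameter_table()]).
#'
#' @param measured_at POSIXct measurement time.
#' @param patient_id,case_id,order_id non-empty identifiers.
#' @param parameter canonical parameter code.
#' @param value numeric value in canonical units.
#' @param raw_units unit string as received.
#' @param source one of "LAB", "POCT", "SIMULATED".
#' @return one-row data.frame of class `lab_result`.
#' @export
lab_result <- function(measured_at, patient_id, case_id, order_id,
                       parameter, value, raw_units = "",
                       source = "LAB") {
  df <- data.frame(
    measured_at = as.POSIXct(measured_at, tz = "UTC"),
    patient_id = as.character(patient_id),
    case_id = as.character(case_id),
    order_id = as.character(order_id),
    parameter = as.character(parameter),
    value = as.numeric(value),
    raw_units = as.character(raw_units),
    source = as.character(source),
    stringsAsFactors = FALSE
  )
  class(df) <- c("lab_result", "data.frame")
  df
}

#' Empty result set with the canonical column layout
#' @return zero-row results data.frame.
#' @export
empty_results <- function() {
  lab_result(as.POSIXct(character(), tz = "UTC"), character(), character(),
             character(), character(), numeric(), character(), character())
}

#' Bind result rows
#' @param ... `lab_result` data.frames.
#' @return combined results data.frame.
#' @export
bind_results <- function(...) {
  out <- do.call(rbind, lapply(list(...), as.data.frame))
  rownames(out) <- NULL
  class(out) <- c("lab_result", "data.frame")
  out
}

#' Validate a result set
#'
#' Checks the record invariants: parseable timestamps not further in the
#' future than the allowed clock skew, non-empty patient/case/order
#' identifiers, known parameter codes, finite positive values.
#'
#' @param results results data.frame.
#' @param ingest_clock optional POSIXct; when given, results more than
#'   `max_skew_hours` ahead of it are rejected.
#' @param max_skew_hours allowed forward clock skew (default 24 h).
#' @return `results`, invisibly; error describing the first violation
#'   otherwise.
#' @export
validate_results <- function(results, ingest_clock = NULL,
                             max_skew_hours = 24) {
  req <- c("measured_at", "patient_id", "case_id", "order_id", "parameter",
           "value")
  miss <- setdiff(req, names(results))
  if (length(miss) > 0) stop("missing result columns: ",
                             paste(miss, collapse = ", "))
  if (nrow(results) == 0) return(invisible(results))
  if (anyNA(results$measured_at)) stop("unparseable measurement timestamp")
  for (col in c("patient_id", "case_id", "order_id")) {
    bad <- is.na(results[[col]]) | !nzchar(results[[col]])
    if (any(bad)) stop("empty ", col, " in result row ", which(bad)[1])
  }
  unknown <- !results$parameter %in% PARAMETER_CODES
  if (any(unknown)) stop("unknown parameter code: ",
                         results$parameter[which(unknown)[1]])
  bad_v <- !is.finite(results$value) | results$value <= 0
  if (any(bad_v)) stop("non-finite or non-positive value in result row ",
                       which(bad_v)[1])
  if (!is.null(ingest_clock)) {
    ahead <- results$measured_at > ingest_clock + max_skew_hours * 3600
    if (any(ahead)) stop("result row ", which(ahead)[1],
                         " is timestamped beyond the allowed clock skew")
  }
  invisible(results)
}
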