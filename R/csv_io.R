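#' Read laboratory results from the CSV fixture format
#'
#' Columns: `measured_at` (ISO 8601), `patient_id`, `case_id`, `order_id`,
#' `parameter` (code or alias), `value`, `units`. Validation and unit
#' conversion are identical to the HL7 path, so equivalent content yields
#' identical result sets.
#'
#' @param path CSV file path.
#' @return `lab_result` data.frame in file order.
#' @export
read_results_csv <- function(path) {
  if (!file.exists(path)) stop("CSV file not found: ", path)
  # na.strings disabled: "NA" is the sodium parameter code, not missing
  raw <- utils::read.csv(path, colClasses = "character",
                         strip.white = TRUE, na.strings = character())
  req <- c("measured_at", "patient_id", "case_id", "order_id", "parameter",
           "value", "units")
  miss <- setdiff(req, names(raw))
  if (length(miss) > 0) stop("CSV missing columns: ",
                             paste(miss, collapse = ", "))
  if (nrow(raw) == 0) return(empty_results())
  out <- empty_results()
  for (i in seq_len(nrow(raw))) {
    line <- i + 1L  # header is line 1
    ts <- suppressWarnings(as.POSIXct(
      raw$measured_at[i], tz = "UTC",
      tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%dT%H:%M",
                     "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M", "%Y-%m-%d")))
    if (is.na(ts)) stop("line ", line, ": unparseable measured_at '",
                        raw$measured_at[i], "'")
    param <- resolve_parameter(raw$parameter[i])
    if (is.na(param)) stop("line ", line, ": unknown parameter '",
                           raw$parameter[i], "'")
    value <- suppressWarnings(as.numeric(raw$value[i]))
    if (is.na(value)) stop("line ", line, ": non-numeric value '",
                           raw$value[i], "'")
    value <- tryCatch(convert_to_canonical(param, value, raw$units[i]),
                      error = function(e) stop("line ", line, ": ",
                                               conditionMessage(e),
                                               call. = FALSE))
    row <- tryCatch(
      validate_results(lab_result(ts, raw$patient_id[i], raw$case_id[i],
                                  raw$order_id[i], param, value,
                                  raw$units[i], "LAB")),
      error = function(e) stop("line ", line, ": ", conditionMessage(e),
                               call. = FALSE))
    out <- bind_results(out, row)
  }
  out
}

#' Write results to the CSV fixture format
#'
#' @param results `lab_result` data.frame (values in canonical units).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(results, path) {
  units <- stats::setNames(parameter_table()$canonical_units,
                           parameter_table()$code)
  df <- data.frame(
    measured_at = format(results$measured_at, "%Y-%m-%dT%H:%M:%S",
                         tz = "UTC"),
    patient_id = results$patient_id,
    case_id = results$case_id,
    order_id = results$order_id,
    parameter = results$parameter,
    value = results$value,
    units = unname(units[results$parameter]),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
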