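#' Simplified HL7 v2 ORU^R01 reader/writer
#'
#' A deliberately small dialect: v2.3-style pipe-delimited ORU^R01, default
#' encoding characters `|^~\&`, one message per envelope, only
#' MSH/PID/PV1/OBR/OBX consumed; unknown segments are ignored. Field
#' mapping: PID-3 patient ID, PV1-19 case ID, OBR-2 order ID, OBX-3
#' parameter (via code table), OBX-5 value, OBX-6 units, OBX-14 (fallback
#' OBR-7) measurement time. Timestamps use the HL7 TS format
#' `YYYYMMDDHHMMSS`, interpreted as zone-naive wall-clock (stored as UTC).
#'
#' @name hl7
NULL

HL7_TS_FORMAT <- "%Y%m%d%H%M%S"

.hl7_parse_ts <- function(x, what) {
  if (is.na(x) || !nzchar(x)) return(as.POSIXct(NA))
  x <- substr(x, 1, 14)
  if (nchar(x) == 8) x <- paste0(x, "000000")
  if (nchar(x) == 12) x <- paste0(x, "00")
  ts <- as.POSIXct(x, format = HL7_TS_FORMAT, tz = "UTC")
  if (is.na(ts)) stop("unparseable HL7 timestamp in ", what, ": '", x, "'")
  ts
}

.hl7_format_ts <- function(ts) format(ts, HL7_TS_FORMAT, tz = "UTC")

# SEG-k for non-MSH segments; fields[1] is the segment name
.fld <- function(fields, k) {
  if (length(fields) >= k + 1) fields[k + 1] else ""
}

.component1 <- function(x) strsplit(x, "^", fixed = TRUE)[[1]][1]

#' Parse one ORU^R01 message
#'
#' @param text raw message text (segments separated by `\r` and/or `\n`).
#' @param strict if TRUE, an unknown parameter code is an error; default
#'   skips the OBX with a warning.
#' @return a `message_envelope`: list with `message_id`, `sent_at`,
#'   `sender`, and `results` (a `lab_result` data.frame).
#' @export
parse_oru_message <- function(text, strict = FALSE) {
  segs <- strsplit(paste(text, collapse = "\n"), "\r\n|\r|\n")[[1]]
  segs <- segs[nzchar(segs)]
  if (length(segs) == 0) stop("empty HL7 message")
  fields_of <- strsplit(segs, "|", fixed = TRUE)
  names(fields_of) <- vapply(fields_of, `[`, "", 1)
  seg_names <- names(fields_of)

  if (seg_names[1] != "MSH") stop("message must start with MSH segment")
  msh <- fields_of[[1]]
  # MSH-1 is the field separator itself, so MSH-k = msh[k] for k >= 2
  sender <- if (length(msh) >= 3) msh[3] else ""
  sent_at <- .hl7_parse_ts(if (length(msh) >= 7) msh[7] else "", "MSH-7")
  message_id <- if (length(msh) >= 10) msh[10] else ""

  pid_i <- which(seg_names == "PID")
  if (length(pid_i) == 0) stop("missing mandatory segment PID")
  patient_id <- .component1(.fld(fields_of[[pid_i[1]]], 3))
  if (is.na(patient_id) || !nzchar(patient_id)) stop("PID-3 empty")

  pv1_i <- which(seg_names == "PV1")
  if (length(pv1_i) == 0) stop("missing mandatory segment PV1")
  case_id <- .component1(.fld(fields_of[[pv1_i[1]]], 19))
  if (is.na(case_id) || !nzchar(case_id)) stop("PV1-19 empty")

  if (!any(seg_names == "OBR")) stop("missing mandatory segment OBR")
  if (!any(seg_names == "OBX")) stop("missing mandatory segment OBX")

  results <- empty_results()
  order_id <- ""
  obr_ts <- as.POSIXct(NA)
  for (i in seq_along(segs)) {
    f <- fields_of[[i]]
    if (seg_names[i] == "OBR") {
      order_id <- .fld(f, 2)
      if (!nzchar(order_id)) stop("OBR-2 empty")
      ts <- .fld(f, 7)
      obr_ts <- if (nzchar(ts)) .hl7_parse_ts(ts, "OBR-7") else as.POSIXct(NA)
    } else if (seg_names[i] == "OBX") {
      value_raw <- .fld(f, 5)
      value <- suppressWarnings(as.numeric(value_raw))
      if (is.na(value)) next  # only numeric observations are consumed
      code <- .component1(.fld(f, 3))
      param <- resolve_parameter(code)
      if (is.na(param)) {
        msg <- paste0("unknown parameter code in OBX-3: '", code, "'")
        if (strict) stop(msg)
        warning(msg, "; observation skipped")
        next
      }
      units <- .component1(.fld(f, 6))
      ts_raw <- .fld(f, 14)
      measured_at <- if (nzchar(ts_raw)) .hl7_parse_ts(ts_raw, "OBX-14")
                     else obr_ts
      if (is.na(measured_at)) stop("OBX-14 empty and no OBR-7 fallback")
      source <- .fld(f, 15)
      if (!nzchar(source)) source <- "LAB"
      results <- bind_results(results, lab_result(
        measured_at, patient_id, case_id, order_id, param,
        convert_to_canonical(param, value, units), units, source))
    }
  }
  if (nrow(results) == 0) stop("message contains no usable numeric OBX")
  validate_results(results)
  structure(list(message_id = message_id, sent_at = sent_at, sender = sender,
                 results = results),
            class = "message_envelope")
}

#' Serialize an envelope as an ORU^R01 message
#'
#' Deterministic segment order (MSH, PID, PV1, then one OBR per order with
#' its OBX set); `parse_oru_message()` accepts the output and reproduces the
#' result set exactly.
#'
#' @param envelope a `message_envelope` (see [parse_oru_message()]).
#' @return single string, segments separated by `\n`.
#' @export
write_oru_message <- function(envelope) {
  res <- envelope$results
  stopifnot(nrow(res) > 0)
  stopifnot(length(unique(res$patient_id)) == 1,
            length(unique(res$case_id)) == 1)
  display <- stats::setNames(parameter_table()$display,
                             parameter_table()$code)
  msh <- paste(c("MSH", "^~\\&", envelope$sender, "", "", "",
                 .hl7_format_ts(envelope$sent_at), "", "ORU^R01",
                 envelope$message_id, "P", "2.3"), collapse = "|")
  pid <- paste(c("PID", "1", "", res$patient_id[1]), collapse = "|")
  pv1 <- paste(c("PV1", "1", "I", rep("", 16), res$case_id[1]),
               collapse = "|")
  lines <- c(msh, pid, pv1)
  set_id <- 0L
  for (ord in unique(res$order_id)) {
    set_id <- set_id + 1L
    grp <- res[res$order_id == ord, , drop = FALSE]
    obr <- paste(c("OBR", set_id, ord, "", "", "", "",
                   .hl7_format_ts(grp$measured_at[1])), collapse = "|")
    lines <- c(lines, obr)
    for (j in seq_len(nrow(grp))) {
      p <- grp$parameter[j]
      obx <- paste(c("OBX", j, "NM",
                     paste0(p, "^", unname(display[p])), "",
                     format(grp$value[j], digits = 15, scientific = FALSE,
                            trim = TRUE),
                     grp$raw_units[j], rep("", 7),
                     .hl7_format_ts(grp$measured_at[j]), grp$source[j]),
                   collapse = "|")
      lines <- c(lines, obx)
    }
  }
  paste(lines, collapse = "\n")
}

#' Read all ORU messages from a file
#'
#' @param path file with one or more messages; a new message starts at each
#'   `MSH|` segment.
#' @param strict passed to [parse_oru_message()].
#' @return list of `message_envelope` objects.
#' @export
read_oru_file <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("HL7 file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- unlist(strsplit(lines, "\r"))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(list())
  starts <- which(startsWith(lines, "MSH|"))
  if (length(starts) == 0) stop("no MSH segment found in ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  lapply(seq_along(starts), function(i) {
    parse_oru_message(lines[starts[i]:ends[i]], strict = strict)
  })
}

#' Write envelopes to an ORU file
#'
#' @param envelopes list of `message_envelope` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_oru_file <- function(envelopes, path) {
  writeLines(vapply(envelopes, write_oru_message, ""), path)
  invisible(path)
}
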