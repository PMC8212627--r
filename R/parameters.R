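#' Supported laboratory parameters
#'
#' The analyte code table: canonical unit per analyte plus the HL7/CSV codes
#' accepted on ingest. All electrolytes and lactate are carried in mmol/L;
#' creatinine in umol/L. Unit conversion happens at ingest, never inside
#' rules.
#'
#' @return data.frame with columns `code`, `canonical_units`, `display`.
#' @export
parameter_table <- function() {
  data.frame(
    code = c("K", "NA", "CA_TOTAL", "CA_IONIZED", "LACTATE", "CREATININE"),
    canonical_units = c("mmol/L", "mmol/L", "mmol/L", "mmol/L", "mmol/L",
                        "umol/L"),
    display = c("Potassium", "Sodium", "Calcium (total)",
                "Calcium (ionized)", "Lactate", "Creatinine"),
    stringsAsFactors = FALSE
  )
}

PARAMETER_CODES <- c("K", "NA", "CA_TOTAL", "CA_IONIZED", "LACTATE",
                     "CREATININE")

# aliases seen in OBX-3 / CSV parameter columns -> canonical code
.parameter_aliases <- c(
  K = "K", POTASSIUM = "K",
  `NA` = "NA", SODIUM = "NA",
  CA = "CA_TOTAL", CA_TOTAL = "CA_TOTAL", CALCIUM = "CA_TOTAL",
  CA_ION = "CA_IONIZED", CA_IONIZED = "CA_IONIZED", ICA = "CA_IONIZED",
  LAC = "LACTATE", LACTATE = "LACTATE",
  CREA = "CREATININE", CREATININE = "CREATININE", KREA = "CREATININE"
)

#' Resolve a parameter code or alias
#'
#' @param code raw code string (case-insensitive; HL7 component or CSV cell).
#' @return canonical parameter code, or NA if unknown.
#' @export
resolve_parameter <- function(code) {
  out <- unname(.parameter_aliases[toupper(trimws(code))])
  out
}

# mg/dL -> umol/L for creatinine
CREATININE_UMOL_PER_MGDL <- 88.4

#' Convert a result value to canonical units
#'
#' Accepts the canonical unit spelled in common variants and, for creatinine,
#' mg/dL (factor 88.4 umol/L per mg/dL).
#'
#' @param parameter canonical parameter code.
#' @param value numeric value.
#' @param units unit string as received.
#' @return numeric value in canonical units.
#' @export
convert_to_canonical <- function(parameter, value, units) {
  u <- tolower(gsub("µ", "u", trimws(units)))
  canonical <- parameter_table()
  canon_u <- tolower(canonical$canonical_units[canonical$code == parameter])
  if (length(canon_u) == 0) stop("unknown parameter: ", parameter)
  if (u == canon_u || u == "") return(value)
  if (parameter == "CREATININE" && u == "mg/dl") {
    return(value * CREATININE_UMOL_PER_MGDL)
  }
  stop("no known conversion for parameter ", parameter, " from units '",
       units, "' to ", canon_u)
}
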