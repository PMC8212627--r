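#' Traffic-light severity levels
#'
#' Severities form the total order GREEN < YELLOW < RED. They are represented
#' as plain character strings; use [severity_max()] and [severity_level()] for
#' order-aware operations.
#'
#' @format Character vector of the three levels in ascending order.
#' @export
SEVERITY_LEVELS <- c("GREEN", "YELLOW", "RED")

#' Numeric rank of a severity
#'
#' @param x character vector of severities.
#' @return integer vector: GREEN = 1, YELLOW = 2, RED = 3.
#' @export
severity_level <- function(x) {
  lv <- match(x, SEVERITY_LEVELS)
  if (anyNA(lv)) {
    stop("unknown severity: ", paste(unique(x[is.na(lv)]), collapse = ", "))
  }
  lv
}

#' Maximum severity under the traffic-light hierarchy
#'
#' Implements the overview colour rule: at least one RED makes the summary
#' RED; otherwise at least one YELLOW makes it YELLOW; GREEN otherwise.
#'
#' @param x character vector of severities; empty input yields GREEN.
#' @return single severity string.
#' @export
severity_max <- function(x) {
  if (length(x) == 0) return("GREEN")
  SEVERITY_LEVELS[max(severity_level(x))]
}
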