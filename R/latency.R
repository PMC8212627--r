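#' Dataflow latency model
#'
#' End-to-end notification delay is bounded by the polling intervals of the
#' pipeline components: the communication server forwards measurements at
#' most every 15 minutes, the warehouse/engine polls its on-disk database at
#' most every 60 minutes, and the ward terminal refreshes at most every 10
#' minutes — a worst case of 85 minutes between measurement and display.
#' The checkbox protocol records per-hop timestamps so an observed lag can
#' be attributed to one component.
#'
#' @name latency
NULL

#' Latency configuration
#'
#' Ordered hop maxima in minutes, pipeline order fixed: measurement ->
#' communication server -> warehouse/engine -> (engine-internal) ->
#' terminal. The engine-internal hop defaults to 0 (the notification is
#' generated in the same polling pass), so any positive engine-internal lag
#' is flagged.
#'
#' @param comm_server_min,warehouse_poll_min,terminal_poll_min hop maxima
#'   in minutes.
#' @param engine_internal_min engine-internal allowance in minutes.
#' @return object of class `latency_config` (named numeric, minutes).
#' @export
latency_config <- function(comm_server_min = 15, warehouse_poll_min = 60,
                           terminal_poll_min = 10,
                           engine_internal_min = 0) {
  hops <- c(comm_server = comm_server_min,
            warehouse_poll = warehouse_poll_min,
            engine_internal = engine_internal_min,
            terminal_poll = terminal_poll_min)
  if (any(!is.finite(hops)) || any(hops < 0)) {
    stop("hop maxima must be finite and >= 0")
  }
  structure(hops, class = "latency_config")
}

#' Worst-case end-to-end delay
#'
#' The sum of the configured hop maxima: with the default 15/60/10-minute
#' hops, 85 minutes between measurement and notification display.
#'
#' @param config a [latency_config()].
#' @return worst-case delay in minutes.
#' @export
worst_case_delay <- function(config) {
  if (any(config < 0)) stop("negative hop duration")
  sum(unclass(config))
}

#' Per-hop timestamps of one measurement's journey
#'
#' @param measured_at,comm_server_at,engine_at,notified_at,terminal_at
#'   POSIXct timestamps; any suffix may be missing (NA).
#' @return object of class `hop_timestamps`.
#' @export
hop_timestamps <- function(measured_at, comm_server_at = NA,
                           engine_at = NA, notified_at = NA,
                           terminal_at = NA) {
  ts <- list(measured_at = measured_at, comm_server_at = comm_server_at,
             engine_at = engine_at, notified_at = notified_at,
             terminal_at = terminal_at)
  ts <- lapply(ts, function(x) as.POSIXct(x, tz = "UTC"))
  present <- !vapply(ts, is.na, TRUE)
  # any suffix may be missing, but no gaps inside the observed prefix-free
  vals <- as.numeric(unlist(ts[present]))
  if (is.unsorted(vals)) {
    stop("hop timestamps must be non-decreasing in pipeline order")
  }
  structure(ts, class = "hop_timestamps")
}

# which configured hop each inter-timestamp interval belongs to
.hop_of_interval <- c(measured_at = NA, comm_server_at = "comm_server",
                      engine_at = "warehouse_poll",
                      notified_at = "engine_internal",
                      terminal_at = "terminal_poll")

#' Attribute observed delay to pipeline components
#'
#' Computes the lag of every observed hop, flags hops whose lag exceeds
#' their configured maximum, and names the dominant component (largest lag;
#' ties broken by the earliest pipeline hop).
#'
#' @param hops a [hop_timestamps()] with at least two timestamps present.
#' @param config a [latency_config()].
#' @return list with `hops` (data.frame: hop, lag_min, max_min, exceeded),
#'   `dominant` (hop name), `total_min`.
#' @export
attribute_delay <- function(hops, config = latency_config()) {
  stopifnot(inherits(hops, "hop_timestamps"))
  present <- names(hops)[!vapply(hops, is.na, TRUE)]
  if (length(present) < 2) {
    stop("attribute_delay needs at least two observed timestamps")
  }
  lag_rows <- list()
  for (i in seq_along(present)[-1]) {
    to <- present[i]
    from <- present[i - 1]
    hop <- .hop_of_interval[[to]]
    lag_min <- as.numeric(difftime(hops[[to]], hops[[from]],
                                   units = "mins"))
    max_min <- unname(unclass(config)[hop])
    lag_rows[[hop]] <- data.frame(
      hop = hop, from = from, to = to, lag_min = lag_min,
      max_min = if (is.na(max_min)) NA_real_ else max_min,
      exceeded = !is.na(max_min) && lag_min > max_min,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, lag_rows)
  rownames(tab) <- NULL
  dominant <- tab$hop[which.max(tab$lag_min)]  # ties -> earliest hop
  list(hops = tab, dominant = dominant, total_min = sum(tab$lag_min))
}

#' Monte-Carlo sample of end-to-end polling delays
#'
#' Each hop delay is drawn uniformly on [0, hop maximum] (a measurement
#' arrives at a uniformly random phase of each polling cycle); the
#' end-to-end delay is their sum, never exceeding
#' [worst_case_delay()]. The sample mean converges to half the worst case.
#'
#' @param config a [latency_config()].
#' @param n sample size (> 0).
#' @param seed integer seed.
#' @return numeric vector of `n` delays in minutes.
#' @export
simulate_polling_delay <- function(config = latency_config(), n = 1000,
                                   seed = 1) {
  stopifnot(n > 0)
  set.seed(seed)
  hops <- unclass(config)
  delays <- vapply(hops, function(mx) stats::runif(n, 0, mx),
                   numeric(n))
  if (n == 1) sum(delays) else rowSums(delays)
}

#' Read hop records from CSV
#'
#' One row per measurement; columns `measured_at`, `comm_server_at`,
#' `engine_at`, `notified_at`, `terminal_at` (ISO 8601, blanks allowed for
#' missing suffixes).
#'
#' @param path CSV path.
#' @return list of `hop_timestamps`.
#' @export
read_hops_csv <- function(path) {
  if (!file.exists(path)) stop("hops file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         strip.white = TRUE, na.strings = "")
  req <- c("measured_at", "comm_server_at", "engine_at", "notified_at",
           "terminal_at")
  miss <- setdiff(req, names(raw))
  if (length(miss) > 0) stop("hops CSV missing columns: ",
                             paste(miss, collapse = ", "))
  if (nrow(raw) == 0) stop("hops CSV has no records")
  parse1 <- function(x) {
    if (is.na(x) || !nzchar(x)) return(as.POSIXct(NA))
    .from_iso(x)
  }
  lapply(seq_len(nrow(raw)), function(i) {
    do.call(hop_timestamps, lapply(raw[i, req], parse1))
  })
}
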