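# Internal helpers: clock-time parsing/formatting and RNG state preservation.

SECONDS_PER_DAY <- 86400L

#' Parse a clock time into seconds since midnight
#'
#' Accepts `HH:MM` or `HH:MM:SS`. `24:00` (and `24:00:00`) is allowed as an
#' end-of-day boundary and maps to 86400.
#'
#' @param x character scalar, e.g. `"9:00"` or `"18:40:30"`.
#' @return integer seconds since midnight.
#' @keywords internal
#' @noRd
parse_clock_time <- function(x) {
  m <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})(?::([0-9]{2}))?$", x))[[1]]
  if (length(m) == 0L) {
    stop("malformed clock time: '", x, "' (expected HH:MM or HH:MM:SS)", call. = FALSE)
  }
  h <- as.integer(m[2]); mi <- as.integer(m[3])
  s <- if (nzchar(m[4])) as.integer(m[4]) else 0L
  if (mi > 59L || s > 59L || h > 24L || (h == 24L && (mi > 0L || s > 0L))) {
    stop("clock time out of range: '", x, "'", call. = FALSE)
  }
  h * 3600L + mi * 60L + s
}

format_clock_time <- function(secs) {
  secs <- as.integer(secs)
  sprintf("%02d:%02d:%02d", secs %/% 3600L, (secs %% 3600L) %/% 60L, secs %% 60L)
}

# Run `expr` under a temporary seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

is_prob <- function(p) is.numeric(p) && length(p) == 1L && !is.na(p) && p >= 0 && p <= 1

# Timestamps are kept at whole-second resolution in UTC so that CSV
# round-trips are exact.
as_utc <- function(x) as.POSIXct(x, tz = "UTC")

format_iso8601 <- function(t) format(t, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

parse_iso8601 <- function(x) {
  t <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  bad <- is.na(t) & !is.na(x)
  if (any(bad)) {
    stop("malformed timestamp: '", x[which(bad)[1]], "'", call. = FALSE)
  }
  t
}

empty_events <- function() {
  data.frame(
    timestamp = as_utc(character(0)),
    sensor = character(0),
    label = character(0),
    marker = character(0),
    stringsAsFactors = FALSE
  )
}

empty_instances <- function() {
  data.frame(
    activity = character(0),
    start_time = as_utc(character(0)),
    end_time = as_utc(character(0)),
    pattern_index = integer(0),
    n_events = integer(0),
    stringsAsFactors = FALSE
  )
}

# Deterministic event ordering: timestamp, then activity events before noise;
# remaining ties keep input (scheduling) order — the sort is stable, so sensor
# order within an activity instance always equals pattern order.
sort_events <- function(ev) {
  if (nrow(ev) == 0L) return(ev)
  ord <- order(ev$timestamp, ev$label == "None", method = "radix")
  ev <- ev[ord, , drop = FALSE]
  rownames(ev) <- NULL
  ev
}
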