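#' Write a labelled dataset to CSV
#'
#' The dialect is a plain comma-separated file with header
#' `timestamp,sensor,label,marker`: ISO-8601 UTC timestamps at second
#' resolution, the activity name (or `None` for noise events) as label, and
#' a marker that is empty, `start`, `end`, or `start+end` when an activity
#' instance has a single surviving activation. Re-reading with
#' [read_dataset_csv()] reproduces the event stream exactly.
#'
#' @param ds a `labelled_dataset` (or any event data frame with those four
#'   columns).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(ds, path) {
  ev <- if (inherits(ds, "labelled_dataset")) ds$events else ds
  out <- data.frame(
    timestamp = format_iso8601(ev$timestamp),
    sensor = ev$sensor, label = ev$label, marker = ev$marker,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a labelled dataset from CSV
#'
#' Inverse of [write_dataset_csv()]. Activity instances are reconstructed
#' from the boundary markers and labels: the pattern index chosen during
#' simulation is not stored in the CSV, so reconstructed instances carry
#' `pattern_index = NA`.
#'
#' @param path input file path.
#' @return a `labelled_dataset`.
#' @export
read_dataset_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("character", "character", "character", "character"))
  expect_cols <- c("timestamp", "sensor", "label", "marker")
  if (!identical(names(df), expect_cols)) {
    stop("malformed dataset CSV: expected header ",
         paste(expect_cols, collapse = ","), call. = FALSE)
  }
  ts <- tryCatch(parse_iso8601(df$timestamp), error = function(e) {
    bad <- which(is.na(suppressWarnings(
      as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC"))))[1]
    stop("malformed dataset CSV row ", bad, ": ", conditionMessage(e), call. = FALSE)
  })
  df$marker[is.na(df$marker)] <- ""
  events <- data.frame(timestamp = ts, sensor = df$sensor, label = df$label,
                       marker = df$marker, stringsAsFactors = FALSE)
  events <- sort_events(events)
  new_dataset_from_events(events)
}

# Rebuild a labelled_dataset around an event table, reconstructing instances
# from the markers present.
new_dataset_from_events <- function(events) {
  instances <- empty_instances()
  act <- events[events$label != "None" & events$label != "unlabelled", , drop = FALSE]
  starts <- if (nrow(act) > 0L) which(act$marker %in% c("start", "start+end"))
            else integer(0)
  if (length(starts) > 0L) {
    inst <- lapply(starts, function(i) {
      lab <- act$label[i]
      if (act$marker[i] == "start+end") {
        j <- i
      } else {
        after <- which(act$marker == "end" & act$label == lab &
                         seq_len(nrow(act)) >= i)
        j <- if (length(after)) after[1] else i
      }
      list(activity = lab, start_time = act$timestamp[i], end_time = act$timestamp[j],
           n_events = NA_integer_)
    })
    instances <- data.frame(
      activity = vapply(inst, `[[`, "", "activity"),
      start_time = as_utc(as.POSIXct(vapply(inst, function(x) as.numeric(x$start_time), 0),
                                     origin = "1970-01-01", tz = "UTC")),
      end_time = as_utc(as.POSIXct(vapply(inst, function(x) as.numeric(x$end_time), 0),
                                   origin = "1970-01-01", tz = "UTC")),
      pattern_index = NA_integer_,
      n_events = NA_integer_,
      stringsAsFactors = FALSE
    )
  }
  span <- if (nrow(events) > 0L) {
    as.Date(range(events$timestamp), tz = "UTC")
  } else {
    as.Date(c(NA, NA))
  }
  structure(list(events = events, instances = instances, span = span),
            class = "labelled_dataset")
}

#' Read a minimal external event log
#'
#' Accepts CSV files with at least `timestamp,sensor` columns (extra columns
#' are ignored except an optional `label`). Rows need not be sorted; events
#' without a label are marked `unlabelled`. This is the entry point for
#' comparing a simulation against an externally collected dataset converted
#' to this minimal dialect.
#'
#' @param path input file path.
#' @return a `labelled_dataset` (instances empty unless markers are present).
#' @export
read_external_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("timestamp", "sensor") %in% names(df))) {
    stop("external event log must have 'timestamp' and 'sensor' columns",
         call. = FALSE)
  }
  ts <- parse_iso8601(as.character(df$timestamp))
  label <- if ("label" %in% names(df)) as.character(df$label) else
    rep("unlabelled", nrow(df))
  label[is.na(label) | !nzchar(label)] <- "unlabelled"
  marker <- if ("marker" %in% names(df)) {
    m <- as.character(df$marker); m[is.na(m)] <- ""; m
  } else rep("", nrow(df))
  events <- sort_events(data.frame(timestamp = ts, sensor = as.character(df$sensor),
                                   label = label, marker = marker,
                                   stringsAsFactors = FALSE))
  new_dataset_from_events(events)
}
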