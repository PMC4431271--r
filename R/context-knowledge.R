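#' Parse a context-knowledge file
#'
#' The context-knowledge file describes the simulated environment as JSON
#' with three top-level keys:
#'
#' * `objects`: array of `{name, location, attached_sensor}` — the household
#'   objects, where they are and which sensor monitors each;
#' * `sensors`: array of `{name, type}` — the deployed sensors and their
#'   technology type (e.g. `contact`, `tilt`, `pressure`, `sound`);
#' * `error_models`: object mapping each sensor type to its missing-noise
#'   probability `p` in `[0, 1]` — the probability that a real interaction
#'   fails to produce an activation.
#'
#' Missing noise is attached to sensor *types* because it is a property of
#' the sensing technology and acquisition infrastructure, unlike positive
#' noise, which is driven by the resident and so lives in the ADL script.
#' Locations are carried through but not interpreted by the simulator.
#'
#' A schema document ships in `inst/extdata/context-schema.json`.
#'
#' @param json_text a JSON string, character vector of lines, or a file path
#'   (when `file` is `TRUE`).
#' @param file if `TRUE`, `json_text` is a path.
#' @return an object of class `context_knowledge` with elements `objects`
#'   (list of `{name, location, attached_sensor}`), `sensors` (list of
#'   `{name, type}`) and `missing_noise` (named numeric vector, sensor type
#'   to miss probability).
#' @examples
#' ctx <- parse_context('{
#'   "objects": [{"name": "fridge", "location": "kitchen",
#'                "attached_sensor": "fridgeSens"}],
#'   "sensors": [{"name": "fridgeSens", "type": "contact"}],
#'   "error_models": {"contact": 0.0208}
#' }')
#' missing_prob_for(ctx, "fridgeSens")
#' @export
parse_context <- function(json_text, file = FALSE) {
  if (!file && length(json_text) > 1L) {
    json_text <- paste(json_text, collapse = "\n")
  }
  doc <- jsonlite::fromJSON(json_text, simplifyVector = FALSE)
  for (key in c("objects", "sensors", "error_models")) {
    if (is.null(doc[[key]])) {
      stop("context knowledge: missing section '", key, "'", call. = FALSE)
    }
  }

  need <- function(entry, fields, what, i) {
    for (f in fields) {
      v <- entry[[f]]
      if (is.null(v) || !is.character(v) || length(v) != 1L || !nzchar(v)) {
        stop("context knowledge: ", what, " ", i, " lacks a valid '", f, "'",
             call. = FALSE)
      }
    }
  }
  sensors <- lapply(seq_along(doc$sensors), function(i) {
    s <- doc$sensors[[i]]
    need(s, c("name", "type"), "sensor", i)
    list(name = s$name, type = s$type)
  })
  sensor_names <- vapply(sensors, `[[`, "", "name")
  if (anyDuplicated(sensor_names)) {
    stop("context knowledge: duplicate sensor name '",
         sensor_names[duplicated(sensor_names)][1], "'", call. = FALSE)
  }

  objects <- lapply(seq_along(doc$objects), function(i) {
    o <- doc$objects[[i]]
    need(o, c("name", "location", "attached_sensor"), "object", i)
    list(name = o$name, location = o$location, attached_sensor = o$attached_sensor)
  })
  for (o in objects) {
    if (!(o$attached_sensor %in% sensor_names)) {
      stop("context knowledge: object '", o$name, "' references unknown sensor '",
           o$attached_sensor, "'", call. = FALSE)
    }
  }

  em <- doc$error_models
  if (length(em) == 0L || is.null(names(em)) || any(!nzchar(names(em)))) {
    stop("context knowledge: 'error_models' must map sensor types to probabilities",
         call. = FALSE)
  }
  missing_noise <- vapply(em, function(p) {
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
      stop("context knowledge: missing probability outside [0, 1]", call. = FALSE)
    }
    as.numeric(p)
  }, 0)

  types <- vapply(sensors, `[[`, "", "type")
  no_model <- setdiff(unique(types), names(missing_noise))
  if (length(no_model) > 0L) {
    stop("context knowledge: sensor type(s) without an error model: ",
         paste(no_model, collapse = ", "), call. = FALSE)
  }

  structure(
    list(objects = objects, sensors = sensors, missing_noise = missing_noise),
    class = "context_knowledge"
  )
}

#' Serialize context knowledge to JSON
#'
#' Inverse of [parse_context()]; `parse_context(format_context(ctx))` equals
#' `ctx`.
#'
#' @param ctx a `context_knowledge` object.
#' @return a JSON string.
#' @export
format_context <- function(ctx) {
  stopifnot(inherits(ctx, "context_knowledge"))
  doc <- list(
    objects = lapply(ctx$objects, function(o)
      list(name = o$name, location = o$location, attached_sensor = o$attached_sensor)),
    sensors = lapply(ctx$sensors, function(s) list(name = s$name, type = s$type)),
    error_models = as.list(ctx$missing_noise)
  )
  jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' @export
print.context_knowledge <- function(x, ...) {
  cat("Context knowledge: ", length(x$objects), " object(s), ",
      length(x$sensors), " sensor(s), ",
      length(x$missing_noise), " error model(s)\n", sep = "")
  invisible(x)
}

#' Missing-noise probability of a sensor
#'
#' Looks up the sensor's type in the context knowledge and returns the
#' type's missing probability: the chance that an interaction with the
#' monitored object produces no activation.
#'
#' @param ctx a `context_knowledge` object.
#' @param sensor_name sensor identifier.
#' @return a probability in `[0, 1]`.
#' @export
missing_prob_for <- function(ctx, sensor_name) {
  stopifnot(inherits(ctx, "context_knowledge"))
  sensors <- vapply(ctx$sensors, `[[`, "", "name")
  i <- match(sensor_name, sensors)
  if (is.na(i)) {
    stop("unknown sensor '", sensor_name, "'", call. = FALSE)
  }
  unname(ctx$missing_noise[[ctx$sensors[[i]]$type]])
}

#' Calibrate a missing probability from interaction-recognition counts
#'
#' Monitoring studies of dense-sensing deployments report, per sensor type,
#' how many of the occurred user-object interactions the system captured
#' (the user-object interaction recognition accuracy, UoIR = captured /
#' total). The missing-noise probability is its complement.
#'
#' @param captured number of correctly captured interactions.
#' @param total number of occurred interactions (> 0).
#' @return `1 - captured / total`, the estimated miss probability.
#' @examples
#' estimate_missing_prob(611, 624)  # contact sensors: ~0.0208
#' @export
estimate_missing_prob <- function(captured, total) {
  stopifnot(length(captured) == 1L, length(total) == 1L)
  if (total <= 0) stop("total interactions must be > 0", call. = FALSE)
  if (captured < 0 || captured > total) {
    stop("captured must satisfy 0 <= captured <= total", call. = FALSE)
  }
  1 - captured / total
}
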