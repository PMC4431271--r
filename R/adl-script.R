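#' @title The ADL script: activity models, behaviour models and positive noise
#'
#' @description
#' An ADL script is a plain-text description of how one resident of a
#' dense-sensing smart environment lives: how many days to simulate, how each
#' activity of daily living translates into sensor activations, how activities
#' compose into days, and which sensors fire spontaneously.
#'
#' The dialect has four ordered sections, each introduced by a header line:
#'
#' ```
#' DAYS
#' 5
#'
#' ACTIVITIES
#' MakeCoffee 2
#' 0.7 afcoffeeSens@0 cookerSens@20 cupSens@45
#' 0.3 decoffeeSens@0 cupSens@30
#'
#' BEHAVIOURS
#' Prob 1.0
#' S 9:00 - 10:00 MakeCoffee@0
#' A 0.5 16:00 - 18:00 MakeCoffee
#'
#' NOISE
#' cupSens 0.1
#' ```
#'
#' * `DAYS` holds one natural number, the number of days to simulate.
#' * `ACTIVITIES` lists each activity as a `Name N` header followed by `N`
#'   sensor-activation patterns. A pattern line starts with its occurrence
#'   probability and continues with `sensor@lapse` steps, where the lapse is
#'   the mean time in seconds after the *previous* activation (the first step
#'   must carry lapse 0). Pattern probabilities of one activity must sum to 1.
#' * `BEHAVIOURS` lists day models. Each starts with `Prob p` and contains
#'   sequence lines `S HH:MM - HH:MM Act@0 Act@lapse ...` (always performed;
#'   lapses are seconds after the previous activity's *end*) and alteration
#'   lines `A p HH:MM - HH:MM Act` (performed with probability `p`).
#'   Behaviour-model probabilities must sum to 1. Both `-` and the en dash
#'   `–` are accepted in time slots.
#' * `NOISE` assigns per-hour spontaneous-activation probabilities to sensors
#'   (user erratic behaviour and other positive sensor noise).
#'
#' `#` starts a comment; blank lines are ignored.
#'
#' @name adl_script
NULL

PROB_SUM_TOL <- 1e-6

#' Parse an ADL script
#'
#' @param text the script source: either a single string (possibly
#'   multi-line), a character vector of lines, or a file path (when `file` is
#'   `TRUE`).
#' @param file if `TRUE`, `text` is a path read with [readLines()].
#' @return an object of class `adl_script`: a list with elements `days`
#'   (integer), `activities` (named list of activity definitions, each with
#'   `name` and `patterns`; a pattern has `probability` and a `steps` data
#'   frame with columns `sensor`, `lapse_s`), `behaviour_models` (list of
#'   lists with `probability` and `elements`; an element is either a sequence
#'   — `kind = "sequence"`, `slot`, `items` data frame with `activity`,
#'   `lapse_s` — or an alteration — `kind = "alteration"`, `probability`,
#'   `slot`, `activity`) and `positive_noise` (named numeric vector mapping
#'   sensor name to per-hour activation probability).
#' @details Structural violations (unknown syntax, a first step with non-zero
#'   lapse, negative lapses, malformed time slots, `days < 1`, probabilities
#'   outside `[0, 1]`) are errors that report the offending line number.
#'   Cross-file coherence and probability-sum checks are deferred to
#'   [validate_script()].
#' @seealso [validate_script()], [format_adl_script()]
#' @examples
#' script <- parse_adl_script(c(
#'   "DAYS", "1",
#'   "ACTIVITIES",
#'   "MakeCoffee 1",
#'   "1.0 afcoffeeSens@0 cookerSens@20",
#'   "BEHAVIOURS",
#'   "Prob 1.0",
#'   "S 9:00 - 10:00 MakeCoffee@0",
#'   "NOISE"
#' ))
#' script$activities$MakeCoffee$patterns[[1]]$steps
#' @export
parse_adl_script <- function(text, file = FALSE) {
  if (file) {
    text <- readLines(text, warn = FALSE, encoding = "UTF-8")
  }
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  if (length(text) == 0L || !any(nzchar(trimws(text)))) {
    stop("empty ADL script", call. = FALSE)
  }

  # Strip comments, normalise the en dash, keep original line numbers.
  raw <- sub("#.*$", "", text)
  raw <- gsub("–", "-", raw)
  raw <- trimws(raw)
  keep <- nzchar(raw)
  lines <- raw[keep]
  lineno <- which(keep)

  perr <- function(i, msg) {
    stop("ADL script line ", lineno[i], ": ", msg, call. = FALSE)
  }

  headers <- c("DAYS", "ACTIVITIES", "BEHAVIOURS", "NOISE")
  idx <- match(headers, lines)
  if (anyNA(idx)) {
    stop("ADL script: missing section header(s): ",
         paste(headers[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  if (is.unsorted(idx, strictly = TRUE)) {
    stop("ADL script: sections must appear in order DAYS, ACTIVITIES, BEHAVIOURS, NOISE",
         call. = FALSE)
  }
  section_of <- function(k) {
    lo <- idx[k] + 1L
    hi <- if (k < 4L) idx[k + 1L] - 1L else length(lines)
    if (hi < lo) integer(0) else lo:hi
  }

  ## DAYS
  di <- section_of(1L)
  if (length(di) != 1L) {
    stop("ADL script: DAYS section must contain exactly one number", call. = FALSE)
  }
  if (!grepl("^[0-9]+$", lines[di])) perr(di, "days must be a natural number")
  days <- as.integer(lines[di])
  if (is.na(days) || days < 1L) perr(di, "days must be >= 1")

  ## ACTIVITIES
  activities <- list()
  ai <- section_of(2L)
  i <- 1L
  while (i <= length(ai)) {
    li <- ai[i]
    head_tok <- strsplit(lines[li], "[[:space:]]+")[[1]]
    if (length(head_tok) != 2L || !grepl("^[0-9]+$", head_tok[2])) {
      perr(li, "expected activity header '<Name> <number-of-patterns>'")
    }
    name <- head_tok[1]
    npat <- as.integer(head_tok[2])
    if (npat < 1L) perr(li, "an activity needs at least one pattern")
    if (name %in% names(activities)) perr(li, paste0("duplicate activity '", name, "'"))
    if (i + npat > length(ai)) {
      perr(li, paste0("activity '", name, "' declares ", npat,
                      " pattern(s) but the section ends early"))
    }
    patterns <- vector("list", npat)
    for (k in seq_len(npat)) {
      lk <- ai[i + k]
      tok <- strsplit(lines[lk], "[[:space:]]+")[[1]]
      if (length(tok) < 2L) perr(lk, "pattern needs a probability and at least one step")
      p <- suppressWarnings(as.numeric(tok[1]))
      if (is.na(p)) perr(lk, "pattern line must start with a probability")
      if (!is_prob(p)) perr(lk, "pattern probability must be in [0, 1]")
      steps <- parse_at_items(tok[-1], function(msg) perr(lk, msg),
                              what = "sensor activation")
      if (steps$lapse_s[1] != 0) {
        perr(lk, "the first sensor activation's lapse must be 0")
      }
      patterns[[k]] <- list(probability = p,
                            steps = data.frame(sensor = steps$name,
                                               lapse_s = steps$lapse_s,
                                               stringsAsFactors = FALSE))
    }
    activities[[name]] <- list(name = name, patterns = patterns)
    i <- i + npat + 1L
  }

  ## BEHAVIOURS
  behaviour_models <- list()
  bi <- section_of(3L)
  current <- NULL
  flush_model <- function() {
    if (!is.null(current)) behaviour_models[[length(behaviour_models) + 1L]] <<- current
  }
  for (li in bi) {
    tok <- strsplit(lines[li], "[[:space:]]+")[[1]]
    kind <- tok[1]
    if (kind == "Prob") {
      flush_model()
      if (length(tok) != 2L) perr(li, "expected 'Prob <p>'")
      p <- suppressWarnings(as.numeric(tok[2]))
      if (is.na(p) || !is_prob(p)) perr(li, "behaviour-model probability must be in [0, 1]")
      current <- list(probability = p, elements = list())
    } else if (kind == "S") {
      if (is.null(current)) perr(li, "sequence line before any 'Prob' header")
      parsed <- parse_slot_tokens(tok[-1], function(msg) perr(li, msg))
      items <- parse_at_items(parsed$rest, function(msg) perr(li, msg),
                              what = "activity")
      if (nrow(items) > 0L && items$lapse_s[1] != 0) {
        perr(li, "the first activity's lapse in a sequence must be 0")
      }
      current$elements[[length(current$elements) + 1L]] <-
        list(kind = "sequence", slot = parsed$slot,
             items = data.frame(activity = items$name, lapse_s = items$lapse_s,
                                stringsAsFactors = FALSE))
    } else if (kind == "A") {
      if (is.null(current)) perr(li, "alteration line before any 'Prob' header")
      if (length(tok) < 2L) perr(li, "expected 'A <p> HH:MM - HH:MM <Activity>'")
      p <- suppressWarnings(as.numeric(tok[2]))
      if (is.na(p) || !is_prob(p)) perr(li, "alteration probability must be in [0, 1]")
      parsed <- parse_slot_tokens(tok[-(1:2)], function(msg) perr(li, msg))
      if (length(parsed$rest) != 1L) {
        perr(li, "an alteration names exactly one activity")
      }
      current$elements[[length(current$elements) + 1L]] <-
        list(kind = "alteration", probability = p, slot = parsed$slot,
             activity = parsed$rest)
    } else {
      perr(li, paste0("unknown behaviour line '", kind,
                      "' (expected Prob, S or A)"))
    }
  }
  flush_model()

  ## NOISE
  noise <- numeric(0)
  for (li in section_of(4L)) {
    tok <- strsplit(lines[li], "[[:space:]]+")[[1]]
    if (length(tok) != 2L) perr(li, "expected '<sensor> <per-hour probability>'")
    p <- suppressWarnings(as.numeric(tok[2]))
    if (is.na(p) || !is_prob(p)) perr(li, "noise probability must be in [0, 1]")
    if (tok[1] %in% names(noise)) perr(li, paste0("duplicate noise sensor '", tok[1], "'"))
    noise[tok[1]] <- p
  }

  structure(
    list(days = days, activities = activities,
         behaviour_models = behaviour_models, positive_noise = noise),
    class = "adl_script"
  )
}

# Parse `name@lapse` tokens shared by pattern steps and sequence items.
parse_at_items <- function(tokens, err, what) {
  if (length(tokens) == 0L) {
    err(paste0("expected at least one ", what))
  }
  m <- regmatches(tokens, regexec("^([^@[:space:]]+)@(-?[0-9]+)$", tokens))
  bad <- lengths(m) == 0L
  if (any(bad)) {
    err(paste0("malformed ", what, " token '", tokens[which(bad)[1]],
               "' (expected name@lapse)"))
  }
  name <- vapply(m, `[`, "", 2L)
  lapse <- as.integer(vapply(m, `[`, "", 3L))
  if (any(lapse < 0L)) err("negative time lapse")
  data.frame(name = name, lapse_s = lapse, stringsAsFactors = FALSE)
}

# Consume `HH:MM - HH:MM` (or `HH:MM-HH:MM`) from the head of a token vector.
parse_slot_tokens <- function(tokens, err) {
  if (length(tokens) >= 1L && grepl("^[0-9]{1,2}:[0-9]{2}(:[0-9]{2})?-[0-9]{1,2}:[0-9]{2}(:[0-9]{2})?$", tokens[1])) {
    parts <- strsplit(tokens[1], "-", fixed = TRUE)[[1]]
    rest <- tokens[-1]
  } else if (length(tokens) >= 3L && tokens[2] == "-") {
    parts <- tokens[c(1L, 3L)]
    rest <- tokens[-(1:3)]
  } else {
    err("malformed time slot (expected HH:MM - HH:MM)")
  }
  slot <- tryCatch(c(parse_clock_time(parts[1]), parse_clock_time(parts[2])),
                   error = function(e) err(conditionMessage(e)))
  if (slot[1] >= slot[2]) err("time slot start must precede its end")
  names(slot) <- c("start_s", "end_s")
  rest2 <- list(slot = slot, rest = rest)
  rest2
}

#' Serialize an ADL script back to its text form
#'
#' Inverse of [parse_adl_script()]: `parse_adl_script(format_adl_script(s))`
#' reproduces `s` exactly.
#'
#' @param script an `adl_script` object.
#' @return a character vector of script lines.
#' @export
format_adl_script <- function(script) {
  stopifnot(inherits(script, "adl_script"))
  fmt_slot <- function(slot) {
    ft <- function(s) {
      if (s %% 60L == 0L) sprintf("%d:%02d", s %/% 3600L, (s %% 3600L) %/% 60L)
      else format_clock_time(s)
    }
    paste(ft(slot[["start_s"]]), "-", ft(slot[["end_s"]]))
  }
  fmt_prob <- function(p) format(p, digits = 15)
  out <- c("DAYS", as.character(script$days), "", "ACTIVITIES")
  for (act in script$activities) {
    out <- c(out, paste(act$name, length(act$patterns)))
    for (pat in act$patterns) {
      out <- c(out, paste(fmt_prob(pat$probability),
                          paste0(pat$steps$sensor, "@", pat$steps$lapse_s,
                                 collapse = " ")))
    }
  }
  out <- c(out, "", "BEHAVIOURS")
  for (bm in script$behaviour_models) {
    out <- c(out, paste("Prob", fmt_prob(bm$probability)))
    for (el in bm$elements) {
      if (el$kind == "sequence") {
        out <- c(out, paste("S", fmt_slot(el$slot),
                            paste0(el$items$activity, "@", el$items$lapse_s,
                                   collapse = " ")))
      } else {
        out <- c(out, paste("A", fmt_prob(el$probability), fmt_slot(el$slot),
                            el$activity))
      }
    }
  }
  out <- c(out, "", "NOISE")
  if (length(script$positive_noise) > 0L) {
    out <- c(out, paste(names(script$positive_noise),
                        vapply(unname(script$positive_noise), fmt_prob, "")))
  }
  out
}

#' @export
print.adl_script <- function(x, ...) {
  cat("ADL script: ", x$days, " day(s), ",
      length(x$activities), " activit(y/ies), ",
      length(x$behaviour_models), " behaviour model(s), ",
      length(x$positive_noise), " noise sensor(s)\n", sep = "")
  invisible(x)
}

#' Occurrence probability of a day model from its weekly frequency
#'
#' Behaviour models do not name specific weekdays; a day model that occurs
#' on `k` of the 7 days of a week (e.g. a weekend day model, `k = 2`) gets
#' occurrence probability `k / 7`. Convenience for script authors
#' translating survey answers.
#'
#' @param days_per_week number of days per week the model describes (0-7).
#' @return `days_per_week / 7`.
#' @examples
#' days_per_week_prob(2)  # weekend day model, ~0.29
#' @export
days_per_week_prob <- function(days_per_week) {
  stopifnot(days_per_week >= 0, days_per_week <= 7)
  days_per_week / 7
}

#' Validate an ADL script against context knowledge
#'
#' Checks every invariant that parsing alone cannot: probability groups
#' (the patterns of each activity; the behaviour models of the script) must
#' sum to 1 within `1e-6`; every activity referenced by a sequence or
#' alteration must be defined; and every sensor used in a pattern or in the
#' positive-noise section must be declared in the context-knowledge file.
#' Simulating a script whose sensors are unknown to the context is an error
#' because missing-noise probabilities could not be looked up.
#'
#' @param script an `adl_script`.
#' @param ctx a `context_knowledge` object (see [parse_context()]).
#' @return a character vector of findings; `character(0)` means the pair is
#'   coherent. Callers that simulate treat any finding as fatal.
#' @seealso [run_simulation()], which refuses scripts with findings.
#' @export
validate_script <- function(script, ctx) {
  stopifnot(inherits(script, "adl_script"), inherits(ctx, "context_knowledge"))
  findings <- character(0)
  add <- function(msg) findings <<- c(findings, msg)
  known_sensors <- vapply(ctx$sensors, `[[`, "", "name")

  for (act in script$activities) {
    probs <- vapply(act$patterns, `[[`, 0, "probability")
    if (abs(sum(probs) - 1) > PROB_SUM_TOL) {
      add(sprintf("activity '%s': pattern probabilities sum to %.6g, not 1",
                  act$name, sum(probs)))
    }
    for (pat in act$patterns) {
      unknown <- setdiff(pat$steps$sensor, known_sensors)
      for (s in unknown) {
        add(sprintf("activity '%s': sensor '%s' is not in the context knowledge",
                    act$name, s))
      }
    }
  }

  if (length(script$behaviour_models) == 0L) {
    add("no behaviour models defined")
  } else {
    probs <- vapply(script$behaviour_models, `[[`, 0, "probability")
    if (abs(sum(probs) - 1) > PROB_SUM_TOL) {
      add(sprintf("behaviour-model probabilities sum to %.6g, not 1", sum(probs)))
    }
  }
  for (i in seq_along(script$behaviour_models)) {
    for (el in script$behaviour_models[[i]]$elements) {
      refs <- if (el$kind == "sequence") el$items$activity else el$activity
      unknown <- setdiff(refs, names(script$activities))
      for (a in unknown) {
        add(sprintf("behaviour model %d: undefined activity '%s'", i, a))
      }
    }
  }

  unknown <- setdiff(names(script$positive_noise), known_sensors)
  for (s in unknown) {
    add(sprintf("positive-noise sensor '%s' is not in the context knowledge", s))
  }
  findings
}
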