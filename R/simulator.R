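#' Simulation configuration
#'
#' @param seed integer seed; a fixed seed makes the simulation fully
#'   reproducible (byte-identical output).
#' @param sd_fraction standard deviation of the Gaussian time-lapse
#'   distributions, as a fraction of the mean. The default 0.25 encodes the
#'   assumption that the lapses a resident reports are the most common ones
#'   and that deviations become less likely the further they are from them.
#' @param start_date first simulated day (a `Date` or `"YYYY-MM-DD"` string).
#'   Fixed by default (`2015-01-01`) so that identical seeds give identical
#'   datasets; pass `Sys.Date()` to anchor the simulation to today.
#' @param max_resample negative Gaussian lapse draws are rejected and
#'   redrawn up to this many times, then clamped to 0. Negative lapses are
#'   never accepted: they would reorder sensor activations.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L, sd_fraction = 0.25,
                              start_date = as.Date("2015-01-01"),
                              max_resample = 100L) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            is.numeric(sd_fraction), sd_fraction >= 0,
            is.numeric(max_resample), max_resample >= 1)
  structure(
    list(seed = as.integer(seed), sd_fraction = sd_fraction,
         start_date = as.Date(start_date), max_resample = as.integer(max_resample)),
    class = "simulation_config"
  )
}

#' Draw a non-negative Gaussian time lapse
#'
#' Time lapses written in an ADL script are the *mean* values of Gaussian
#' distributions with standard deviation `cfg$sd_fraction * mean` (25% of
#' the mean by default). Negative draws are resampled up to
#' `cfg$max_resample` times and finally clamped to 0, so activation order is
#' always preserved. A zero mean returns 0 without consuming randomness.
#'
#' @param mean_s mean lapse in seconds (>= 0).
#' @param cfg a [simulation_config()].
#' @return a non-negative number of seconds (not rounded).
#' @export
sample_time_lapse <- function(mean_s, cfg = simulation_config()) {
  stopifnot(mean_s >= 0)
  if (mean_s == 0) return(0)
  sd_s <- cfg$sd_fraction * mean_s
  if (sd_s == 0) return(mean_s)
  for (i in seq_len(cfg$max_resample)) {
    x <- stats::rnorm(1L, mean = mean_s, sd = sd_s)
    if (x >= 0) return(x)
  }
  0
}

#' Generate one day of positive sensor noise
#'
#' For every sensor with a positive per-hour probability, each of the 24
#' hours of the day holds an independent Bernoulli trial; on success the
#' activation time is drawn uniformly inside that hour. At most one noise
#' event per sensor per hour is emitted. All noise events carry the
#' distinguished label `None` and no boundary marker.
#'
#' @param day a `Date`, the simulated day.
#' @param noise named numeric vector, sensor name to per-hour probability.
#' @return an event data frame (`timestamp`, `sensor`, `label`, `marker`),
#'   unsorted.
#' @export
generate_positive_noise_day <- function(day, noise) {
  day_start <- as_utc(as.POSIXct(as.Date(day), tz = "UTC"))
  ts <- as_utc(character(0)); sens <- character(0)
  for (s in names(noise)) {
    p <- noise[[s]]
    if (p <= 0) next
    for (h in 0:23) {
      if (stats::runif(1L) < p) {
        at <- day_start + h * 3600L + floor(stats::runif(1L) * 3600)
        ts <- c(ts, at); sens <- c(sens, s)
      }
    }
  }
  data.frame(timestamp = as_utc(ts), sensor = sens,
             label = rep("None", length(sens)),
             marker = rep("", length(sens)),
             stringsAsFactors = FALSE)
}

# Categorical draw over a probability vector (assumed to sum to 1).
draw_categorical <- function(probs) {
  u <- stats::runif(1L)
  cum <- cumsum(probs)
  cum[length(cum)] <- 1  # guard against numeric undershoot
  which(u < cum)[1]
}

#' Select a behaviour model according to the stated probabilities
#'
#' @param models list of behaviour models (each with a `probability`).
#' @return one element of `models`.
#' @export
select_behaviour_model <- function(models) {
  if (length(models) == 0L) stop("no behaviour models to select from", call. = FALSE)
  probs <- vapply(models, `[[`, 0, "probability")
  models[[draw_categorical(probs)]]
}

#' Select a sensor-activation pattern of an activity
#'
#' @param activity an activity definition (with a `patterns` list).
#' @return index of the chosen pattern.
#' @export
select_pattern <- function(activity) {
  probs <- vapply(activity$patterns, `[[`, 0, "probability")
  draw_categorical(probs)
}

# Schedule one activity instance starting at `start_s` (numeric seconds from
# epoch). Returns list(events = data.frame(time_s, sensor, label, instance),
# instance = list(...)). Consumes RNG: one uniform for the pattern draw, then
# one lapse per step beyond the first.
schedule_activity <- function(name, activity, start_s, cfg, instance_id) {
  pat_idx <- select_pattern(activity)
  pat <- activity$patterns[[pat_idx]]
  times <- numeric(nrow(pat$steps))
  t <- start_s
  for (k in seq_len(nrow(pat$steps))) {
    if (k > 1L) t <- t + sample_time_lapse(pat$steps$lapse_s[k], cfg)
    times[k] <- floor(t)
  }
  list(
    events = data.frame(time_s = times, sensor = pat$steps$sensor,
                        label = rep(name, length(times)),
                        instance = rep(instance_id, length(times)),
                        stringsAsFactors = FALSE),
    instance = list(activity = name, start_s = times[1],
                    end_s = times[length(times)], pattern_index = pat_idx)
  )
}

# Execute a sequence element within a day. `day_origin_s` is midnight of the
# day in epoch seconds. Returns events/instances; `next_id` tracks instance
# numbering across the day.
schedule_sequence <- function(seq_el, script, cfg, day_origin_s, next_id) {
  events <- list(); instances <- list()
  slot <- seq_el$slot
  start_s <- day_origin_s + slot[["start_s"]] +
    stats::runif(1L) * (slot[["end_s"]] - slot[["start_s"]])
  prev_end <- NA_real_
  for (k in seq_len(nrow(seq_el$items))) {
    name <- seq_el$items$activity[k]
    if (k == 1L) {
      t0 <- start_s
    } else {
      t0 <- prev_end + sample_time_lapse(seq_el$items$lapse_s[k], cfg)
    }
    sched <- schedule_activity(name, script$activities[[name]], t0, cfg, next_id)
    events[[k]] <- sched$events
    instances[[k]] <- sched$instance
    prev_end <- sched$instance$end_s
    next_id <- next_id + 1L
  }
  list(events = events, instances = instances, next_id = next_id)
}

#' Run the simulation loop
#'
#' For each of `script$days` days the simulator (in this exact RNG order):
#'
#' 1. generates positive sensor noise for the 24 hours of the day
#'    ([generate_positive_noise_day()]);
#' 2. draws one behaviour model according to the model probabilities;
#' 3. executes the model's elements in list order. A *sequence* draws the
#'    first activity's start time uniformly inside its slot; every later
#'    activity starts a Gaussian lapse after the previous activity's end.
#'    Within an activity, a sensor-activation pattern is drawn and its steps
#'    are scheduled with Gaussian lapses ([sample_time_lapse()]). An
#'    *alteration* executes with its probability as a one-activity sequence
#'    in its own slot;
#' 4. applies missing noise: every scheduled activity event is independently
#'    dropped with its sensor's miss probability ([apply_missing_noise()]).
#'    Noise events are not subject to missing noise.
#'
#' Missing noise never reschedules surviving events, so the time structure
#' of a day does not depend on which events were lost. Instance start/end
#' times record the pre-drop schedule; boundary *markers* sit on the first
#' and last surviving event of each instance (a single surviving event
#' carries the combined marker `start+end`). Activities may overrun their
#' slot or the day boundary; timestamps are absolute.
#'
#' @param script an `adl_script` (see [parse_adl_script()]).
#' @param ctx a `context_knowledge` (see [parse_context()]).
#' @param cfg a [simulation_config()].
#' @param days optional override of `script$days`.
#' @return a `labelled_dataset`: list with `events` (data frame `timestamp`,
#'   `sensor`, `label`, `marker`, sorted by timestamp with a deterministic
#'   tie-break), `instances` (data frame `activity`, `start_time`,
#'   `end_time`, `pattern_index`, `n_events`) and `span` (first day, last
#'   day).
#' @export
run_simulation <- function(script, ctx, cfg = simulation_config(), days = NULL) {
  findings <- validate_script(script, ctx)
  if (length(findings) > 0L) {
    stop("invalid script/context pair:\n  ", paste(findings, collapse = "\n  "),
         call. = FALSE)
  }
  n_days <- if (is.null(days)) script$days else as.integer(days)
  stopifnot(n_days >= 1L)

  with_seed(cfg$seed, {
    noise_events <- list(); act_events <- list(); instances <- list()
    next_id <- 1L
    for (d in seq_len(n_days) - 1L) {
      day <- cfg$start_date + d
      day_origin_s <- as.numeric(as.POSIXct(day, tz = "UTC"))

      noise_events[[d + 1L]] <- generate_positive_noise_day(day, script$positive_noise)

      model <- select_behaviour_model(script$behaviour_models)
      day_ev <- list(); day_inst <- list()
      for (el in model$elements) {
        if (el$kind == "sequence") {
          res <- schedule_sequence(el, script, cfg, day_origin_s, next_id)
        } else {
          if (stats::runif(1L) < el$probability) {
            one <- list(kind = "sequence", slot = el$slot,
                        items = data.frame(activity = el$activity, lapse_s = 0L,
                                           stringsAsFactors = FALSE))
            res <- schedule_sequence(one, script, cfg, day_origin_s, next_id)
          } else {
            res <- list(events = list(), instances = list(), next_id = next_id)
          }
        }
        day_ev <- c(day_ev, res$events)
        day_inst <- c(day_inst, res$instances)
        next_id <- res$next_id
      }
      day_df <- if (length(day_ev)) do.call(rbind, day_ev) else NULL

      # Missing noise, per day, in scheduled order.
      if (!is.null(day_df) && nrow(day_df) > 0L) {
        miss <- vapply(day_df$sensor, function(s) missing_prob_for(ctx, s), 0)
        keep <- stats::runif(nrow(day_df)) >= miss
        day_df <- day_df[keep, , drop = FALSE]
      }
      act_events[[d + 1L]] <- day_df
      instances <- c(instances, day_inst)
    }

    act_df <- do.call(rbind, Filter(Negate(is.null), act_events))
    inst_df <- if (length(instances)) {
      data.frame(
        activity = vapply(instances, `[[`, "", "activity"),
        start_time = as_utc(as.POSIXct(vapply(instances, `[[`, 0, "start_s"),
                                       origin = "1970-01-01", tz = "UTC")),
        end_time = as_utc(as.POSIXct(vapply(instances, `[[`, 0, "end_s"),
                                     origin = "1970-01-01", tz = "UTC")),
        pattern_index = vapply(instances, `[[`, 0L, "pattern_index"),
        n_events = 0L,
        stringsAsFactors = FALSE
      )
    } else empty_instances()

    # Boundary markers on the surviving events of each instance.
    marker <- character(0)
    if (!is.null(act_df) && nrow(act_df) > 0L) {
      marker <- rep("", nrow(act_df))
      for (id in unique(act_df$instance)) {
        rows <- which(act_df$instance == id)
        rows <- rows[order(act_df$time_s[rows])]
        inst_df$n_events[id] <- length(rows)
        if (length(rows) == 1L) {
          marker[rows] <- "start+end"
        } else {
          marker[rows[1]] <- "start"
          marker[rows[length(rows)]] <- "end"
        }
      }
      act_df <- data.frame(
        timestamp = as_utc(as.POSIXct(act_df$time_s, origin = "1970-01-01", tz = "UTC")),
        sensor = act_df$sensor, label = act_df$label, marker = marker,
        stringsAsFactors = FALSE
      )
    } else {
      act_df <- empty_events()
    }

    events <- sort_events(rbind(act_df, do.call(rbind, noise_events)))
    structure(
      list(events = events, instances = inst_df,
           span = c(cfg$start_date, cfg$start_date + n_days - 1L)),
      class = "labelled_dataset"
    )
  })
}

#' Apply missing noise to a set of scheduled events
#'
#' Each event whose label is not `None` is independently dropped with its
#' sensor's miss probability; surviving events keep their timestamps.
#' Exposed mainly for calibration experiments — [run_simulation()] applies
#' missing noise internally.
#'
#' @param events an event data frame (`timestamp`, `sensor`, `label`, ...).
#' @param ctx a `context_knowledge`.
#' @return the surviving subset of `events`.
#' @export
apply_missing_noise <- function(events, ctx) {
  if (nrow(events) == 0L) return(events)
  miss <- vapply(events$sensor, function(s) missing_prob_for(ctx, s), 0)
  miss[events$label == "None"] <- 0
  keep <- stats::runif(nrow(events)) >= miss
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.labelled_dataset <- function(x, ...) {
  cat("Labelled sensor-event dataset: ", nrow(x$events), " event(s) (",
      sum(x$events$label == "None"), " noise), ",
      nrow(x$instances), " activity instance(s), ",
      format(x$span[1]), " to ", format(x$span[2]), "\n", sep = "")
  invisible(x)
}
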