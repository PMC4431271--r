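#' Binning specification for sensor-frequency histograms
#'
#' Dataset similarity is judged on per-sensor occurrence histograms over a
#' grid of equal time intervals. Five minutes is the default interval: small
#' enough to resolve activity structure (activities of daily living last
#' minutes to tens of minutes) while keeping per-interval counts meaningful.
#'
#' @param interval_s interval width in seconds; must divide 86400.
#' @param period_days number of days covered; `NULL` lets consumers derive
#'   it from the data.
#' @return a `binning_spec` list.
#' @export
binning_spec <- function(interval_s = 300L, period_days = NULL) {
  interval_s <- as.integer(interval_s)
  stopifnot(interval_s > 0L, SECONDS_PER_DAY %% interval_s == 0L)
  if (!is.null(period_days)) {
    period_days <- as.integer(period_days)
    stopifnot(period_days >= 1L)
  }
  structure(list(interval_s = interval_s, period_days = period_days),
            class = "binning_spec")
}

#' Bin a dataset into per-sensor interval histograms
#'
#' Each event lands in interval `floor(t / interval_s)` of its day, counted
#' from `origin` (midnight of the dataset's first day by default); the days
#' are concatenated in order, so a 5-day period at 300 s yields histograms
#' of length 1440 (5 x 288).
#'
#' @param ds a `labelled_dataset` or an event data frame.
#' @param spec a [binning_spec()]; its `period_days` (or the data's span)
#'   fixes the histogram length.
#' @param origin `POSIXct` start of the period; defaults to midnight (UTC)
#'   of the earliest event's day.
#' @param sensors optional sensor names; defaults to the sensors present.
#'   Sensors without events get all-zero histograms.
#' @return named list, sensor name to integer count vector.
#' @export
bin_events <- function(ds, spec = binning_spec(), origin = NULL, sensors = NULL) {
  ev <- if (inherits(ds, "labelled_dataset")) ds$events else ds
  if (is.null(origin)) {
    origin <- if (nrow(ev) > 0L) {
      as_utc(as.POSIXct(as.Date(min(ev$timestamp), tz = "UTC"), tz = "UTC"))
    } else {
      as_utc(as.POSIXct("1970-01-01", tz = "UTC"))
    }
  }
  offset <- as.numeric(ev$timestamp) - as.numeric(origin)
  period_days <- spec$period_days
  if (is.null(period_days)) {
    period_days <- if (nrow(ev) > 0L) {
      as.integer(max(floor(offset / SECONDS_PER_DAY)) + 1L)
    } else 1L
  }
  n_bins <- period_days * (SECONDS_PER_DAY %/% spec$interval_s)
  if (nrow(ev) > 0L && (any(offset < 0) || any(offset >= period_days * SECONDS_PER_DAY))) {
    stop("event outside the binning period", call. = FALSE)
  }
  if (is.null(sensors)) sensors <- sort(unique(ev$sensor))
  idx <- floor(offset / spec$interval_s) + 1L
  out <- lapply(sensors, function(s) {
    counts <- integer(n_bins)
    tab <- tabulate(idx[ev$sensor == s], nbins = n_bins)
    counts + as.integer(tab)
  })
  names(out) <- sensors
  out
}

#' Build a 2xK contingency table from two sensor histograms
#'
#' Rows are the two datasets' count vectors; intervals in which neither
#' dataset saw an activation carry no information about the shared
#' frequency distribution and are dropped, which also keeps the exact test
#' tractable.
#'
#' @param hA,hB equal-length non-negative integer count vectors.
#' @return a 2xK integer matrix (rows `A`, `B`).
#' @export
build_contingency <- function(hA, hB) {
  stopifnot(length(hA) == length(hB))
  keep <- (hA + hB) > 0
  if (!any(keep)) {
    stop("no informative intervals: both histograms are all-zero", call. = FALSE)
  }
  tab <- rbind(A = as.integer(hA[keep]), B = as.integer(hB[keep]))
  tab
}

# Log-probability of row `a` under the multivariate hypergeometric null with
# column sums `cs`, first-row sum `r1` and total `N`.
table_logprob <- function(a, cs, r1, N) {
  sum(lchoose(cs, a)) - lchoose(N, r1)
}

# Exact two-sided p-value by depth-first enumeration of every 2xK table with
# the observed margins.
fisher_exact_enumerate <- function(tab, tie_tol = 1e-7) {
  cs <- colSums(tab)
  r1 <- sum(tab[1, ])
  N <- sum(tab)
  K <- length(cs)
  logp_obs <- table_logprob(tab[1, ], cs, r1, N)
  cutoff <- logp_obs + log1p(tie_tol)
  suffix <- rev(cumsum(rev(cs)))  # suffix[j] = cs[j] + ... + cs[K]
  psum <- 0
  recurse <- function(j, rem, logacc) {
    if (j > K) {
      if (rem == 0L && logacc - lchoose(N, r1) <= cutoff) {
        psum <<- psum + exp(logacc - lchoose(N, r1))
      }
      return(invisible())
    }
    tail_cap <- if (j < K) suffix[j + 1L] else 0
    lo <- max(0, rem - tail_cap)
    hi <- min(cs[j], rem)
    if (lo > hi) return(invisible())
    for (a in lo:hi) {
      recurse(j + 1L, rem - a, logacc + lchoose(cs[j], a))
    }
  }
  recurse(1L, r1, 0)
  min(psum, 1)
}

#' Fisher's exact test for a 2xK contingency table
#'
#' Tests the null hypothesis that both rows were drawn from the same
#' frequency distribution. Conditional on the margins, a table has the
#' multivariate hypergeometric probability
#' \deqn{P(T) = \prod_j \binom{c_j}{a_j} \Big/ \binom{N}{r_1},}
#' and the two-sided p-value sums \eqn{P(T)} over every margin-compatible
#' table at most as probable as the observed one (with a relative tie
#' tolerance of `1e-7`). When the margins admit more than `max_tables`
#' tables (bounded above by \eqn{\prod_j (c_j + 1)}), the sum is replaced by
#' a Monte-Carlo estimate over `n_mc` tables drawn from the null with fixed
#' margins (Patefield's algorithm via [stats::r2dtable()]), with the
#' add-one estimator \eqn{p = (1 + \#\{P(T^*) \le P(obs)\}) / (n_{mc} + 1)}.
#'
#' Fisher's exact test is preferred here over the chi-squared test because
#' interval counts are mostly 0-2, far below chi-squared's validity regime.
#'
#' @param table a 2xK matrix of non-negative integer counts. Rows must have
#'   positive sums; all-zero columns are permitted and carry no weight.
#' @param seed optional seed for the Monte-Carlo branch (the caller's RNG
#'   state is preserved); if `NULL` the current RNG stream is used.
#' @param max_tables switch point between exact enumeration and Monte Carlo.
#' @param n_mc number of Monte-Carlo tables.
#' @return a list with `p.value`, `mode` (`"exact"` or `"monte-carlo"`) and
#'   `n_tables_bound` (the enumeration-size upper bound used for the
#'   switch).
#' @examples
#' fisher_exact(rbind(c(3, 1), c(1, 3)))  # p ~ 0.4857
#' @export
fisher_exact <- function(table, seed = NULL, max_tables = 1e6, n_mc = 1e4) {
  tab <- as.matrix(table)
  if (nrow(tab) != 2L) stop("fisher_exact expects a 2xK table", call. = FALSE)
  if (any(tab < 0) || any(tab != floor(tab))) {
    stop("fisher_exact expects non-negative integer counts", call. = FALSE)
  }
  rs <- rowSums(tab)
  if (any(rs == 0) || sum(tab) == 0) {
    stop("degenerate margins: each row needs at least one count", call. = FALSE)
  }
  cs <- colSums(tab)
  n_bound <- prod(cs + 1)

  if (n_bound <= max_tables) {
    return(list(p.value = fisher_exact_enumerate(tab), mode = "exact",
                n_tables_bound = n_bound))
  }

  draw <- function() {
    r1 <- rs[1]; N <- sum(tab)
    logp_obs <- table_logprob(tab[1, ], cs, r1, N)
    cutoff <- logp_obs + log1p(1e-7)
    tabs <- stats::r2dtable(n_mc, rs, cs)
    logp_star <- vapply(tabs, function(t) table_logprob(t[1, ], cs, r1, N), 0)
    (1 + sum(logp_star <= cutoff)) / (n_mc + 1)
  }
  p <- if (is.null(seed)) draw() else with_seed(seed, draw())
  list(p.value = p, mode = "monte-carlo", n_tables_bound = n_bound)
}

#' Assemble a dataset-comparison report
#'
#' @param p_values named numeric vector of per-sensor p-values (`NA` for
#'   sensors that could not be tested).
#' @param mode optional character vector of test modes per sensor.
#' @param binning the [binning_spec()] used.
#' @return a `comparison_report` with `per_sensor` (data frame `sensor`,
#'   `p_value`, `mode`) and `mean_p`, the unweighted arithmetic mean of the
#'   non-`NA` per-sensor p-values — the similarity score of the two
#'   datasets.
#' @export
comparison_report <- function(p_values, mode = NULL, binning = NULL) {
  stopifnot(is.numeric(p_values))
  if (is.null(mode)) mode <- rep(NA_character_, length(p_values))
  per_sensor <- data.frame(
    sensor = if (is.null(names(p_values))) as.character(seq_along(p_values))
             else names(p_values),
    p_value = as.numeric(p_values),
    mode = mode,
    stringsAsFactors = FALSE
  )
  structure(
    list(per_sensor = per_sensor,
         mean_p = mean(per_sensor$p_value, na.rm = TRUE),
         binning = binning),
    class = "comparison_report"
  )
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Dataset comparison (Fisher's exact test per sensor)\n")
  if (!is.null(x$binning)) {
    cat("  interval: ", x$binning$interval_s, " s\n", sep = "")
  }
  df <- x$per_sensor
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-28s p = %s%s\n", df$sensor[i],
                ifelse(is.na(df$p_value[i]), "NA", format(round(df$p_value[i], 4))),
                ifelse(is.na(df$mode[i]), "", paste0(" (", df$mode[i], ")"))))
  }
  cat(sprintf("  mean p-value: %.4f\n", x$mean_p))
  invisible(x)
}

#' Compare two sensor-event datasets
#'
#' Bins both datasets on the same interval grid (day `k` of one dataset is
#' aligned with day `k` of the other at matching clock time), builds a 2xK
#' contingency table per sensor from the interval counts, runs
#' [fisher_exact()] on each, and averages the per-sensor p-values. Under
#' the null hypothesis that both datasets arise from the same behaviour,
#' per-sensor p-values are large; the mean p-value is the similarity score.
#'
#' @param dsA,dsB `labelled_dataset` objects (or event data frames).
#' @param spec a [binning_spec()]; a `NULL` `period_days` is replaced by the
#'   larger of the two datasets' spans.
#' @param sensors sensors to test; defaults to all sensors seen in either
#'   dataset. Sensors present in only one dataset cannot be tested: they are
#'   reported with `NA` and excluded from the mean, with a warning.
#' @param seed seed forwarded to the Monte-Carlo branch of [fisher_exact()].
#' @param max_tables,n_mc forwarded to [fisher_exact()].
#' @return a [comparison_report()].
#' @export
compare_datasets <- function(dsA, dsB, spec = binning_spec(), sensors = NULL,
                             seed = NULL, max_tables = 1e6, n_mc = 1e4) {
  evA <- if (inherits(dsA, "labelled_dataset")) dsA$events else dsA
  evB <- if (inherits(dsB, "labelled_dataset")) dsB$events else dsB
  if (is.null(spec$period_days)) {
    span_days <- function(ev) {
      if (nrow(ev) == 0L) return(1L)
      o <- as.numeric(as.POSIXct(as.Date(min(ev$timestamp), tz = "UTC"), tz = "UTC"))
      as.integer(floor((max(as.numeric(ev$timestamp)) - o) / SECONDS_PER_DAY) + 1L)
    }
    spec <- binning_spec(spec$interval_s, max(span_days(evA), span_days(evB)))
  }
  seenA <- unique(evA$sensor); seenB <- unique(evB$sensor)
  if (is.null(sensors)) sensors <- sort(union(seenA, seenB))
  common <- intersect(intersect(sensors, seenA), seenB)
  if (length(common) == 0L) stop("no common sensors to compare", call. = FALSE)
  only_one <- setdiff(sensors, common)
  if (length(only_one) > 0L) {
    warning("sensor(s) present in only one dataset, excluded from mean p-value: ",
            paste(only_one, collapse = ", "), call. = FALSE)
  }

  hA <- bin_events(evA, spec, sensors = sensors)
  hB <- bin_events(evB, spec, sensors = sensors)
  p <- stats::setNames(rep(NA_real_, length(sensors)), sensors)
  mode <- stats::setNames(rep(NA_character_, length(sensors)), sensors)
  for (s in common) {
    tab <- build_contingency(hA[[s]], hB[[s]])
    res <- fisher_exact(tab, seed = seed, max_tables = max_tables, n_mc = n_mc)
    p[s] <- res$p.value
    mode[s] <- res$mode
  }
  comparison_report(p, mode = unname(mode), binning = spec)
}
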