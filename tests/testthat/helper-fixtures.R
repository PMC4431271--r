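# Shared helpers: tiny scripts/contexts built in code, plus brute-force
# Fisher oracles kept deliberately independent of the package's enumeration.

minimal_script_lines <- function(days = 1L,
                                 pattern = "1.0 cupSens@0 cupSens@60 cupSens@120",
                                 noise = character(0)) {
  c("DAYS", as.character(days),
    "ACTIVITIES",
    "MakeCoffee 1",
    pattern,
    "BEHAVIOURS",
    "Prob 1.0",
    "S 9:00 - 10:00 MakeCoffee@0",
    "NOISE",
    noise)
}

minimal_context_json <- function(miss = 0.0, extra_sensors = character(0)) {
  sens <- c("cupSens", extra_sensors)
  paste0('{"objects": [',
         paste(sprintf('{"name": "o%d", "location": "kitchen", "attached_sensor": "%s"}',
                       seq_along(sens), sens), collapse = ","),
         '], "sensors": [',
         paste(sprintf('{"name": "%s", "type": "contact"}', sens), collapse = ","),
         '], "error_models": {"contact": ', miss, '}}')
}

# Exact two-sided Fisher p-value for a 2x2 table by direct hypergeometric
# enumeration over the first cell (closed form via dhyper).
oracle_fisher_2x2 <- function(tab, tie_tol = 1e-7) {
  c1 <- sum(tab[, 1]); c2 <- sum(tab[, 2]); r1 <- sum(tab[1, ])
  a <- max(0L, r1 - c2):min(c1, r1)
  probs <- stats::dhyper(a, c1, c2, r1)
  p_obs <- stats::dhyper(tab[1, 1], c1, c2, r1)
  sum(probs[probs <= p_obs * (1 + tie_tol)])
}

# Exact two-sided Fisher p-value for a 2x3 table by a double loop over the
# first row, with explicit multivariate hypergeometric probabilities.
oracle_fisher_2x3 <- function(tab, tie_tol = 1e-7) {
  cs <- colSums(tab); r1 <- sum(tab[1, ]); N <- sum(tab)
  prob_of <- function(a) prod(choose(cs, a)) / choose(N, r1)
  p_obs <- prob_of(tab[1, ])
  p <- 0
  for (a1 in 0:min(cs[1], r1)) {
    for (a2 in 0:min(cs[2], r1 - a1)) {
      a3 <- r1 - a1 - a2
      if (a3 >= 0 && a3 <= cs[3]) {
        pr <- prob_of(c(a1, a2, a3))
        if (pr <= p_obs * (1 + tie_tol)) p <- p + pr
      }
    }
  }
  p
}

# Shift every timestamp of a dataset by `by_s` seconds.
shift_dataset <- function(ds, by_s) {
  ds$events$timestamp <- ds$events$timestamp + by_s
  ds
}

# Reassign the dataset's timestamps uniformly at random among its events,
# destroying the time structure while keeping the time and sensor multisets.
shuffle_dataset <- function(ds, seed) {
  set.seed(seed)
  ev <- ds$events
  ev$timestamp <- ev$timestamp[sample.int(nrow(ev))]
  ev$marker <- ""
  ds$events <- adlsim:::sort_events(ev)
  ds
}
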