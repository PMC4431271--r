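noise_free_pair <- function(days = 1L) {
  list(script = parse_adl_script(minimal_script_lines(days = days)),
       ctx = parse_context(minimal_context_json()))
}

test_that("a forced deterministic setup yields exact event counts and markers", {
  px <- noise_free_pair(1L)
  ds <- run_simulation(px$script, px$ctx, simulation_config(seed = 11))
  expect_equal(nrow(ds$events), 3L)
  expect_equal(nrow(ds$instances), 1L)
  expect_equal(ds$events$marker, c("start", "", "end"))
  expect_true(all(ds$events$label == "MakeCoffee"))

  px5 <- noise_free_pair(5L)
  ds5 <- run_simulation(px5$script, px5$ctx, simulation_config(seed = 11))
  expect_equal(nrow(ds5$events), 15L)
  expect_equal(nrow(ds5$instances), 5L)
  expect_equal(sum(ds5$events$marker == "start"), 5L)
  expect_equal(sum(ds5$events$marker == "end"), 5L)
})

test_that("per-hour positive noise at p = 1 fires once per hour, labelled None", {
  script <- parse_adl_script(minimal_script_lines(noise = "hallSens 1.0"))
  ctx <- parse_context(minimal_context_json(extra_sensors = "hallSens"))
  ds <- run_simulation(script, ctx, simulation_config(seed = 3))
  noise <- ds$events[ds$events$sensor == "hallSens", ]
  expect_equal(nrow(noise), 24L)
  expect_true(all(noise$label == "None"))
  expect_true(all(noise$marker == ""))
  # k-th noise event falls inside hour k
  hours <- as.integer(format(noise$timestamp, "%H", tz = "UTC"))
  expect_equal(hours, 0:23)
  # label conservation: everything else is activity-labelled
  expect_equal(sum(ds$events$label == "None"), 24L)
  expect_equal(nrow(ds$events), 27L)

  # all probabilities zero -> no noise at all
  set.seed(1)
  empty <- generate_positive_noise_day(as.Date("2015-01-01"),
                                       c(hallSens = 0, cupSens = 0))
  expect_equal(nrow(empty), 0L)
})

test_that("noise rate is recovered empirically (p = 0.1 per hour)", {
  set.seed(20)
  n_days <- 1000L
  counts <- vapply(seq_len(n_days), function(i) {
    nrow(generate_positive_noise_day(as.Date("2015-01-01") + (i %% 30),
                                     c(cupSens = 0.1)))
  }, 0L)
  m <- mean(counts)
  expect_gte(m, 2.2)  # expectation 24 * 0.1 = 2.4
  expect_lte(m, 2.6)
  expect_lte(max(counts), 24L)
})

test_that("behaviour-model and pattern selection match their probabilities", {
  models <- list(list(probability = 2 / 7, name = "weekend"),
                 list(probability = 5 / 7, name = "weekday"))
  set.seed(4)
  draws <- replicate(1e4, select_behaviour_model(models)$name)
  expect_equal(mean(draws == "weekend"), 2 / 7, tolerance = 0.02 / (2 / 7))

  act <- list(patterns = list(list(probability = 0.5), list(probability = 0.5)))
  set.seed(5)
  picks <- replicate(1e4, select_pattern(act))
  expect_equal(mean(picks == 1L), 0.5, tolerance = 0.02 / 0.5)

  single <- list(list(probability = 1, name = "only"))
  set.seed(6)
  expect_true(all(replicate(50, select_behaviour_model(single)$name) == "only"))
  expect_error(select_behaviour_model(list()), "no behaviour models")
})

test_that("Gaussian time lapses have the configured moments and are never negative", {
  cfg <- simulation_config(seed = 1)
  expect_identical(sample_time_lapse(0, cfg), 0)

  set.seed(7)
  x <- replicate(1e5, sample_time_lapse(20, cfg))
  expect_gte(mean(x), 19.9); expect_lte(mean(x), 20.1)
  expect_gte(sd(x), 4.9); expect_lte(sd(x), 5.1)

  set.seed(8)
  y <- replicate(1e5, sample_time_lapse(1, cfg))
  expect_true(all(y >= 0))
})

test_that("sequences start uniformly in their slot and respect activity lapses", {
  px <- noise_free_pair(1L)
  starts <- numeric(200)
  for (r in seq_along(starts)) {
    ds <- run_simulation(px$script, px$ctx, simulation_config(seed = 1000 + r))
    t0 <- min(ds$events$timestamp)
    starts[r] <- as.numeric(t0) - as.numeric(as.POSIXct("2015-01-01", tz = "UTC"))
  }
  expect_true(all(starts >= 9 * 3600 & starts < 10 * 3600))
  # timestamps are floored to whole seconds, so occasional ties are expected
  ks <- suppressWarnings(stats::ks.test(starts, "punif", 9 * 3600, 10 * 3600))
  expect_gt(ks$p.value, 0.01)
})

test_that("alterations execute with their stated probability", {
  mk <- function(p) parse_adl_script(c(
    "DAYS", "1", "ACTIVITIES",
    "MakeCoffee 1", "1.0 cupSens@0",
    "BEHAVIOURS", "Prob 1.0",
    paste("A", p, "16:00 - 18:00 MakeCoffee"),
    "NOISE"))
  ctx <- parse_context(minimal_context_json())
  run_n <- function(script, n) {
    vapply(seq_len(n), function(r) {
      nrow(run_simulation(script, ctx, simulation_config(seed = r))$events) > 0
    }, NA)
  }
  expect_true(all(!run_n(mk(0), 30)))
  expect_true(all(run_n(mk(1), 30)))
  freq <- mean(run_n(mk(0.5), 1e3))
  expect_gte(freq, 0.45); expect_lte(freq, 0.55)
})

test_that("missing noise drops events at the sensor's rate without rescheduling", {
  ctx_some <- parse_context(minimal_context_json(miss = 0.0311))
  n <- 1e5
  ev <- data.frame(
    timestamp = as.POSIXct("2015-01-01", tz = "UTC") + seq_len(n),
    sensor = "cupSens", label = "MakeCoffee", marker = "",
    stringsAsFactors = FALSE)
  set.seed(9)
  kept <- apply_missing_noise(ev, ctx_some)
  retention <- nrow(kept) / n
  expect_gte(retention, 0.967); expect_lte(retention, 0.971)
  # surviving events keep their timestamps
  expect_true(all(kept$timestamp %in% ev$timestamp))

  ctx0 <- parse_context(minimal_context_json(miss = 0))
  expect_identical(apply_missing_noise(ev, ctx0), ev)
  ctx1 <- parse_context(minimal_context_json(miss = 1))
  expect_equal(nrow(apply_missing_noise(ev, ctx1)), 0L)
  # noise events are never dropped
  evn <- ev; evn$label <- "None"
  expect_equal(nrow(apply_missing_noise(evn, ctx1)), n)
})

test_that("simulation is deterministic under a fixed seed and preserves order", {
  fx <- make_fixture("paper_like")
  a <- run_simulation(fx$script, fx$ctx, simulation_config(seed = 42))
  b <- run_simulation(fx$script, fx$ctx, simulation_config(seed = 42))
  expect_identical(a, b)
  c2 <- run_simulation(fx$script, fx$ctx, simulation_config(seed = 43))
  expect_false(identical(a$events, c2$events))

  # the caller's RNG stream is untouched
  set.seed(123); before <- runif(3)
  set.seed(123); invisible(run_simulation(fx$script, fx$ctx,
                                          simulation_config(seed = 42)))
  expect_identical(runif(3), before)

  # within every instance, sensor order equals pattern order
  px <- noise_free_pair(3L)
  # distinct sensors so order is observable
  script <- parse_adl_script(minimal_script_lines(
    days = 3L, pattern = "1.0 cupSens@0 potSens@1 cupSens@1"))
  ctx <- parse_context(minimal_context_json(extra_sensors = "potSens"))
  for (s in 1:20) {
    ds <- run_simulation(script, ctx, simulation_config(seed = s))
    act <- ds$events[ds$events$label != "None", ]
    expect_equal(act$sensor, rep(c("cupSens", "potSens", "cupSens"), 3),
                 info = paste("seed", s))
  }
})

test_that("days override and span bookkeeping work", {
  px <- noise_free_pair(1L)
  ds <- run_simulation(px$script, px$ctx, simulation_config(seed = 2), days = 4L)
  expect_equal(nrow(ds$instances), 4L)
  expect_equal(ds$span, as.Date(c("2015-01-01", "2015-01-04")))
  expect_error(run_simulation(parse_adl_script(minimal_script_lines(
    pattern = "1.0 ghostSens@0")), px$ctx, simulation_config()),
    "invalid script")
})
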