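test_that("events are binned into per-day intervals, concatenated across days", {
  mk_ev <- function(times, sensor = "fridgeSens") data.frame(
    timestamp = as.POSIXct(times, tz = "UTC"), sensor = sensor,
    label = "x", marker = "", stringsAsFactors = FALSE)

  ev <- mk_ev(c("2015-01-01 09:01:00", "2015-01-01 09:04:00"))
  h <- bin_events(ev, binning_spec(300, 1))
  expect_length(h$fridgeSens, 288L)
  nine <- 9 * 3600 / 300 + 1  # the 09:00-09:05 bin
  expect_equal(h$fridgeSens[nine], 2L)
  expect_equal(sum(h$fridgeSens), 2L)

  h5 <- bin_events(ev, binning_spec(300, 5))
  expect_length(h5$fridgeSens, 1440L)  # 5 x 288

  # day 2 events land after day 1's 288 bins
  ev2 <- mk_ev(c("2015-01-01 00:00:00", "2015-01-02 00:02:00"))
  h2 <- bin_events(ev2, binning_spec(300, 2))
  expect_equal(which(h2$fridgeSens > 0), c(1L, 289L))

  h0 <- bin_events(adlsim:::empty_events(), binning_spec(300, 1),
                   sensors = "fridgeSens")
  expect_equal(h0$fridgeSens, integer(288))
  expect_error(bin_events(ev2, binning_spec(300, 1)), "outside")
  expect_error(binning_spec(7), "interval_s")
})

test_that("contingency tables drop uninformative columns", {
  tab <- build_contingency(c(2, 0, 1), c(2, 0, 1))
  expect_equal(unname(tab), rbind(c(2L, 1L), c(2L, 1L)))
  expect_error(build_contingency(c(0, 0), c(0, 0)), "all-zero")
  expect_equal(unname(build_contingency(c(1, 0), c(0, 2))),
               rbind(c(1L, 0L), c(0L, 2L)))
})

test_that("exact p-values match brute-force enumeration on 2x2 tables", {
  for (a in 0:4) for (b in 0:4) for (c in 0:4) for (d in 0:4) {
    tab <- rbind(c(a, b), c(c, d))
    if (any(rowSums(tab) == 0)) next
    res <- fisher_exact(tab)
    expect_equal(res$mode, "exact")
    expect_equal(res$p.value, oracle_fisher_2x2(tab), tolerance = 1e-12,
                 info = paste(a, b, c, d))
  }
})

test_that("exact p-values match brute-force enumeration on 2x3 tables", {
  cells <- expand.grid(a1 = 0:2, a2 = 0:2, a3 = 0:2,
                       b1 = 0:2, b2 = 0:2, b3 = 0:2)
  cells <- cells[seq(1, nrow(cells), by = 3), ]  # a grid, thinned for speed
  for (i in seq_len(nrow(cells))) {
    tab <- matrix(as.numeric(cells[i, ]), nrow = 2, byrow = TRUE)
    if (any(rowSums(tab) == 0)) next
    res <- fisher_exact(tab)
    expect_equal(res$p.value, oracle_fisher_2x3(tab), tolerance = 1e-12,
                 info = paste(cells[i, ], collapse = ","))
  }
})

test_that("reference tables reproduce known exact p-values", {
  expect_equal(fisher_exact(rbind(c(2, 0), c(2, 0)))$p.value, 1)
  expect_equal(fisher_exact(rbind(c(3, 1), c(1, 3)))$p.value, 0.4857143,
               tolerance = 1e-6)
  expect_equal(fisher_exact(rbind(c(2, 1), c(2, 1)))$p.value, 1)
  # independent cross-check against R's own implementation
  for (tab in list(rbind(c(3, 1), c(1, 3)), rbind(c(5, 2), c(1, 4)),
                   rbind(c(2, 1, 3), c(3, 1, 0)))) {
    expect_equal(fisher_exact(tab)$p.value,
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
  expect_error(fisher_exact(rbind(c(0, 0), c(1, 2))), "degenerate")
  expect_error(fisher_exact(rbind(c(1.5, 1), c(1, 1))), "integer")
})

test_that("p-values are invariant under row swap and column permutation", {
  set.seed(31)
  for (r in 1:20) {
    K <- sample(2:4, 1)
    tab <- matrix(rpois(2 * K, 1.5), nrow = 2)
    if (any(rowSums(tab) == 0)) next
    p <- fisher_exact(tab)$p.value
    expect_equal(fisher_exact(tab[2:1, ])$p.value, p, tolerance = 1e-12)
    perm <- sample(K)
    expect_equal(fisher_exact(tab[, perm, drop = FALSE])$p.value, p,
                 tolerance = 1e-12)
    expect_gte(p, 0); expect_lte(p, 1)
  }
})

test_that("Monte-Carlo mode agrees with exact mode within 3 standard errors", {
  tabs <- list(rbind(c(3, 1, 2), c(1, 3, 0)),
               rbind(c(4, 0), c(1, 3)),
               rbind(c(2, 2, 1), c(1, 0, 3)))
  n_mc <- 1e4
  for (tab in tabs) {
    p_exact <- fisher_exact(tab)$p.value
    mc <- fisher_exact(tab, seed = 99, max_tables = 0, n_mc = n_mc)
    expect_equal(mc$mode, "monte-carlo")
    se <- sqrt(p_exact * (1 - p_exact) / n_mc) + 1 / n_mc
    expect_lte(abs(mc$p.value - p_exact), 3 * se)
  }
})

test_that("comparison reports average per-sensor p-values exactly", {
  p <- c(s1 = 0.2, s2 = 0.9, s3 = 1)
  rep <- comparison_report(p)
  expect_identical(rep$mean_p, mean(p))
  # NA sensors are excluded
  rep2 <- comparison_report(c(p, s4 = NA))
  expect_identical(rep2$mean_p, mean(p))
})

test_that("a dataset compared with an exact copy of itself gives p = 1", {
  fx <- make_fixture("paper_like")
  ds <- run_simulation(fx$script, fx$ctx, simulation_config(seed = 21))
  rep <- compare_datasets(ds, ds, binning_spec(300, 5), seed = 1)
  expect_equal(rep$per_sensor$p_value, rep(1, 8), tolerance = 1e-9)
  expect_equal(rep$mean_p, 1, tolerance = 1e-9)
})

test_that("sensors present in only one dataset are excluded with a warning", {
  mk <- function(sensors) data.frame(
    timestamp = as.POSIXct("2015-01-01 09:00:00", tz = "UTC") + seq_along(sensors),
    sensor = sensors, label = "x", marker = "", stringsAsFactors = FALSE)
  dsA <- mk(c("fridgeSens", "fridgeSens", "panSens"))
  dsB <- mk(c("fridgeSens", "fridgeSens"))
  expect_warning(rep <- compare_datasets(dsA, dsB, binning_spec(300, 1)),
                 "panSens")
  expect_true(is.na(rep$per_sensor$p_value[rep$per_sensor$sensor == "panSens"]))
  expect_false(is.na(rep$mean_p))
  expect_error(compare_datasets(mk("a"), mk("b"), binning_spec(300, 1)),
               "no common sensors")
})
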