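# Engine: determinism, seeding, configuration validation, conservation and
# bookkeeping of full runs.

fixtureRun <- function(scenario = 1, seed = 7, ...) {
  runGC(smallGCConfig(scenario = scenario, ...), seed = seed)
}

.configAsListPublic <- function(cfg) kineticGC:::.configAsList(cfg)

test_that("identical (config, seed) gives identical results", {
  a <- fixtureRun(scenario = 1, seed = 13)
  b <- fixtureRun(scenario = 1, seed = 13)
  expect_identical(timeSeries(a), timeSeries(b))
  expect_identical(cellEvents(a), cellEvents(b))
  expect_identical(ocLog(a), ocLog(b))
  expect_identical(agLedger(a), agLedger(b))
  # a different seed gives a different trajectory
  c <- fixtureRun(scenario = 1, seed = 14)
  expect_false(identical(timeSeries(a), timeSeries(c)))
})

test_that("the small fixture completes quickly with non-empty logs", {
  t0 <- Sys.time()
  res <- fixtureRun(scenario = 1, seed = 7)
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 10)
  ts <- timeSeries(res)
  expect_gt(nrow(ts), 0)
  expect_gt(sum(ts$n_cb + ts$n_cc), 0)
  expect_gt(nrow(cellEvents(res)), 0)
})

test_that("time sampling matches the configured cadence and duration", {
  res <- fixtureRun(scenario = 0, seed = 3)
  ts <- timeSeries(res)
  hours <- sort(unique(ts$time_h))
  expect_equal(hours, 0:48)               # 2 days, hourly
  expect_equal(nrow(ts), 49 * 3)          # three clones
  # a 21-day configuration at dt = 7.2 s is exactly 252,000 steps
  cfg <- gcConfig(scenario = 0)
  expect_equal(cfg@durationDays * 86400 / cfg@dt, 252000)
})

test_that("replicate seeding is counter-based and order-stable", {
  expect_equal(childSeed(1, 1:3), c(1, 1000004, 2000007))
  cfg <- smallGCConfig(scenario = 2, durationDays = 1, masterSeed = 5,
                       nReplicates = 2)
  reps <- runReplicates(cfg)
  expect_length(reps, 2L)
  expect_equal(vapply(reps, runSeed, integer(1)),
               childSeed(5, 1:2))
  solo <- runGC(cfg, childSeed(5, 1))
  expect_identical(timeSeries(reps[[1]]), timeSeries(solo))
})

test_that("antigen ledger balances and cell bookkeeping closes", {
  for (sc in 0:2) {
    res <- fixtureRun(scenario = sc, seed = 21 + sc)
    led <- agLedger(res)
    expect_equal(led[["ag_initial"]],
                 led[["ag_on_sites"]] + led[["ag_in_cells"]] +
                   led[["ag_in_oc"]] + led[["ag_lost_apoptosis"]],
                 tolerance = 1e-8)
    # every division adds net one cell; OC and apoptosis are absorbing
    expect_equal(led[["founders"]] + led[["divisions"]],
                 led[["alive_final"]] + led[["n_oc"]] + led[["apoptosis"]])
    # captured antigen equals antigen missing from sites
    ts <- timeSeries(res)
    lastAg <- sum(ts$ag_collected_total[ts$time_h == max(ts$time_h)])
    expect_equal(led[["ag_initial"]] - led[["ag_on_sites"]], lastAg)
  }
})

test_that("cumulative series are monotone and event counters consistent", {
  res <- fixtureRun(scenario = 1, seed = 2)
  ts <- timeSeries(res)
  for (cl in unique(ts$clone_id)) {
    sub <- ts[ts$clone_id == cl, ]
    expect_false(is.unsorted(sub$n_oc_cum))
    expect_false(is.unsorted(sub$ag_collected_total))
  }
  ev <- cellEvents(res)
  expect_true(all(ev$n_associations <= ev$n_fdc_contacts))
  expect_true(all(ev$n_dissoc_no_ag + ev$n_dissoc_with_ag <=
                    ev$n_associations))
  # every cell that reached the Tfh phase collected at least one unit
  expect_true(all(ev$n_dissoc_with_ag >= 1))
})

test_that("Scenario 0 ignores kinetic phenotypes: permuting the clone
           angles leaves the trajectory identical", {
  base <- smallGCConfig(scenario = 0)
  permuted <- smallGCConfig(scenario = 0)
  permuted@clones$thetaDeg <- c(0, 90, 45)  # relabel the angles
  a <- runGC(base, seed = 31)
  b <- runGC(permuted, seed = 31)
  expect_identical(timeSeries(a)[, c("time_h", "clone_id", "n_cb", "n_cc",
                                     "n_oc_cum", "ag_collected_total")],
                   timeSeries(b)[, c("time_h", "clone_id", "n_cb", "n_cc",
                                     "n_oc_cum", "ag_collected_total")])
})

test_that("configuration validation reports offending fields", {
  expect_error(gcConfig(scenario = 3), "scenario")
  expect_error(gcConfig(durationDays = 1, dt = 7), "integer step count")
  expect_error(gcConfig(lifecycle = lifecycleParams(mutationProb = 2)),
               "mutationProb")
  expect_error(gcConfig(clones = data.frame(cloneId = c("a", "a"),
                                            thetaDeg = c(10, 20))),
               "unique")
  expect_error(gcConfig(domain = domainParams(radius = 2)), "lattice")
})

test_that("configuration files round-trip and reject unknown keys", {
  cfg <- smallGCConfig(scenario = 2, masterSeed = 9)
  f <- tempfile(fileext = ".yaml")
  writeGCConfig(cfg, f)
  back <- readGCConfig(f)
  expect_equal(.configAsListPublic(cfg), .configAsListPublic(back))
  # unknown top-level key
  bad <- tempfile(fileext = ".yaml")
  writeLines(c("scenario: 1", "bogusKey: 2"), bad)
  expect_error(readGCConfig(bad), "bogusKey")
  # unknown parameter inside a group
  bad2 <- tempfile(fileext = ".yaml")
  writeLines(c("scenario: 1", "collection:", "  pFinnish: 0.5"), bad2)
  expect_error(readGCConfig(bad2), "pFinnish")
})

test_that("run tables are written to disk", {
  res <- fixtureRun(scenario = 1, seed = 7, durationDays = 1)
  dir <- file.path(tempdir(), "gc-out-test")
  writeGCTables(res, dir)
  expect_true(file.exists(file.path(dir, "time_series.csv")))
  expect_true(file.exists(file.path(dir, "cell_events.csv")))
  expect_true(file.exists(file.path(dir, "oc_log.csv")))
  meta <- yaml::read_yaml(file.path(dir, "run_metadata.yaml"))
  expect_equal(meta$seed, 7)
  back <- read.csv(file.path(dir, "time_series.csv"))
  expect_equal(nrow(back), nrow(timeSeries(res)))
  unlink(dir, recursive = TRUE)
})
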