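#' Antigen concentration factor
#'
#' The probability weight contributed by local antigen availability: 0 with
#' an empty site, 1 at or above the per-cell saturation level, and
#' `cAg / sAg` in between.
#'
#' @param cAg antigen units at the binding site (vectorised, >= 0).
#' @param sAg saturation level in antigen units (> 0).
#' @return numeric vector in \[0, 1\].
#' @examples
#' concentrationFactor(c(0, 10, 25), sAg = 20)
#' @export
concentrationFactor <- function(cAg, sAg = 20) {
  if (sAg <= 0) stop("sAg must be > 0", call. = FALSE)
  if (any(cAg < 0)) stop("cAg must be >= 0", call. = FALSE)
  pmin(1, cAg / sAg)
}

#' Closed-form single-interaction capture probability
#'
#' Probability that one binding attempt of a free centrocyte at an antigen
#' site ends with a captured antigen unit, marginalised over the
#' geometrically distributed extraction duration:
#' \describe{
#'   \item{Scenario 0}{`affinity * pC` (binding implies capture);}
#'   \item{Scenario 2}{`pA * pC * (1 - pD)` (capture once the first
#'     post-binding dissociation test is survived);}
#'   \item{Scenario 1}{`pA * pC * (1 - pD)` times the geometric-series
#'     closure of rupture-before-completion,
#'     `(1 - pD) * pFinish / (1 - (1 - pD)(1 - pFinish))`.}
#' }
#' These are the independent oracles against which the stochastic state
#' machine is validated.
#'
#' @param scenario 0, 1 or 2.
#' @param pA,pD association and dissociation probabilities per time step.
#' @param pC concentration factor (default 1).
#' @param affinity affinity used by Scenario 0.
#' @param pFinish completion probability per extraction step.
#' @return capture probability in \[0, 1\].
#' @examples
#' f <- founderPhenotypes()
#' captureProbability(1, pA = f$pA[2], pD = f$pD[2])  # Clone-M, Scenario-1
#' @export
captureProbability <- function(scenario, pA = NA_real_, pD = NA_real_,
                               pC = 1, affinity = NA_real_,
                               pFinish = 0.04) {
  stopifnot(scenario %in% 0:2)
  if (scenario == 0) {
    if (is.na(affinity)) stop("Scenario 0 needs affinity", call. = FALSE)
    return(affinity * pC)
  }
  if (any(is.na(c(pA, pD)))) stop("need pA and pD", call. = FALSE)
  if (scenario == 2) return(pA * pC * (1 - pD))
  surv <- (1 - pD) * pFinish
  denom <- 1 - (1 - pD) * (1 - pFinish)
  if (denom <= 0) return(0)  # pD = 0 and pFinish = 0: extraction never ends
  pA * pC * (1 - pD) * surv / denom
}

#' Fresh centrocyte collection state
#'
#' @return list representing the state machine position of a collecting
#'   centrocyte: `phase` (FREE/BOUND/EXTRACTING/REFRACTORY), `phaseTimer`
#'   (remaining refractory seconds), `windowClock` (seconds in the light
#'   zone), the four event counters and `agCollected`.
#' @examples newCollectionState()
#' @export
newCollectionState <- function() {
  list(phase = "FREE", phaseTimer = 0, windowClock = 0,
       nFdcContacts = 0L, nAssociations = 0L,
       nDissocNoAg = 0L, nDissocWithAg = 0L,
       agCollected = 0L, extractionSteps = 0L)
}

#' Advance a centrocyte's collection state machine by one time step
#'
#' Reference (pure R) implementation of the per-step stochastic update used
#' by the engine. `FREE` at a site: Scenario 0 binds with probability
#' `affinity * pC` and starts extracting; Scenarios 1-2 bind with
#' `pA * pC` and enter `BOUND`. `BOUND`: dissociates with `pD`
#' (dissociation without antigen, refractory) or starts extracting.
#' `EXTRACTING`: Scenario 1 first applies the rupture test with probability
#' `pD`; survivors (and Scenarios 0/2 unconditionally) complete with
#' probability `pFinish`, transferring one antigen unit from the site.
#' `REFRACTORY` counts down to `FREE`. Draws come from R's RNG.
#'
#' @param state collection state from [newCollectionState()].
#' @param phenotype list with `pA`, `pD`, `affinity` (see
#'   [kineticPhenotype()]).
#' @param site `NULL` (no FDC site here) or a list with `agAmount`.
#' @param scenario 0, 1 or 2.
#' @param params collection parameters from [collectionParams()]; `dt` is
#'   taken from the engine default of 7.2 s unless supplied.
#' @param dt time step in seconds.
#' @return list with updated `state`, `site` and the `event` label, one of
#'   `"none"`, `"association"`, `"dissociation_without_ag"`,
#'   `"dissociation_with_ag"`.
#' @examples
#' ph <- kineticPhenotype(c(5, 0, 0, 0), 45)
#' st <- newCollectionState()
#' collectionStep(st, ph, list(agAmount = 20), scenario = 1)
#' @export
collectionStep <- function(state, phenotype, site = NULL, scenario = 1,
                           params = collectionParams(), dt = 7.2) {
  stopifnot(scenario %in% 0:2)
  if (scenario == 0 && state$phase == "BOUND")
    stop("BOUND does not exist in Scenario 0", call. = FALSE)
  event <- "none"
  toRefractory <- function(s) {
    if (params$refractoryTime > 0) {
      s$phase <- "REFRACTORY"; s$phaseTimer <- params$refractoryTime
    } else s$phase <- "FREE"
    s
  }
  if (state$phase == "REFRACTORY") {
    state$phaseTimer <- state$phaseTimer - dt
    if (state$phaseTimer <= 0) { state$phase <- "FREE"; state$phaseTimer <- 0 }
  } else if (state$phase == "FREE") {
    if (!is.null(site)) {
      pC <- concentrationFactor(site$agAmount, params$sAg)
      state$nFdcContacts <- state$nFdcContacts + 1L
      pBind <- if (scenario == 0) phenotype$affinity * pC else
        phenotype$pA * pC
      if (runif(1) < pBind) {
        state$nAssociations <- state$nAssociations + 1L
        event <- "association"
        state$phase <- if (scenario == 0) "EXTRACTING" else "BOUND"
        state$extractionSteps <- 0L
      }
    }
  } else if (state$phase == "BOUND") {
    if (runif(1) < phenotype$pD) {
      state$nDissocNoAg <- state$nDissocNoAg + 1L
      event <- "dissociation_without_ag"
      state <- toRefractory(state)
    } else state$phase <- "EXTRACTING"
  } else if (state$phase == "EXTRACTING") {
    if (!is.null(site) && site$agAmount < 1) {
      ## degenerate: nothing left to extract -> rupture without antigen
      state$nDissocNoAg <- state$nDissocNoAg + 1L
      event <- "dissociation_without_ag"
      state <- toRefractory(state)
    } else {
      ruptured <- finished <- FALSE
      if (params$ruptureBeforeCompletion) {
        if (scenario == 1 && runif(1) < phenotype$pD) ruptured <- TRUE
        if (!ruptured) {
          state$extractionSteps <- state$extractionSteps + 1L
          finished <- runif(1) < params$pFinish
        }
      } else {
        finished <- runif(1) < params$pFinish
        if (!finished && scenario == 1 && runif(1) < phenotype$pD)
          ruptured <- TRUE
        if (!ruptured) state$extractionSteps <- state$extractionSteps + 1L
      }
      if (ruptured) {
        state$nDissocNoAg <- state$nDissocNoAg + 1L
        event <- "dissociation_without_ag"
        state <- toRefractory(state)
      } else if (finished) {
        state$nDissocWithAg <- state$nDissocWithAg + 1L
        state$agCollected <- state$agCollected + 1L
        if (!is.null(site)) site$agAmount <- site$agAmount - 1
        event <- "dissociation_with_ag"
        state <- toRefractory(state)
      }
    }
  }
  list(state = state, site = site, event = event)
}

#' Monte-Carlo capture frequencies for single binding attempts
#'
#' Runs `n` independent binding attempts of the collection state machine to
#' absorption (capture, or dissociation without antigen, or no binding) in
#' compiled code and returns the capture count. Used to validate the state
#' machine against [captureProbability()].
#'
#' @param n number of attempts.
#' @param scenario 0, 1 or 2.
#' @param pA,pD,pC,affinity,pFinish as in [captureProbability()].
#' @param seed integer RNG seed.
#' @return list with `captures`, `n` and the empirical `frequency`.
#' @examples
#' simulateCaptures(1e4, 1, pA = 0.2, pD = 0.8, seed = 1)
#' @export
simulateCaptures <- function(n, scenario, pA = 0, pD = 0, pC = 1,
                             affinity = 0, pFinish = 0.04, seed = 1L) {
  cap <- cpp_simulate_captures(as.integer(n), as.integer(scenario),
                               pA, pD, pC, affinity, pFinish,
                               as.integer(seed))
  list(captures = cap, n = as.integer(n), frequency = cap / n)
}
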