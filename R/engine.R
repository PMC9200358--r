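#' Build a simulation configuration
#'
#' Assembles a validated [GCConfig-class]. Defaults reproduce the standard
#' study conditions: a 21-day reaction at dt = 7.2 s (252,000 steps) in a
#' 160-um sphere, three founder clones of identical affinity (Theta = 90,
#' 45, 0), and 30 replicates.
#'
#' @param scenario antigen-collection mechanism: 0 (affinity-based), 1
#'   (kinetic with rupture during extraction) or 2 (kinetic without
#'   rupture).
#' @param durationDays simulated days.
#' @param dt time step in seconds.
#' @param sampleEveryH time-series cadence in hours.
#' @param clones data.frame of clone definitions ([defaultClones()]).
#' @param shape,collection,lifecycle,motility,domain parameter lists from
#'   the corresponding constructors.
#' @param nReplicates replicates for [runReplicates()].
#' @param masterSeed master seed; replicate seeds derive from it via
#'   [childSeed()].
#' @return a [GCConfig-class] object.
#' @examples
#' gcConfig(scenario = 1, durationDays = 2)
#' @export
gcConfig <- function(scenario = 1, durationDays = 21, dt = 7.2,
                     sampleEveryH = 1, clones = defaultClones(),
                     shape = shapeSpaceParams(),
                     collection = collectionParams(),
                     lifecycle = lifecycleParams(),
                     motility = motilityParams(),
                     domain = domainParams(),
                     nReplicates = 30, masterSeed = 1) {
  cfg <- new("GCConfig", scenario = as.integer(scenario),
             durationDays = as.numeric(durationDays), dt = as.numeric(dt),
             sampleEveryH = as.numeric(sampleEveryH), clones = clones,
             shape = shape, collection = collection, lifecycle = lifecycle,
             motility = motility, domain = domain,
             nReplicates = as.integer(nReplicates),
             masterSeed = as.integer(masterSeed))
  validObject(cfg)
  cfg
}

#' Small fixture configuration
#'
#' A reduced GC that runs the full pipeline in seconds: 60-um sphere, one
#' FDC, 10 Tfh cells, founders expanding through 4 divisions, 2 simulated
#' days. Intended for tests and examples; pass overrides for intermediate
#' scales.
#'
#' @param scenario collection scenario (0, 1 or 2).
#' @param durationDays simulated days.
#' @param radius sphere radius, micrometres.
#' @param nFdc,nTfh stroma and Tfh counts.
#' @param expansionDivisions founder expansion divisions.
#' @param nReplicates,masterSeed as in [gcConfig()].
#' @param ... further arguments to [gcConfig()].
#' @return a [GCConfig-class] object.
#' @examples
#' smallGCConfig(scenario = 0)
#' @export
smallGCConfig <- function(scenario = 1, durationDays = 2, radius = 60,
                          nFdc = 1, nTfh = 10, expansionDivisions = 4,
                          nReplicates = 5, masterSeed = 1, ...) {
  gcConfig(scenario = scenario, durationDays = durationDays,
           domain = domainParams(radius = radius, nFdc = nFdc, nTfh = nTfh,
                                 nStromalSources = 30),
           lifecycle = lifecycleParams(
             founderExpansionDivisions = expansionDivisions),
           nReplicates = nReplicates, masterSeed = masterSeed, ...)
}

#' Replicate seed derivation
#'
#' Child seed for replicate `i`:
#' `(masterSeed + 1000003 * (i - 1)) mod (2^31 - 1)`. The rule is
#' counter-based, so replicates are independent of execution order.
#'
#' @param masterSeed integer master seed.
#' @param i replicate index (1-based).
#' @return integer seed.
#' @examples childSeed(1, 1:3)
#' @export
childSeed <- function(masterSeed, i) {
  as.integer((as.numeric(masterSeed) + 1000003 * (i - 1)) %% 2147483647)
}

## Assemble lattice, fields and stroma, then hand over to compiled code.
.prepareRun <- function(config, seed) {
  dm <- config@domain
  mo <- config@motility
  co <- config@collection
  lc <- config@lifecycle
  sh <- config@shape
  dt <- config@dt

  moveProbB <- mo$speedB * (dt / 60) / dm$latticeConstant
  moveProbT <- mo$speedTfh * (dt / 60) / dm$latticeConstant
  if (moveProbB > 1 || moveProbT > 1)
    stop("speed * dt / latticeConstant must be <= 1", call. = FALSE)

  domain <- buildDomain(dm$radius, dm$latticeConstant)
  insideIdx <- which(domain@inside)
  dzSites <- insideIdx[domain@zone[insideIdx] == 0L]

  stroma <- placeStroma(domain, nFdc = dm$nFdc, arms = dm$fdcArms,
                        armLength = dm$fdcArmLength,
                        totalAg = dm$agPerFdc * dm$nFdc, nTfh = dm$nTfh)
  cxcl12Src <- dzSites[sample.int(length(dzSites),
                                  min(dm$nStromalSources, length(dzSites)))]
  cxcl13Src <- if (length(stroma$somata)) stroma$somata else integer(0)
  domain <- suppressWarnings(
    steadyStateFields(domain, cxcl12Src, cxcl13Src,
                      diffusion = dm$chemokineDiffusion,
                      decay = dm$chemokineDecay))

  fdcMap <- rep(-1L, domain@nside^3)
  fdcMap[stroma$fdcSites] <- seq_along(stroma$fdcSites) - 1L

  founderPos <- founderPosition(sh)
  founderShape <- matrix(rep(founderPos, each = nrow(config@clones)),
                         nrow = nrow(config@clones))

  nSteps <- as.integer(round(config@durationDays * 86400 / dt))
  sampleEvery <- max(1L, as.integer(round(config@sampleEveryH * 3600 / dt)))

  list(
    scenario = config@scenario, n_steps = nSteps,
    sample_every = sampleEvery, dt = dt,
    nside = domain@nside, inside = as.integer(domain@inside),
    zone = domain@zone, f12 = domain@cxcl12, f13 = domain@cxcl13,
    fdc_map = fdcMap, fdc_ag = as.integer(stroma$fdcAg),
    tfh_pos = as.integer(stroma$tfhSites - 1L),
    dz_sites = as.integer(dzSites - 1L),
    theta_deg = as.numeric(config@clones$thetaDeg),
    n_dims = sh$nDims, gamma = sh$gamma,
    affinity_floor = sh$affinityFloor, ag_pos = sh$agPosition,
    founder_shape = founderShape, n_founders = lc$nFounders,
    p_finish = co$pFinish, s_ag = co$sAg,
    refract_steps = as.integer(round(co$refractoryTime / dt)),
    window_steps = as.integer(round(co$collectionWindow / dt)),
    rupture_first = co$ruptureBeforeCompletion,
    expansion_div = lc$founderExpansionDivisions,
    div_after_sel = lc$divisionsAfterSelection,
    cycle_steps = lc$cbCycleTime / dt, jitter = lc$cycleJitter,
    mut_prob = lc$mutationProb,
    tfh_req_steps = as.integer(round(lc$tfhRequiredSignal / dt)),
    seek_steps = as.integer(round(lc$tfhSearchWindow / dt)),
    contact_patience_steps = max(1L, as.integer(round(
      lc$tfhContactPatience / dt))),
    contact_refract_steps = as.integer(round(lc$tfhContactRefractory / dt)),
    asym_prob = lc$asymmetricDivisionProb,
    asym_frac = lc$asymmetryThreshold,
    move_prob_b = moveProbB, move_prob_tfh = moveProbT,
    persist_steps = max(1L, as.integer(round(mo$persistenceTime / dt))),
    chemo_weight_b = mo$chemoWeightB, chemo_weight_tfh = mo$chemoWeightTfh,
    seed = as.integer(seed))
}

#' Run one GC simulation
#'
#' Executes founder seeding and the full time loop: per step, motility for
#' all agents in RNG-shuffled order, antigen-collection updates, Tfh help
#' competition, and lifecycle transitions. The run is deterministic given
#' `(config, seed)`: re-running returns identical output tables.
#'
#' @param config a [GCConfig-class].
#' @param seed integer seed for this run (defaults to the config's master
#'   seed).
#' @return a [GCResult-class].
#' @examples
#' \donttest{
#' res <- runGC(smallGCConfig(scenario = 1), seed = 7)
#' head(timeSeries(res))
#' }
#' @export
runGC <- function(config, seed = config@masterSeed) {
  validObject(config)
  seed <- as.integer(seed)
  ## R-side draws (stroma placement, founder position) and the compiled
  ## stream are both pinned to this seed.
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  args <- .prepareRun(config, seed)
  raw <- cpp_run_gc(args)

  cloneIds <- config@clones$cloneId
  nC <- length(cloneIds)
  timeH <- raw$time_h
  ts <- data.frame(
    time_h = rep(timeH, times = nC),
    clone_id = rep(cloneIds, each = length(timeH)),
    n_cb = as.vector(raw$n_cb), n_cc = as.vector(raw$n_cc),
    n_oc_cum = as.vector(raw$n_oc_cum),
    ag_collected_total = as.vector(raw$ag_collected_total),
    mean_affinity_alive = as.vector(raw$mean_affinity_alive),
    mean_affinity_oc_cum = as.vector(raw$mean_affinity_oc_cum),
    stringsAsFactors = FALSE)
  ev <- as.data.frame(raw$ev, stringsAsFactors = FALSE)
  ev$clone_id <- cloneIds[ev$clone + 1L]
  ev$clone <- NULL
  ev$selected <- as.logical(ev$selected)
  ev <- ev[, c("cell_id", "clone_id", "n_fdc_contacts", "n_associations",
               "n_dissoc_no_ag", "n_dissoc_with_ag", "selected")]
  oc <- as.data.frame(raw$oc, stringsAsFactors = FALSE)
  oc$clone_id <- if (nrow(oc)) cloneIds[oc$clone + 1L] else character(0)
  oc$clone <- NULL
  oc <- oc[, c("clone_id", "time_h", "affinity", "ag")]

  new("GCResult", timeSeries = ts, cellEvents = ev, ocLog = oc,
      ledger = raw$ledger, seed = seed, config = config)
}

#' Run all replicates of a configuration
#'
#' Replicate `i` runs with [childSeed()]`(masterSeed, i)`; results are
#' independent and stable under re-ordering.
#'
#' @param config a [GCConfig-class].
#' @param nReplicates optional override of the config's replicate count.
#' @return list of [GCResult-class] objects.
#' @examples
#' \donttest{
#' reps <- runReplicates(smallGCConfig(scenario = 0, nReplicates = 2))
#' }
#' @export
runReplicates <- function(config, nReplicates = config@nReplicates) {
  lapply(seq_len(nReplicates), function(i)
    runGC(config, childSeed(config@masterSeed, i)))
}

#' Write one run's tables to a directory
#'
#' Emits `time_series.csv`, `cell_events.csv`, `oc_log.csv` and a
#' `run_metadata.yaml` (config echo, seed, package version).
#'
#' @param result a [GCResult-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeGCTables <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(timeSeries(result), file.path(dir, "time_series.csv"),
            row.names = FALSE)
  write.csv(cellEvents(result), file.path(dir, "cell_events.csv"),
            row.names = FALSE)
  write.csv(ocLog(result), file.path(dir, "oc_log.csv"), row.names = FALSE)
  meta <- list(seed = result@seed,
               package_version = as.character(
                 utils::packageVersion("kineticGC")),
               ledger = as.list(agLedger(result)),
               config = .configAsList(result@config))
  yaml::write_yaml(meta, file.path(dir, "run_metadata.yaml"))
  invisible(dir)
}
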