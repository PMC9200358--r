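#' GCConfig: complete parameterisation of one simulation
#'
#' Holds everything needed to reproduce a run: the collection scenario, run
#' length, time step, clone definitions, and the five parameter groups (see
#' [shapeSpaceParams()], [collectionParams()], [lifecycleParams()],
#' [motilityParams()], [domainParams()]). Build with [gcConfig()] or
#' [smallGCConfig()] rather than `new()`.
#'
#' @slot scenario integer 0, 1 or 2 (collection mechanism).
#' @slot durationDays simulated days.
#' @slot dt time step in seconds.
#' @slot sampleEveryH time-series sampling cadence in hours.
#' @slot clones data.frame with `cloneId`, `thetaDeg`.
#' @slot shape,collection,lifecycle,motility,domain parameter lists.
#' @slot nReplicates replicate count for [runReplicates()].
#' @slot masterSeed master seed from which replicate seeds are derived.
#' @aliases GCConfig
#' @exportClass GCConfig
setClass("GCConfig",
  representation(scenario = "integer", durationDays = "numeric",
                 dt = "numeric", sampleEveryH = "numeric",
                 clones = "data.frame", shape = "list", collection = "list",
                 lifecycle = "list", motility = "list", domain = "list",
                 nReplicates = "integer", masterSeed = "integer"))

setValidity("GCConfig", function(object) {
  errs <- character()
  add <- function(e) errs <<- c(errs, e)
  if (!(object@scenario %in% 0:2)) add("scenario must be 0, 1 or 2")
  if (object@durationDays <= 0) add("durationDays must be > 0")
  if (object@dt <= 0) add("dt must be > 0")
  steps <- object@durationDays * 86400 / object@dt
  if (abs(steps - round(steps)) > 1e-9)
    add("durationDays * 86400 / dt must be an integer step count")
  if (object@sampleEveryH <= 0) add("sampleEveryH must be > 0")
  cl <- object@clones
  if (!all(c("cloneId", "thetaDeg") %in% names(cl)))
    add("clones needs columns cloneId and thetaDeg")
  else {
    if (nrow(cl) < 1) add("at least one clone is required")
    if (anyDuplicated(cl$cloneId)) add("cloneId values must be unique")
    if (any(cl$thetaDeg < 0 | cl$thetaDeg > 90))
      add("thetaDeg must lie in [0, 90]")
  }
  for (grp in c("shape", "collection", "lifecycle", "motility", "domain")) {
    ok <- tryCatch({
      do.call(paste0(sub("^shape$", "shapeSpace", grp), "Params"),
              slot(object, grp))
      TRUE
    }, error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) add(sprintf("%s: %s", grp, ok))
  }
  if (object@nReplicates < 1L) add("nReplicates must be >= 1")
  if (length(errs)) errs else TRUE
})

#' GCDomain: spherical lattice, zones and chemokine fields
#'
#' Produced by [buildDomain()]; fields are attached by [steadyStateFields()].
#' Lattice coordinates are integer offsets from the sphere centre scaled by
#' the lattice constant; the dark zone is the `z > 0` hemisphere and the
#' light zone `z <= 0`.
#'
#' @slot radius,latticeConstant geometry in micrometres.
#' @slot nside cube side length in lattice units (bounding box).
#' @slot inside logical vector over the bounding cube; TRUE inside sphere.
#' @slot zone integer vector: 0 dark zone, 1 light zone, NA outside.
#' @slot cxcl12,cxcl13 numeric steady-state fields over the cube.
#' @slot volumeNl analytic sphere volume in nanolitres.
#' @aliases GCDomain
#' @exportClass GCDomain
setClass("GCDomain",
  representation(radius = "numeric", latticeConstant = "numeric",
                 nside = "integer", inside = "logical", zone = "integer",
                 cxcl12 = "numeric", cxcl13 = "numeric",
                 volumeNl = "numeric"))

setValidity("GCDomain", function(object) {
  n3 <- object@nside^3
  if (length(object@inside) != n3) return("inside has wrong length")
  if (length(object@zone) != n3) return("zone has wrong length")
  if (length(object@cxcl12) && length(object@cxcl12) != n3)
    return("cxcl12 has wrong length")
  if (length(object@cxcl13) && length(object@cxcl13) != n3)
    return("cxcl13 has wrong length")
  TRUE
})

#' GCResult: outputs of one simulated GC reaction
#'
#' @slot timeSeries data.frame sampled at the configured cadence with columns
#'   `time_h`, `clone_id`, `n_cb`, `n_cc`, `n_oc_cum`, `ag_collected_total`,
#'   `mean_affinity_alive`, `mean_affinity_oc_cum`.
#' @slot cellEvents one row per centrocyte that reached the Tfh phase:
#'   `cell_id`, `clone_id`, `n_fdc_contacts`, `n_associations`,
#'   `n_dissoc_no_ag`, `n_dissoc_with_ag`, `selected`.
#' @slot ocLog output cells: `clone_id`, `time_h`, `affinity`, `ag`.
#' @slot ledger named numeric antigen ledger (initial units, left on sites,
#'   held by live cells, exported in output cells, lost to apoptosis) plus
#'   cell bookkeeping totals.
#' @slot seed integer seed actually used for this run.
#' @slot config the [GCConfig-class] that produced the run.
#' @aliases GCResult
#' @exportClass GCResult
setClass("GCResult",
  representation(timeSeries = "data.frame", cellEvents = "data.frame",
                 ocLog = "data.frame", ledger = "numeric", seed = "integer",
                 config = "GCConfig"))

setValidity("GCResult", function(object) {
  ts <- object@timeSeries
  need <- c("time_h", "clone_id", "n_cb", "n_cc", "n_oc_cum",
            "ag_collected_total", "mean_affinity_alive",
            "mean_affinity_oc_cum")
  if (!all(need %in% names(ts))) return("timeSeries is missing columns")
  if (nrow(ts)) {
    if (any(ts$n_cb < 0 | ts$n_cc < 0 | ts$n_oc_cum < 0))
      return("negative counts in timeSeries")
    for (cl in unique(ts$clone_id)) {
      oc <- ts$n_oc_cum[ts$clone_id == cl]
      if (is.unsorted(oc)) return("n_oc_cum must be non-decreasing")
    }
  }
  TRUE
})

#' GCSummary: replicate aggregation
#'
#' Produced by [aggregateReplicates()].
#'
#' @slot timeSeriesStats pointwise mean/min/max envelopes over replicates,
#'   long format: `clone_id`, `time_h`, `series`, `mean`, `min`, `max`.
#' @slot eventStats pooled per-cell event-count summaries per clone for
#'   centrocytes that reached the Tfh phase.
#' @slot ocCounts output cells per replicate and clone.
#' @slot nReplicates replicate count.
#' @aliases GCSummary
#' @exportClass GCSummary
setClass("GCSummary",
  representation(timeSeriesStats = "data.frame", eventStats = "data.frame",
                 ocCounts = "data.frame", nReplicates = "integer"))

setValidity("GCSummary", function(object) {
  s <- object@timeSeriesStats
  if (nrow(s) && any(s$min > s$mean + 1e-9 | s$mean > s$max + 1e-9,
                     na.rm = TRUE))
    return("envelope must satisfy min <= mean <= max")
  TRUE
})

#' @export
setMethod("show", "GCConfig", function(object) {
  cat(sprintf("GCConfig: Scenario-%d, %g day(s), dt = %g s, %d clone(s)\n",
              object@scenario, object@durationDays, object@dt,
              nrow(object@clones)))
  cat(sprintf("  clones: %s\n",
              paste(sprintf("%s (Theta=%g)", object@clones$cloneId,
                            object@clones$thetaDeg), collapse = ", ")))
  cat(sprintf("  domain: radius %g um, lattice %g um, %d FDC, %d Tfh\n",
              object@domain$radius, object@domain$latticeConstant,
              object@domain$nFdc, object@domain$nTfh))
  cat(sprintf("  replicates: %d, master seed %d\n",
              object@nReplicates, object@masterSeed))
})

#' @export
setMethod("show", "GCDomain", function(object) {
  cat(sprintf(
    "GCDomain: radius %g um, lattice %g um, %d sites, volume %.2f nL\n",
    object@radius, object@latticeConstant, sum(object@inside),
    object@volumeNl))
  cat(sprintf("  fields: %s\n",
              if (length(object@cxcl12)) "CXCL12 + CXCL13 attached"
              else "none"))
})

#' @export
setMethod("show", "GCResult", function(object) {
  ts <- object@timeSeries
  cat(sprintf("GCResult: Scenario-%d, seed %d\n",
              object@config@scenario, object@seed))
  if (nrow(ts)) {
    last <- ts[ts$time_h == max(ts$time_h), ]
    cat(sprintf("  final (t = %g h): %s\n", max(ts$time_h),
                paste(sprintf("%s CB+CC=%d OC=%d", last$clone_id,
                              last$n_cb + last$n_cc, last$n_oc_cum),
                      collapse = "; ")))
  }
  cat(sprintf("  %d Tfh-phase centrocyte record(s), %d output cell(s)\n",
              nrow(object@cellEvents), nrow(object@ocLog)))
})

#' @export
setMethod("show", "GCSummary", function(object) {
  cat(sprintf("GCSummary over %d replicate(s): %d envelope rows\n",
              object@nReplicates, nrow(object@timeSeriesStats)))
})
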