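## Parameter-group constructors. Each returns a validated named list; unknown
## names are rejected so that configuration files cannot silently misspell a
## parameter. All times are seconds, all lengths micrometres unless noted.

.check_params <- function(defaults, supplied, what) {
  if (length(supplied)) {
    if (is.null(names(supplied)) || any(!nzchar(names(supplied))))
      stop(what, ": all parameters must be named", call. = FALSE)
    unknown <- setdiff(names(supplied), names(defaults))
    if (length(unknown))
      stop(what, ": unknown parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
  }
  modifyList(defaults, as.list(supplied))
}

.assert <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

#' Shape-space parameters
#'
#' The shape space is an unbounded integer lattice in `nDims` dimensions with
#' the antigen at a fixed position. L1 distance `d` to the antigen maps to
#' affinity via `exp(-d^2 / gamma^2)`; affinities below `affinityFloor` are
#' truncated to zero.
#'
#' @param nDims number of shape-space dimensions (default 4).
#' @param gamma width of the affinity weight function (default 2.8,
#'   dimensionless).
#' @param agPosition integer antigen coordinate of length `nDims`
#'   (default the origin).
#' @param affinityFloor affinity below which a cell's affinity is treated as
#'   exactly zero (default 3e-4).
#' @param founderDistance L1 distance of founder cells from the antigen
#'   (default 5, the integer distance whose affinity rounds to 0.04).
#' @return a named list of class-checked shape-space parameters.
#' @examples
#' shapeSpaceParams()
#' shapeSpaceParams(gamma = 3.0)
#' @export
shapeSpaceParams <- function(nDims = 4L, gamma = 2.8,
                             agPosition = integer(nDims),
                             affinityFloor = 3e-4, founderDistance = 5L) {
  p <- list(nDims = as.integer(nDims), gamma = as.numeric(gamma),
            agPosition = as.integer(agPosition),
            affinityFloor = as.numeric(affinityFloor),
            founderDistance = as.integer(founderDistance))
  .assert(p$nDims >= 1L, "nDims must be >= 1")
  .assert(p$gamma > 0, "gamma must be > 0")
  .assert(length(p$agPosition) == p$nDims,
          "agPosition must have length nDims")
  .assert(p$affinityFloor >= 0 && p$affinityFloor < 1,
          "affinityFloor must lie in [0, 1)")
  .assert(p$founderDistance >= 0L, "founderDistance must be >= 0")
  p
}

#' Antigen-collection parameters
#'
#' @param pFinish probability per time step that an ongoing extraction
#'   completes (default 0.04 per dt).
#' @param refractoryTime seconds during which a centrocyte cannot re-engage
#'   an FDC site after any dissociation (default 72 s).
#' @param collectionWindow seconds a centrocyte may search for antigen before
#'   the no-antigen apoptosis deadline (default 42 min).
#' @param sAg antigen saturation level of a single centrocyte, in antigen
#'   units (default 20).
#' @param ruptureBeforeCompletion logical; in Scenario 1, apply the rupture
#'   test before the completion test within an extraction step (default
#'   TRUE, so that every extraction step including the completing one is a
#'   survived interruption). The alternative ordering is retained for
#'   sensitivity analysis.
#' @return named parameter list.
#' @examples collectionParams()
#' @export
collectionParams <- function(pFinish = 0.04, refractoryTime = 72,
                             collectionWindow = 42 * 60, sAg = 20,
                             ruptureBeforeCompletion = TRUE) {
  p <- list(pFinish = as.numeric(pFinish),
            refractoryTime = as.numeric(refractoryTime),
            collectionWindow = as.numeric(collectionWindow),
            sAg = as.numeric(sAg),
            ruptureBeforeCompletion = isTRUE(ruptureBeforeCompletion))
  .assert(p$pFinish >= 0 && p$pFinish <= 1, "pFinish must lie in [0, 1]")
  .assert(p$refractoryTime >= 0, "refractoryTime must be >= 0")
  .assert(p$collectionWindow > 0, "collectionWindow must be > 0")
  .assert(p$sAg > 0, "sAg must be > 0")
  p
}

#' B-cell lifecycle parameters
#'
#' Constants the underlying biology literature leaves to the base model
#' family; all are exposed here. Defaults: one founder per clone expanding
#' through 6 divisions, a 7 h centroblast cycle with +/-25% jitter, static
#' mutation probability 0.5 per division, 2 divisions after positive
#' selection, 30 min of cumulative Tfh contact required within a 3 h search
#' window, and asymmetric antigen division (probability 0.72, dominant
#' daughter receiving fraction 0.72) driving output-cell differentiation.
#'
#' @param nFounders founder cells per clone.
#' @param founderExpansionDivisions divisions granted to founder cells.
#' @param cbCycleTime centroblast division cycle time in seconds.
#' @param cycleJitter relative uniform jitter applied to each division time.
#' @param mutationProb probability per daughter per division of one
#'   somatic-hypermutation step.
#' @param divisionsAfterSelection divisions granted to a positively selected
#'   cell re-entering the dark zone.
#' @param tfhRequiredSignal cumulative Tfh contact seconds required for
#'   positive selection.
#' @param tfhSearchWindow seconds a centrocyte may seek Tfh help before
#'   apoptosis.
#' @param tfhContactPatience seconds an engaged centrocyte stays bound to a
#'   Tfh without receiving help before detaching (default 6 min). While
#'   engaged the cell competes in place: the Tfh polarises its help to the
#'   strongest antigen presenter among its contacts.
#' @param tfhContactRefractory seconds after detaching during which a
#'   centrocyte cannot re-engage a Tfh (default 3 min).
#' @param asymmetricDivisionProb probability that a division of an
#'   antigen-carrying selected cell distributes antigen asymmetrically.
#' @param asymmetryThreshold fraction of the mother's antigen given to the
#'   dominant daughter in an asymmetric division.
#' @return named parameter list.
#' @examples lifecycleParams(mutationProb = 0)
#' @export
lifecycleParams <- function(nFounders = 1L, founderExpansionDivisions = 6L,
                            cbCycleTime = 7 * 3600, cycleJitter = 0.25,
                            mutationProb = 0.5, divisionsAfterSelection = 2L,
                            tfhRequiredSignal = 30 * 60,
                            tfhSearchWindow = 3 * 3600,
                            tfhContactPatience = 6 * 60,
                            tfhContactRefractory = 3 * 60,
                            asymmetricDivisionProb = 0.72,
                            asymmetryThreshold = 0.72) {
  p <- list(nFounders = as.integer(nFounders),
            founderExpansionDivisions = as.integer(founderExpansionDivisions),
            cbCycleTime = as.numeric(cbCycleTime),
            cycleJitter = as.numeric(cycleJitter),
            mutationProb = as.numeric(mutationProb),
            divisionsAfterSelection = as.integer(divisionsAfterSelection),
            tfhRequiredSignal = as.numeric(tfhRequiredSignal),
            tfhSearchWindow = as.numeric(tfhSearchWindow),
            tfhContactPatience = as.numeric(tfhContactPatience),
            tfhContactRefractory = as.numeric(tfhContactRefractory),
            asymmetricDivisionProb = as.numeric(asymmetricDivisionProb),
            asymmetryThreshold = as.numeric(asymmetryThreshold))
  .assert(p$nFounders >= 1L, "nFounders must be >= 1")
  .assert(p$founderExpansionDivisions >= 0L,
          "founderExpansionDivisions must be >= 0")
  .assert(p$cbCycleTime > 0, "cbCycleTime must be > 0")
  .assert(p$cycleJitter >= 0 && p$cycleJitter < 1,
          "cycleJitter must lie in [0, 1)")
  for (nm in c("mutationProb", "asymmetricDivisionProb", "asymmetryThreshold"))
    .assert(p[[nm]] >= 0 && p[[nm]] <= 1, paste(nm, "must lie in [0, 1]"))
  .assert(p$divisionsAfterSelection >= 0L,
          "divisionsAfterSelection must be >= 0")
  .assert(p$tfhRequiredSignal > 0, "tfhRequiredSignal must be > 0")
  .assert(p$tfhSearchWindow > 0, "tfhSearchWindow must be > 0")
  .assert(p$tfhContactPatience > 0, "tfhContactPatience must be > 0")
  .assert(p$tfhContactRefractory >= 0, "tfhContactRefractory must be >= 0")
  p
}

#' Motility parameters
#'
#' Cells perform a persistent random walk on the lattice: a cell attempts one
#' lattice step per time step with probability `speed * dt / latticeConstant`
#' and re-draws its direction after the persistence time, following the local
#' chemokine gradient with the cell type's chemotaxis weight and a uniform
#' direction otherwise.
#'
#' @param speedB B-cell speed, micrometres per minute (default 7.5).
#' @param speedTfh Tfh speed, micrometres per minute (default 10).
#' @param persistenceTime seconds between direction re-draws (default 90 s).
#' @param chemoWeightB probability that a B-cell direction re-draw follows
#'   the relevant chemokine gradient (CXCL12 for centroblasts, CXCL13 for
#'   centrocytes).
#' @param chemoWeightTfh as above for Tfh cells (CXCL13).
#' @return named parameter list.
#' @examples motilityParams(chemoWeightB = 0)
#' @export
motilityParams <- function(speedB = 7.5, speedTfh = 10,
                           persistenceTime = 90,
                           chemoWeightB = 0.5, chemoWeightTfh = 0.5) {
  p <- list(speedB = as.numeric(speedB), speedTfh = as.numeric(speedTfh),
            persistenceTime = as.numeric(persistenceTime),
            chemoWeightB = as.numeric(chemoWeightB),
            chemoWeightTfh = as.numeric(chemoWeightTfh))
  .assert(p$speedB > 0 && p$speedTfh > 0, "speeds must be > 0")
  .assert(p$persistenceTime > 0, "persistenceTime must be > 0")
  for (nm in c("chemoWeightB", "chemoWeightTfh"))
    .assert(p[[nm]] >= 0 && p[[nm]] <= 1, paste(nm, "must lie in [0, 1]"))
  p
}

#' Domain and stroma parameters
#'
#' Geometry of the spherical GC, the FDC network, antigen loading, Tfh
#' numbers, and the chemokine-field solver.
#'
#' @param radius sphere radius in micrometres (default 160).
#' @param latticeConstant lattice spacing in micrometres (default 5).
#' @param nFdc number of FDCs placed in the light zone (default 200).
#' @param fdcArms dendritic arms per FDC, along lattice axes (default 6).
#' @param fdcArmLength arm length in micrometres (default 40).
#' @param agPerFdc antigen units loaded per FDC (default 3000); the total is
#'   spread uniformly over all FDC sites.
#' @param nTfh number of Tfh cells, placed uniformly in the light zone
#'   (default 250).
#' @param nStromalSources number of CXCL12-secreting stromal sites sampled
#'   in the dark zone (default 200).
#' @param chemokineDiffusion,chemokineDecay diffusion and degradation
#'   coefficients (lattice units) of the steady-state chemokine solver;
#'   their ratio sets the decay length `sqrt(D/k)` (~8 lattice units, 40 um,
#'   with the defaults).
#' @return named parameter list.
#' @examples domainParams(radius = 60, nFdc = 1, nTfh = 10)
#' @export
domainParams <- function(radius = 160, latticeConstant = 5,
                         nFdc = 200L, fdcArms = 6L, fdcArmLength = 40,
                         agPerFdc = 3000, nTfh = 250L,
                         nStromalSources = 200L,
                         chemokineDiffusion = 1, chemokineDecay = 1 / 64) {
  p <- list(radius = as.numeric(radius),
            latticeConstant = as.numeric(latticeConstant),
            nFdc = as.integer(nFdc), fdcArms = as.integer(fdcArms),
            fdcArmLength = as.numeric(fdcArmLength),
            agPerFdc = as.numeric(agPerFdc), nTfh = as.integer(nTfh),
            nStromalSources = as.integer(nStromalSources),
            chemokineDiffusion = as.numeric(chemokineDiffusion),
            chemokineDecay = as.numeric(chemokineDecay))
  .assert(p$radius >= p$latticeConstant && p$latticeConstant > 0,
          "need radius >= latticeConstant > 0")
  .assert(p$nFdc >= 0L && p$nTfh >= 0L, "nFdc and nTfh must be >= 0")
  .assert(p$fdcArms >= 0L && p$fdcArmLength >= 0, "invalid FDC geometry")
  .assert(p$agPerFdc >= 0, "agPerFdc must be >= 0")
  .assert(p$nStromalSources >= 0L, "nStromalSources must be >= 0")
  .assert(p$chemokineDiffusion > 0 && p$chemokineDecay > 0,
          "chemokine coefficients must be > 0")
  p
}

#' Default clone definitions
#'
#' The three founder clones share one affinity but split it differently into
#' association and dissociation probabilities: Clone-L (Theta = 90, slow
#' association, never dissociates), Clone-M (Theta = 45, intermediate), and
#' Clone-H (Theta = 0, certain association, fast dissociation). Theta is
#' fixed for a clone's whole lineage; mutation only changes the shape-space
#' distance.
#'
#' @return data.frame with columns `cloneId` (character) and `thetaDeg`
#'   (numeric, degrees in \[0, 90\]).
#' @examples defaultClones()
#' @export
defaultClones <- function() {
  data.frame(cloneId = c("Clone-L", "Clone-M", "Clone-H"),
             thetaDeg = c(90, 45, 0),
             stringsAsFactors = FALSE)
}
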