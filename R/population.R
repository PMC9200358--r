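#' Construct a B-cell record
#'
#' Reference representation of a GC B cell used by the pure-R lifecycle
#' operations (the engine keeps the same fields in compiled code).
#'
#' @param cloneId clone label.
#' @param thetaDeg the clone's fixed kinetic angle, degrees.
#' @param shapePosition integer shape-space coordinate.
#' @param phase one of `"CB"`, `"CC_collecting"`, `"CC_seeking_tfh"`,
#'   `"selected"`, `"apoptotic"`, `"OC"`.
#' @param divisionsLeft remaining divisions.
#' @param agRetained antigen units internalised from previous selection
#'   rounds (drives output-cell differentiation).
#' @param shape shape-space parameters.
#' @return list with the cell fields plus a `phenotype` consistent with the
#'   position and angle.
#' @examples
#' newBCell("Clone-M", 45, c(5, 0, 0, 0))
#' @export
newBCell <- function(cloneId, thetaDeg, shapePosition, phase = "CB",
                     divisionsLeft = 0L, agRetained = 0,
                     shape = shapeSpaceParams()) {
  list(cloneId = cloneId, thetaDeg = thetaDeg,
       shapePosition = shapePosition, phase = phase,
       divisionsLeft = as.integer(divisionsLeft), agRetained = agRetained,
       agCollected = 0L, tfhSignal = 0, windowClock = 0, seekClock = 0,
       phenotype = kineticPhenotype(shapePosition, thetaDeg, shape))
}

#' Divide a centroblast
#'
#' Produces two daughters, each independently mutated with probability
#' `lifecycle$mutationProb` by one [applySHM()] step; phenotypes are
#' recomputed with the clone's fixed angle and `divisionsLeft` is
#' decremented. When the mother carries antigen, the split is asymmetric
#' with probability `asymmetricDivisionProb` (the dominant daughter, chosen
#' at random, receives fraction `asymmetryThreshold`), otherwise 50/50.
#'
#' @param cell a `"CB"`-phase cell from [newBCell()] with
#'   `divisionsLeft > 0`.
#' @param lifecycle lifecycle parameters.
#' @param shape shape-space parameters.
#' @return list with `daughters` (list of two cells), `asymmetric`
#'   (logical) and `dominant` (1, 2 or NA).
#' @examples
#' m <- newBCell("Clone-M", 45, c(5, 0, 0, 0), divisionsLeft = 2)
#' set.seed(1)
#' divideCell(m, lifecycleParams(mutationProb = 0))
#' @export
divideCell <- function(cell, lifecycle = lifecycleParams(),
                       shape = shapeSpaceParams()) {
  if (cell$phase != "CB") stop("only CB-phase cells divide", call. = FALSE)
  if (cell$divisionsLeft <= 0L)
    stop("cell has no divisions left", call. = FALSE)
  mk <- function(agShare) {
    d <- cell
    d$divisionsLeft <- cell$divisionsLeft - 1L
    d$agRetained <- agShare
    if (runif(1) < lifecycle$mutationProb)
      d$shapePosition <- applySHM(d$shapePosition, shape)
    d$phenotype <- kineticPhenotype(d$shapePosition, d$thetaDeg, shape)
    d
  }
  asym <- FALSE
  dominant <- NA_integer_
  if (cell$agRetained > 0 && runif(1) < lifecycle$asymmetricDivisionProb) {
    asym <- TRUE
    dominant <- sample(1:2, 1L)
    big <- lifecycle$asymmetryThreshold * cell$agRetained
    shares <- c(big, cell$agRetained - big)
    if (dominant == 2L) shares <- rev(shares)
  } else shares <- rep(cell$agRetained / 2, 2L)
  list(daughters = list(mk(shares[1L]), mk(shares[2L])),
       asymmetric = asym, dominant = dominant)
}

#' Tfh help assignment among neighbouring centrocytes
#'
#' A Tfh cell helps exactly one neighbour per time step: the centrocyte
#' presenting the most collected antigen, ties broken uniformly. Cells with
#' zero collected antigen never receive help.
#'
#' @param agCollected numeric vector of collected-antigen amounts of the
#'   neighbouring centrocytes (possibly empty).
#' @return index of the helped cell, or `0L` when no neighbour qualifies.
#' @examples
#' tfhHelp(c(5, 3))   # 1
#' tfhHelp(c(0, 0))   # 0
#' @export
tfhHelp <- function(agCollected) {
  if (!length(agCollected)) return(0L)
  m <- max(agCollected)
  if (m <= 0) return(0L)
  best <- which(agCollected == m)
  if (length(best) == 1L) best else best[sample.int(length(best), 1L)]
}

#' Resolve a centrocyte's fate at the current time step
#'
#' Collecting centrocytes that reach the collection window with no antigen
#' die; those with antigen move on to seek Tfh help. Seeking centrocytes
#' are positively selected once their cumulative Tfh signal reaches the
#' threshold and die when the search window expires unselected.
#'
#' @param cell a cell in phase `"CC_collecting"` or `"CC_seeking_tfh"`.
#' @param collection collection parameters (for `collectionWindow`).
#' @param lifecycle lifecycle parameters (for `tfhRequiredSignal`,
#'   `tfhSearchWindow`).
#' @return one of `"continue"`, `"apoptotic"`, `"seek_tfh"`, `"selected"`.
#' @examples
#' cc <- newBCell("Clone-M", 45, c(5, 0, 0, 0), phase = "CC_collecting")
#' cc$windowClock <- 42 * 60
#' resolveCCFate(cc)  # no antigen at the deadline -> apoptotic
#' @export
resolveCCFate <- function(cell, collection = collectionParams(),
                          lifecycle = lifecycleParams()) {
  if (cell$phase == "CC_collecting") {
    if (cell$windowClock >= collection$collectionWindow)
      return(if (cell$agCollected > 0) "seek_tfh" else "apoptotic")
    return("continue")
  }
  if (cell$phase == "CC_seeking_tfh") {
    if (cell$tfhSignal >= lifecycle$tfhRequiredSignal) return("selected")
    if (cell$seekClock >= lifecycle$tfhSearchWindow) return("apoptotic")
    return("continue")
  }
  stop("resolveCCFate applies to collecting or seeking centrocytes",
       call. = FALSE)
}

#' One post-selection division with output-cell differentiation
#'
#' A positively selected cell re-enters the dark zone and divides; on an
#' asymmetric division the daughter holding the large antigen share leaves
#' the GC as an output cell (memory/plasma, not distinguished), while the
#' other daughter (and both daughters of a symmetric division) continue to
#' cycle.
#'
#' @param cell a `"CB"`-phase cell from a selected lineage
#'   (`agRetained > 0` for output-cell production to be possible).
#' @param lifecycle,shape parameter lists.
#' @return list with `cells` (daughters staying in the GC) and `oc` (the
#'   output cell, or `NULL`).
#' @examples
#' sel <- newBCell("Clone-M", 45, c(4, 0, 0, 0), divisionsLeft = 2,
#'                 agRetained = 6)
#' set.seed(2)
#' postSelectionFate(sel, lifecycleParams(asymmetricDivisionProb = 1))
#' @export
postSelectionFate <- function(cell, lifecycle = lifecycleParams(),
                              shape = shapeSpaceParams()) {
  div <- divideCell(cell, lifecycle, shape)
  if (div$asymmetric) {
    ocCell <- div$daughters[[div$dominant]]
    if (ocCell$agRetained > 0) {
      ocCell$phase <- "OC"
      return(list(cells = div$daughters[-div$dominant], oc = ocCell))
    }
  }
  list(cells = div$daughters, oc = NULL)
}
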