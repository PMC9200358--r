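#' Affinity from shape-space distance
#'
#' Maps the L1 distance `d` between a B cell and the antigen to a binding
#' probability, `exp(-d^2 / gamma^2)`, truncating values below the
#' configured floor to exactly zero.
#'
#' @param d non-negative integer L1 distance (vectorised).
#' @param shape shape-space parameter list from [shapeSpaceParams()].
#' @param floor logical; apply the affinity floor (default TRUE). The
#'   un-floored value is what the kinetic decomposition reproduces exactly.
#' @return numeric vector of affinities in \[0, 1\].
#' @examples
#' affinityFromDistance(0:8, shapeSpaceParams())
#' @export
affinityFromDistance <- function(d, shape = shapeSpaceParams(),
                                 floor = TRUE) {
  if (any(d < 0)) stop("d must be >= 0", call. = FALSE)
  a <- exp(-d^2 / shape$gamma^2)
  if (floor) a[a < shape$affinityFloor] <- 0
  a
}

#' Decompose shape-space distance into kinetic probabilities
#'
#' The distance `d` is split into an association distance `x = d sin(Theta)`
#' and a dissociation distance `y = d cos(Theta)`, giving
#' `P_a = exp(-d^2 sin^2(Theta) / gamma^2)` and
#' `P_d = 1 - exp(-d^2 cos^2(Theta) / gamma^2)`, so that
#' `P_a (1 - P_d)` equals the (un-floored) affinity identically. `Theta` is
#' a fixed clonal property: Theta = 90 pins `P_d` at 0 (Clone-L), Theta = 0
#' pins `P_a` at 1 (Clone-H).
#'
#' @param d non-negative integer L1 distance (vectorised).
#' @param thetaDeg angle in degrees in \[0, 90\].
#' @param shape shape-space parameter list.
#' @return list with numeric components `pA` and `pD`.
#' @examples
#' decomposeKinetics(5, 45)   # the Clone-M founder phenotype
#' @export
decomposeKinetics <- function(d, thetaDeg, shape = shapeSpaceParams()) {
  if (any(d < 0)) stop("d must be >= 0", call. = FALSE)
  if (any(thetaDeg < 0 | thetaDeg > 90))
    stop("thetaDeg must lie in [0, 90]: decomposition undefined outside",
         call. = FALSE)
  th <- thetaDeg * pi / 180
  list(pA = exp(-d^2 * sin(th)^2 / shape$gamma^2),
       pD = 1 - exp(-d^2 * cos(th)^2 / shape$gamma^2))
}

#' Kinetic phenotype of a cell at a shape-space position
#'
#' @param position integer shape-space coordinate (length `shape$nDims`).
#' @param thetaDeg the clone's fixed angle, degrees.
#' @param shape shape-space parameter list.
#' @return list with `distance`, `thetaDeg`, `pA`, `pD`, `affinity`
#'   (floored), `assocDistance` (`d sin Theta`) and `dissocDistance`
#'   (`d cos Theta`).
#' @examples
#' kineticPhenotype(c(5, 0, 0, 0), thetaDeg = 45)
#' @export
kineticPhenotype <- function(position, thetaDeg,
                             shape = shapeSpaceParams()) {
  if (length(position) != shape$nDims)
    stop("position must have length nDims", call. = FALSE)
  d <- sum(abs(position - shape$agPosition))
  k <- decomposeKinetics(d, thetaDeg, shape)
  th <- thetaDeg * pi / 180
  list(distance = d, thetaDeg = thetaDeg, pA = k$pA, pD = k$pD,
       affinity = affinityFromDistance(d, shape),
       assocDistance = d * sin(th), dissocDistance = d * cos(th))
}

#' Apply one somatic-hypermutation step
#'
#' Moves a shape-space position by exactly one grid point: a coordinate and
#' a direction are drawn uniformly over the `2 * nDims` unit moves. The
#' lattice is unbounded, so no clipping occurs.
#'
#' @param position integer vector of length `shape$nDims`.
#' @param shape shape-space parameter list.
#' @return mutated integer position (L1 distance 1 from the input).
#' @examples
#' set.seed(1)
#' applySHM(c(0, 0, 0, 0))
#' @export
applySHM <- function(position, shape = shapeSpaceParams()) {
  if (length(position) != shape$nDims)
    stop("position must have length nDims", call. = FALSE)
  i <- sample.int(shape$nDims, 1L)
  position[i] <- position[i] + sample(c(-1L, 1L), 1L)
  position
}

## All lattice points at L1 distance d from the origin in n dimensions.
.l1Sphere <- function(d, n) {
  if (d == 0L) return(matrix(0L, 1L, n))
  grid <- as.matrix(expand.grid(rep(list(seq.int(-d, d)), n)))
  storage.mode(grid) <- "integer"
  grid[rowSums(abs(grid)) == d, , drop = FALSE]
}

#' Draw a founder shape-space position
#'
#' Samples uniformly from the lattice points at L1 distance
#' `shape$founderDistance` from the antigen. By default all clones share one
#' founder position, so that clonal differences are purely kinetic.
#'
#' @param shape shape-space parameter list.
#' @return integer position vector.
#' @examples
#' set.seed(1); founderPosition()
#' @export
founderPosition <- function(shape = shapeSpaceParams()) {
  pts <- .l1Sphere(shape$founderDistance, shape$nDims)
  shape$agPosition + pts[sample.int(nrow(pts), 1L), ]
}

#' Founder phenotypes for a set of clones
#'
#' Evaluates the kinetic decomposition for each clone at its founder
#' position. All founders must sit at the configured founder distance, which
#' guarantees identical affinities across clones.
#'
#' @param clones data.frame with `cloneId` and `thetaDeg` (see
#'   [defaultClones()]); an optional list column `position` supplies
#'   per-clone founder positions, otherwise `position` (a single shared
#'   coordinate) is used.
#' @param shape shape-space parameter list.
#' @param position shared founder position; defaults to
#'   `c(founderDistance, 0, 0, ...)`.
#' @return data.frame with one row per clone: `cloneId`, `thetaDeg`,
#'   `distance`, `pA`, `pD`, `affinity`.
#' @examples
#' founderPhenotypes(defaultClones())
#' @export
founderPhenotypes <- function(clones = defaultClones(),
                              shape = shapeSpaceParams(),
                              position = NULL) {
  if (nrow(clones) == 0L)
    return(data.frame(cloneId = character(), thetaDeg = numeric(),
                      distance = integer(), pA = numeric(), pD = numeric(),
                      affinity = numeric()))
  if (is.null(position))
    position <- shape$agPosition +
      c(shape$founderDistance, integer(shape$nDims - 1L))
  getPos <- function(i) {
    if (!is.null(clones$position)) clones$position[[i]] else position
  }
  rows <- lapply(seq_len(nrow(clones)), function(i) {
    p <- getPos(i)
    d <- sum(abs(p - shape$agPosition))
    if (d != shape$founderDistance)
      stop(sprintf("founder of %s is at L1 distance %d, expected %d",
                   clones$cloneId[i], d, shape$founderDistance),
           call. = FALSE)
    ph <- kineticPhenotype(p, clones$thetaDeg[i], shape)
    data.frame(cloneId = clones$cloneId[i], thetaDeg = clones$thetaDeg[i],
               distance = ph$distance, pA = ph$pA, pD = ph$pD,
               affinity = ph$affinity)
  })
  do.call(rbind, rows)
}
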