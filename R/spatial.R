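## Lattice directions (x+, x-, y+, y-, z+, z-)
.DIRS <- matrix(c(1L, 0L, 0L, -1L, 0L, 0L, 0L, 1L, 0L,
                  0L, -1L, 0L, 0L, 0L, 1L, 0L, 0L, -1L),
                ncol = 3L, byrow = TRUE)

#' Build the spherical simulation domain
#'
#' Enumerates all integer lattice points whose scaled position lies inside a
#' sphere of the given radius, assigns dark-zone (`z > 0`) and light-zone
#' (`z <= 0`) labels, and records the analytic volume. Chemokine fields are
#' attached later by [steadyStateFields()].
#'
#' @param radius sphere radius in micrometres.
#' @param latticeConstant lattice spacing in micrometres.
#' @return a [GCDomain-class] object.
#' @examples
#' buildDomain(60, 5)
#' @export
buildDomain <- function(radius = 160, latticeConstant = 5) {
  if (!(radius >= latticeConstant && latticeConstant > 0))
    stop("need radius >= latticeConstant > 0", call. = FALSE)
  rmax <- as.integer(floor(radius / latticeConstant))
  nside <- 2L * rmax + 1L
  ax <- seq.int(-rmax, rmax)
  g <- expand.grid(x = ax, y = ax, z = ax)
  inside <- (g$x^2 + g$y^2 + g$z^2) * latticeConstant^2 <= radius^2
  zone <- rep(NA_integer_, nrow(g))
  zone[inside] <- ifelse(g$z[inside] > 0L, 0L, 1L)
  volumeNl <- 4 / 3 * pi * radius^3 * 1e-6  # um^3 -> nL
  new("GCDomain", radius = radius, latticeConstant = latticeConstant,
      nside = nside, inside = inside, zone = zone,
      cxcl12 = numeric(0), cxcl13 = numeric(0), volumeNl = volumeNl)
}

## cube linear index (1-based) from integer lattice coords
.cubeIndex <- function(domain, coords) {
  rmax <- (domain@nside - 1L) %/% 2L
  n <- domain@nside
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 3L)
  (coords[, 1L] + rmax) + n * (coords[, 2L] + rmax) +
    n * n * (coords[, 3L] + rmax) + 1L
}

#' Lattice coordinates of all sites inside the sphere
#'
#' @param domain a [GCDomain-class].
#' @return integer matrix with columns x, y, z (lattice units, centre at 0).
#' @examples nrow(domainSites(buildDomain(25, 5)))
#' @export
domainSites <- function(domain) {
  rmax <- (domain@nside - 1L) %/% 2L
  ax <- seq.int(-rmax, rmax)
  g <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  storage.mode(g) <- "integer"
  g[domain@inside, , drop = FALSE]
}

## Sparse steady-state diffusion-degradation solve:
## (k + D * deg(i)) c_i - D * sum_nb c_nb = s_i, reflecting boundary
## (outside-sphere neighbours carry no flux). SPD system solved by
## conjugate gradient on the inside sites.
.solveField <- function(domain, sourceIdx, D, k, tol = 1e-10,
                        maxIter = 5000L) {
  siteIdx <- which(domain@inside)
  n <- length(siteIdx)
  rank <- integer(domain@nside^3)
  rank[siteIdx] <- seq_len(n)
  coords <- domainSites(domain)
  nb <- matrix(0L, n, 6L)
  for (d in 1:6) {
    shifted <- sweep(coords, 2L, .DIRS[d, ], "+")
    rmax <- (domain@nside - 1L) %/% 2L
    okBox <- abs(shifted[, 1L]) <= rmax & abs(shifted[, 2L]) <= rmax &
      abs(shifted[, 3L]) <= rmax
    idx <- integer(n)
    idx[okBox] <- rank[.cubeIndex(domain, shifted[okBox, , drop = FALSE])]
    nb[, d] <- idx  # 0 when the neighbour is outside the sphere
  }
  deg <- rowSums(nb > 0L)
  diagA <- k + D * deg
  b <- numeric(n)
  b[rank[sourceIdx]] <- 1
  Amul <- function(v) {
    acc <- diagA * v
    for (d in 1:6) {
      has <- nb[, d] > 0L
      acc[has] <- acc[has] - D * v[nb[has, d]]
    }
    acc
  }
  x <- numeric(n)
  r <- b
  p <- r
  rs <- sum(r * r)
  b2 <- max(rs, .Machine$double.eps)
  for (it in seq_len(maxIter)) {
    Ap <- Amul(p)
    alpha <- rs / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs2 <- sum(r * r)
    if (sqrt(rs2 / b2) < tol) break
    p <- r + (rs2 / rs) * p
    rs <- rs2
  }
  field <- numeric(domain@nside^3)
  field[siteIdx] <- x
  field
}

#' Attach steady-state chemokine fields to a domain
#'
#' Solves the discrete diffusion-degradation equation
#' `D * laplacian(c) - k * c + s = 0` (unit production at each source site,
#' zero-flux boundary) once per field; the result is deterministic given the
#' sources. CXCL12 is produced by dark-zone stromal sites and CXCL13 by FDC
#' sites in the light zone.
#'
#' @param domain a [GCDomain-class].
#' @param cxcl12Sources,cxcl13Sources cube indices (see
#'   [.cubeIndex()][buildDomain()] internals or use the site indices in
#'   [placeStroma()] output) of the producing sites; an empty vector gives a
#'   uniformly zero field with a warning.
#' @param diffusion,decay solver coefficients (lattice units).
#' @return the domain with `cxcl12` and `cxcl13` fields attached.
#' @examples
#' d <- buildDomain(25, 5)
#' ctr <- which(domainSites(d)[, 1] == 0 & domainSites(d)[, 2] == 0 &
#'              domainSites(d)[, 3] == 0)
#' d <- steadyStateFields(d, which(d@inside)[ctr], which(d@inside)[ctr])
#' @export
steadyStateFields <- function(domain, cxcl12Sources, cxcl13Sources,
                              diffusion = 1, decay = 1 / 64) {
  solveOne <- function(src, label) {
    if (!length(src)) {
      warning("no ", label, " sources: field is uniformly zero",
              call. = FALSE)
      return(numeric(domain@nside^3))
    }
    if (any(!domain@inside[src]))
      stop(label, " sources must lie inside the domain", call. = FALSE)
    .solveField(domain, src, diffusion, decay)
  }
  domain@cxcl12 <- solveOne(cxcl12Sources, "CXCL12")
  domain@cxcl13 <- solveOne(cxcl13Sources, "CXCL13")
  validObject(domain)
  domain
}

#' Place the FDC network, antigen and Tfh cells
#'
#' Each FDC occupies a soma site in the light zone plus dendritic arms of
#' `armLength / latticeConstant` sites along lattice axes (6 arms cover all
#' axis directions); overlapping sites are merged. The total antigen is
#' spread over all FDC sites in integer units (remainder units go to
#' randomly chosen sites). Tfh cells start at distinct light-zone sites.
#' Draws use R's RNG.
#'
#' @param domain a [GCDomain-class].
#' @param nFdc number of FDCs.
#' @param arms dendritic arms per FDC (up to 6; fewer arms are drawn at
#'   random per FDC).
#' @param armLength arm length in micrometres.
#' @param totalAg total antigen units over the whole network.
#' @param nTfh number of Tfh starting positions.
#' @return list with `fdcSites` (cube indices), `fdcAg` (integer units per
#'   site, summing to `round(totalAg)`), `somata`, and `tfhSites`.
#' @examples
#' d <- buildDomain(60, 5)
#' set.seed(1)
#' s <- placeStroma(d, nFdc = 2, totalAg = 6000, nTfh = 5)
#' sum(s$fdcAg)
#' @export
placeStroma <- function(domain, nFdc, arms = 6L, armLength = 40,
                        totalAg = 3000 * nFdc, nTfh) {
  lzIdx <- which(domain@inside & !is.na(domain@zone) & domain@zone == 1L)
  if (nFdc > length(lzIdx))
    stop("more FDCs than light-zone sites", call. = FALSE)
  if (nTfh > length(lzIdx))
    stop("more Tfh cells than light-zone sites", call. = FALSE)
  armSites <- as.integer(floor(armLength / domain@latticeConstant))
  rmax <- (domain@nside - 1L) %/% 2L
  coordsAll <- domainSites(domain)
  lzCoords <- coordsAll[domain@zone[domain@inside] == 1L, , drop = FALSE]
  somaPick <- sample.int(nrow(lzCoords), nFdc)
  somata <- lzCoords[somaPick, , drop = FALSE]
  sites <- integer(0)
  for (i in seq_len(nFdc)) {
    dirs <- if (arms >= 6L) 1:6 else sample.int(6L, arms)
    fdc <- .cubeIndex(domain, somata[i, , drop = FALSE])
    for (d in dirs) {
      for (s in seq_len(armSites)) {
        p <- somata[i, ] + s * .DIRS[d, ]
        if (any(abs(p) > rmax)) break
        ci <- .cubeIndex(domain, p)
        if (!domain@inside[ci]) break
        fdc <- c(fdc, ci)
      }
    }
    sites <- c(sites, fdc)
  }
  sites <- sort(unique(sites))
  k <- length(sites)
  ag <- integer(k)
  if (k > 0L && totalAg > 0) {
    tot <- as.integer(round(totalAg))
    ag <- rep(tot %/% k, k)
    rem <- tot - sum(ag)
    if (rem > 0L) {
      bump <- sample.int(k, rem)
      ag[bump] <- ag[bump] + 1L
    }
  }
  tfhSites <- lzIdx[sample.int(length(lzIdx), nTfh)]
  list(fdcSites = sites, fdcAg = ag,
       somata = .cubeIndex(domain, somata), tfhSites = tfhSites)
}

#' One persistent-random-walk motility step (reference implementation)
#'
#' A cell attempts one lattice step with probability `moveProb`; its
#' direction is re-drawn every `persistSteps` steps, following the steepest
#' local gradient of `field` with probability `chemoWeight` and a uniform
#' direction otherwise. Moves out of the sphere or onto occupied sites are
#' rejected (the cell stays and re-orients). The engine applies the same
#' rule in compiled code.
#'
#' @param pos integer lattice coordinate (length 3).
#' @param dir current direction index in 1..6, or 0 for none.
#' @param persistLeft steps remaining until the next direction re-draw.
#' @param domain a [GCDomain-class].
#' @param field numeric field over the cube used for chemotaxis (may be a
#'   zero vector).
#' @param moveProb per-step movement probability (`speed * dt / lattice`).
#' @param chemoWeight probability that a re-draw follows the gradient.
#' @param persistSteps steps between re-draws.
#' @param occupied optional function(coords) -> logical for site exclusion.
#' @return list with updated `pos`, `dir`, `persistLeft`.
#' @examples
#' d <- buildDomain(25, 5)
#' set.seed(1)
#' moveCell(c(0, 0, 0), 0, 0, d, numeric(d@nside^3), 0.18, 0, 12)
#' @export
moveCell <- function(pos, dir, persistLeft, domain, field,
                     moveProb, chemoWeight, persistSteps,
                     occupied = NULL) {
  rmax <- (domain@nside - 1L) %/% 2L
  insideAt <- function(p) all(abs(p) <= rmax) &&
    domain@inside[.cubeIndex(domain, p)]
  if (persistLeft <= 0L || dir < 1L) {
    if (length(field) && runif(1) < chemoWeight) {
      vals <- rep(-Inf, 6)
      for (k in 1:6) {
        p <- pos + .DIRS[k, ]
        if (insideAt(p)) vals[k] <- field[.cubeIndex(domain, p)]
      }
      best <- which(vals == max(vals))
      dir <- if (length(best) == 1L) best else
        best[sample.int(length(best), 1L)]
    } else dir <- sample.int(6L, 1L)
    persistLeft <- persistSteps
  }
  persistLeft <- persistLeft - 1L
  if (runif(1) < moveProb) {
    cand <- pos + .DIRS[dir, ]
    blocked <- !insideAt(cand) ||
      (!is.null(occupied) && isTRUE(occupied(cand)))
    if (blocked) dir <- 0L else pos <- cand
  }
  list(pos = pos, dir = dir, persistLeft = persistLeft)
}
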