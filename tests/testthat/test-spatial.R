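# Lattice domain, chemokine fields, stroma placement and motility.

test_that("domain geometry matches the analytic sphere", {
  d <- buildDomain(160, 5)
  expect_equal(d@volumeNl, 4 / 3 * pi * 160^3 * 1e-6, tolerance = 1e-12)
  expect_equal(round(d@volumeNl), 17)                 # ~17 nL
  expect_equal(d@volumeNl * 1e-6 * 1e-3, 1.7157e-11,  # in m^3
               tolerance = 1e-3)
  # lattice-point count approximates volume / a^3 within 2%
  nSites <- sum(d@inside)
  expect_lt(abs(nSites - d@volumeNl * 1e6 / 125) /
              (d@volumeNl * 1e6 / 125), 0.02)
  # every site lies within the radius
  co <- domainSites(d)
  expect_true(all(rowSums(co^2) * 25 <= 160^2))
  # both zones present and complementary
  z <- d@zone[d@inside]
  expect_setequal(unique(z), c(0L, 1L))
  expect_true(all(co[z == 0L, 3] > 0) && all(co[z == 1L, 3] <= 0))
})

test_that("degenerate radius gives the 7-site cross", {
  d <- buildDomain(5, 5)
  expect_equal(sum(d@inside), 7L)
  expect_error(buildDomain(3, 5), "latticeConstant")
  expect_error(buildDomain(-1, 5), "latticeConstant")
})

test_that("field solver agrees with a dense linear solve on a small
           domain", {
  d <- buildDomain(10, 5)
  co <- domainSites(d)
  n <- nrow(co)
  D <- 1; k <- 0.25
  # independent dense construction of the same reflecting-boundary system
  A <- matrix(0, n, n)
  key <- paste(co[, 1], co[, 2], co[, 3])
  for (i in seq_len(n)) {
    for (dd in 1:6) {
      nb <- co[i, ] + c(1, -1, 0, 0, 0, 0, 0, 0, 1, -1, 0, 0,
                        0, 0, 0, 0, 1, -1)[seq(dd, 18, by = 6)]
      j <- match(paste(nb[1], nb[2], nb[3]), key)
      if (!is.na(j)) {
        A[i, j] <- A[i, j] - D
        A[i, i] <- A[i, i] + D
      }
    }
    A[i, i] <- A[i, i] + k
  }
  ctr <- which(co[, 1] == 0 & co[, 2] == 0 & co[, 3] == 0)
  b <- numeric(n); b[ctr] <- 1
  expected <- solve(A, b)
  got <- kineticGC:::.solveField(d, which(d@inside)[ctr], D, k)
  expect_equal(got[d@inside], expected, tolerance = 1e-8)
})

test_that("fields are symmetric, source-maximal and zone-ordered", {
  d <- buildDomain(40, 5)
  idx <- which(d@inside)
  co <- domainSites(d)
  ctr <- idx[co[, 1] == 0 & co[, 2] == 0 & co[, 3] == 0]
  d2 <- steadyStateFields(d, ctr, ctr)
  f <- d2@cxcl12[idx]
  expect_true(all(f > 0))
  expect_equal(which.max(f), which(idx == ctr))
  # octahedral symmetry: lattice-equivalent sites carry equal field
  orbit <- apply(co, 1, function(p) paste(sort(abs(p)), collapse = ","))
  orbitSpread <- tapply(f, orbit, function(v) diff(range(v)))
  expect_true(all(orbitSpread < 1e-8 * max(f)))
  # strict decay with distance along an axis ray from the source
  onAxis <- co[, 2] == 0 & co[, 3] == 0 & co[, 1] >= 0
  expect_true(all(diff(f[onAxis][order(co[onAxis, 1])]) < 0))
  # light-zone sources give LZ mean > DZ mean
  lzSrc <- idx[d@zone[idx] == 1L][1:5]
  d3 <- suppressWarnings(steadyStateFields(d, integer(0), lzSrc))
  f13 <- d3@cxcl13[idx]
  expect_gt(mean(f13[d@zone[idx] == 1L]), mean(f13[d@zone[idx] == 0L]))
  # no sources: zero field with warning
  expect_warning(steadyStateFields(d, integer(0), lzSrc), "CXCL12")
  expect_true(all(d3@cxcl12 == 0))
  expect_error(steadyStateFields(d, .Machine$integer.max %/% 2L, lzSrc))
})

test_that("stroma placement conserves antigen and respects geometry", {
  d <- buildDomain(160, 5)
  set.seed(3)
  s <- placeStroma(d, nFdc = 5, totalAg = 15000, nTfh = 20)
  expect_equal(sum(s$fdcAg), 15000)
  expect_true(all(s$fdcAg >= 0))
  expect_false(anyDuplicated(s$fdcSites) > 0)
  expect_false(anyDuplicated(s$tfhSites) > 0)
  expect_true(all(d@zone[s$tfhSites] == 1L))
  expect_true(all(d@zone[s$somata] == 1L))
  # an FDC whose soma sits deeper than the arm length has the full
  # 1 + 6 * 8 = 49 sites
  rmax <- (d@nside - 1L) %/% 2L
  co <- domainSites(d)
  set.seed(10)
  for (i in 1:20) {
    s1 <- placeStroma(d, nFdc = 1, totalAg = 3000, nTfh = 1)
    somaCoord <- co[match(s1$somata, which(d@inside)), ]
    if (sqrt(sum(somaCoord^2)) * 5 <= 160 - 40 && somaCoord[3] <= -8) {
      expect_length(s1$fdcSites, 49L)
    } else {
      expect_lte(length(s1$fdcSites), 49L)
    }
  }
  # degenerate: no FDCs means no binding sites
  s0 <- placeStroma(d, nFdc = 0, totalAg = 0, nTfh = 1)
  expect_length(s0$fdcSites, 0L)
  # demand beyond the light zone is a configuration error
  small <- buildDomain(10, 5)
  expect_error(placeStroma(small, nFdc = 1e5, totalAg = 1, nTfh = 1),
               "more FDCs")
})

test_that("persistent random walk has the configured step rate and is
           isotropic without chemotaxis", {
  d <- buildDomain(100, 5)
  zero <- numeric(d@nside^3)
  set.seed(5)
  # restart from the centre periodically so boundary rejections stay rare
  moves <- 0L
  n <- 0L
  disp <- NULL
  for (chunk in 1:4) {
    st <- list(pos = c(0L, 0L, 0L), dir = 0L, persistLeft = 0L)
    for (i in 1:1200) {
      old <- st$pos
      st <- moveCell(st$pos, st$dir, st$persistLeft, d, zero,
                     moveProb = 0.18, chemoWeight = 0, persistSteps = 12)
      if (any(st$pos != old)) moves <- moves + 1L
      n <- n + 1L
      disp <- rbind(disp, st$pos)
    }
  }
  # 7.5 um/min * 7.2 s / 5 um = 0.18 per step
  expect_lt(abs(moves / n - 0.18), 4 * sqrt(0.18 * 0.82 / n))
  # unbiased: mean displacement small relative to path length
  expect_lt(sqrt(sum(colMeans(disp)^2)), 12)
})

test_that("chemotaxis pulls cells toward the source", {
  d <- buildDomain(60, 5)
  idx <- which(d@inside)
  co <- domainSites(d)
  src <- idx[co[, 1] == 0 & co[, 2] == 0 & co[, 3] == -10]
  df <- steadyStateFields(d, src, src)
  set.seed(8)
  finalDist <- replicate(30, {
    st <- list(pos = c(0L, 0L, 10L), dir = 0L, persistLeft = 0L)
    for (i in 1:800)
      st <- moveCell(st$pos, st$dir, st$persistLeft, d, df@cxcl12,
                     moveProb = 0.18, chemoWeight = 0.7, persistSteps = 12)
    sqrt(sum((st$pos - c(0, 0, -10))^2))
  })
  startDist <- sqrt(sum((c(0, 0, 10) - c(0, 0, -10))^2))
  expect_lt(mean(finalDist), startDist / 2)
})
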