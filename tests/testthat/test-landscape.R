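rtAt <- function(temperature) 1.9872e-3 * temperature

test_that("population grids bin points exactly as the brute-force oracle", {
  # 4 identical points on a 2x2 grid occupy a single bin
  p4 <- matrix(rep(c(0.3, 0.7), each = 4L), ncol = 2L)
  g4 <- populationGrid(p4, nBins = 2L, bounds = list(c(0, 1), c(0, 1)))
  expect_equal(sort(as.vector(gridCounts(g4))), c(0L, 0L, 0L, 4L))
  # one point per bin center
  ctr <- expand.grid(x = c(0.25, 0.75), y = c(0.25, 0.75))
  gc <- populationGrid(as.matrix(ctr), nBins = 2L,
                       bounds = list(c(0, 1), c(0, 1)))
  expect_true(all(gridCounts(gc) == 1L))
  # half-open bins, closed top: upper-edge point goes to the higher bin
  ge <- populationGrid(rbind(c(0.5, 0.2), c(1.0, 0.2)), nBins = 2L,
                       bounds = list(c(0, 1), c(0, 1)))
  expect_equal(gridCounts(ge)[2L, 1L], 2L)
  # 1e4 uniform points vs the double-loop oracle, bin for bin
  set.seed(99)
  pts <- matrix(runif(2e4), ncol = 2L)
  g <- populationGrid(pts, nBins = 10L, bounds = list(c(0, 1), c(0, 1)))
  expect_equal(gridCounts(g),
               binCountOracle(pts, g@breaks[[1L]], g@breaks[[2L]]))
  expect_equal(sum(gridCounts(g)), nrow(pts))
  expect_error(populationGrid(cbind(rep(1, 5), 1:5), nBins = 5L),
               "zero-extent")
})

test_that("the statistical free energy formula is exact bin for bin", {
  # counts {4, 2, 1} at 498 K: deltaF = {0, RT ln 2, RT ln 4}
  pts <- rbind(
    matrix(rep(c(0.1, 0.1), 4L), ncol = 2L, byrow = TRUE),
    matrix(rep(c(0.9, 0.1), 2L), ncol = 2L, byrow = TRUE),
    c(0.1, 0.9)
  )
  g <- freeEnergy(
    populationGrid(pts, nBins = 2L, bounds = list(c(0, 1), c(0, 1))), 498
  )
  rt <- rtAt(498)
  expect_equal(rt, 0.9896256, tolerance = 1e-6)
  dF <- deltaF(g)
  expect_equal(dF[1L, 1L], 0)
  expect_equal(dF[2L, 1L], rt * log(2), tolerance = 1e-12)
  expect_equal(dF[1L, 2L], rt * log(4), tolerance = 1e-12)
  expect_true(is.na(dF[2L, 2L]))
  # uniform counts: zero everywhere occupied
  gU <- freeEnergy(
    populationGrid(as.matrix(expand.grid(c(0.25, 0.75), c(0.25, 0.75))),
                   nBins = 2L, bounds = list(c(0, 1), c(0, 1))), 300
  )
  expect_true(all(deltaF(gU) == 0))
  # temperature scaling: deltaF scales exactly with T, counts unchanged
  g2 <- freeEnergy(populationGrid(pts, nBins = 2L,
                                  bounds = list(c(0, 1), c(0, 1))), 996)
  expect_equal(deltaF(g2)[!is.na(deltaF(g2))],
               2 * dF[!is.na(dF)], tolerance = 1e-12)
  expect_identical(gridCounts(g2), gridCounts(g))
})

test_that("reaction paths recover the analytic double-well barrier and
          match the minimax oracle", {
  kT <- 1
  dw <- potentialSpec("double_well", h = 3, a = 1, kappa = 1)
  g <- analyticCountsGrid(dw, kT, xlim = c(-1.6, 1.6), ylim = c(-3, 3),
                          nBins = 50L)
  g <- freeEnergy(g, 1 / 1.9872e-3) # RT = 1 kcal/mol
  left <- halfModalBin(g, positive = FALSE)
  right <- halfModalBin(g, positive = TRUE)
  p <- extractReactionPath(g, startBin = left, endBin = right)
  expect_gt(deltaFActivation(p), 2.9)
  expect_lt(deltaFActivation(p), 3.1)
  oracle <- minimaxBarrierOracle(g, left, right)
  tol <- max(abs(diff(pathProfile(p))))
  expect_lt(abs(deltaFActivation(p) - oracle), tol + 1e-9)
  # start = end: single-bin path with zero barrier
  p0 <- extractReactionPath(g, startBin = left, endBin = left)
  expect_equal(deltaFActivation(p0), 0)
  expect_equal(nrow(p0@binSequence), 1L)
})

test_that("a channel potential yields a flat-topped profile", {
  kT <- 1
  ch <- potentialSpec("channel", h = 3, a = 1, L = 4, kappa = 1)
  g <- freeEnergy(
    analyticCountsGrid(ch, kT, xlim = c(-3.6, 3.6), ylim = c(-3, 3),
                       nBins = 50L),
    1 / 1.9872e-3
  )
  p <- extractReactionPath(g, startBin = halfModalBin(g, FALSE),
                           endBin = halfModalBin(g, TRUE))
  binW <- diff(g@breaks[[1L]])[1L]
  nearTop <- sum(pathProfile(p) >= deltaFActivation(p) - 0.5)
  expect_gte(nearTop, floor(4 / binW))
})

test_that("barrier statistics follow the stated rules on constructed
          profiles", {
  rt1 <- 1 / 1 # constructed grids use RT = 1 via gridFromCounts default
  # profile {0, 3, 1}: barrier 3, the boundary end point is no intermediate
  cnt <- matrix(0L, 3L, 3L)
  cnt[, 2L] <- as.integer(round(1e6 * exp(-c(0, 3, 1))))
  g <- gridFromCounts(cnt)
  p <- barrierStats(
    extractReactionPath(g, startBin = c(1L, 2L), endBin = c(3L, 2L)),
    stabilityThreshold = 1.0
  )
  expect_equal(deltaFActivation(p), 3, tolerance = 1e-3)
  expect_equal(nrow(intermediates(p)), 0L)
  # profile {0, 3, 2.8, 3.0, 0.5} with RT = 1: channel band covers the arc
  # of the three near-top points (3/4 of the four unit segments), and the
  # 0.2-deep dip is not a stable intermediate
  cnt2 <- matrix(0L, 5L, 3L)
  cnt2[, 2L] <- as.integer(round(1e7 * exp(-c(0, 3, 2.8, 3.0, 0.5))))
  g2 <- gridFromCounts(cnt2)
  p2 <- barrierStats(
    extractReactionPath(g2, startBin = c(1L, 2L), endBin = c(5L, 2L))
  )
  expect_equal(channelIndex(p2), 0.75, tolerance = 1e-3)
  ints <- intermediates(p2)
  expect_equal(nrow(ints), 1L)
  expect_equal(ints$depth, 0.2, tolerance = 1e-3)
  expect_false(ints$stable)
  # sharp single-bin peak vs a 10-bin plateau: the plateau's channel index
  # is more than 3x larger
  vSharp <- rep(0, 21)
  vSharp[11L] <- 3
  vPlateau <- c(rep(0, 5), rep(3, 10), rep(0, 6))
  mk <- function(v) {
    m <- matrix(0L, length(v), 3L)
    m[, 2L] <- as.integer(round(1e7 * exp(-v)))
    gridFromCounts(m)
  }
  cSharp <- channelIndex(barrierStats(extractReactionPath(
    mk(vSharp), startBin = c(1L, 2L), endBin = c(21L, 2L)
  )))
  cPlateau <- channelIndex(barrierStats(extractReactionPath(
    mk(vPlateau), startBin = c(1L, 2L), endBin = c(21L, 2L)
  )))
  expect_gt(cPlateau, 3 * cSharp)
})

test_that("barrier estimates tighten with sample size", {
  kT <- rtAt(498)
  dw <- potentialSpec("double_well", h = 3 * kT, a = 1, kappa = 3)
  errAt <- function(n, seed) {
    s <- brownianSample(dw, kT = kT, dt = 0.002, nSteps = n, seed = seed)
    g <- freeEnergy(populationGrid(s, nBins = 50L), 498)
    p <- extractReactionPath(g, startBin = halfModalBin(g, FALSE),
                             endBin = halfModalBin(g, TRUE))
    deltaFActivation(p) - 3 * kT
  }
  # paired seeds, RMS over replicates: the estimate tightens with sampling
  errSmall <- vapply(1:5, function(s) errAt(1e5, 300 + s), numeric(1L))
  errBig <- vapply(1:5, function(s) errAt(1e6, 300 + s), numeric(1L))
  expect_lt(sqrt(mean(errBig^2)), sqrt(mean(errSmall^2)))
})

test_that("the TST rate formula is exact", {
  expect_equal(tstRate(0, 498)$ku, 1e6)
  rt <- rtAt(498)
  expect_equal(tstRate(rt, 498)$ku, 1e6 / exp(1), tolerance = 1e-12)
  expect_equal(tstRate(3.8, 498)$ku, 1e6 * exp(-3.8 / rt),
               tolerance = 1e-12)
  expect_equal(tstRate(1, 300, prefactor = 2e6)$ku,
               2e6 * exp(-1 / rtAt(300)), tolerance = 1e-12)
  expect_error(tstRate(-1, 300), "non-negative")
})
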