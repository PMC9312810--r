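test_that("Brownian sampler reproduces the Boltzmann statistics of a
          harmonic well", {
  spec <- potentialSpec("harmonic", kappa = 1)
  s <- brownianSample(spec, kT = 1, dt = 0.01, nSteps = 1e6, seed = 101)
  expect_equal(nrow(s), 1e6 + 1)
  # analytic Boltzmann variance kT / kappa = 1
  expect_lt(abs(var(s[, 1L]) - 1), 0.05)
  expect_lt(abs(var(s[, 2L]) - 1), 0.05)
  # detailed-balance proxy: sampled marginal vs the analytic Gaussian
  ks <- suppressWarnings(
    ks.test(s[seq(1, nrow(s), by = 200L), 1L], "pnorm", 0, 1)
  )
  expect_lt(unname(ks$statistic), 0.03)
})

test_that("zero temperature pins the sampler at a minimum and bad dt is
          reported", {
  dw <- potentialSpec("double_well", h = 3, a = 1)
  s <- brownianSample(dw, kT = 0, dt = 0.01, nSteps = 100, seed = 1)
  expect_true(all(s[, 1L] == -1) && all(s[, 2L] == 0))
  expect_error(
    brownianSample(dw, kT = 1, dt = 50, nSteps = 1e4, seed = 1),
    "dt"
  )
})

test_that("double-well occupancy matches the Boltzmann ratio from
          quadrature", {
  # a tilted well so the ratio is not trivially 1
  dw <- potentialSpec("double_well", h = 3, a = 1, kappa = 1, tilt = 0.5)
  s <- brownianSample(dw, kT = 1, dt = 0.01, nSteps = 1e6, seed = 202)
  vx <- function(x) 3 * ((x / 1)^2 - 1)^2 + 0.5 * x
  zR <- integrate(function(x) exp(-vx(x)), 0, Inf)$value
  zL <- integrate(function(x) exp(-vx(x)), -Inf, 0)$value
  sampled <- sum(s[, 1L] > 0) / sum(s[, 1L] < 0)
  expect_lt(abs(sampled / (zR / zL) - 1), 0.10)
})

test_that("generators are bit-reproducible for a fixed seed", {
  dw <- potentialSpec("double_well", h = 2, a = 1)
  expect_identical(
    brownianSample(dw, kT = 1, dt = 0.01, nSteps = 500, seed = 7),
    brownianSample(dw, kT = 1, dt = 0.01, nSteps = 500, seed = 7)
  )
  toy <- makeToyNative(30)
  expect_identical(toy$coords, makeToyNative(30)$coords)
  sc <- unfoldingScenario(exitFrame = 20, plateauFrames = 30,
                          totalFrames = 80, seed = 5)
  expect_identical(
    coords(makeUnfoldingTrajectory(toy, sc)),
    coords(makeUnfoldingTrajectory(toy, sc))
  )
})

test_that("the toy native has physical chain geometry and an ideal helix", {
  toy <- makeToyNative(30)
  expect_equal(nrow(toy$coords), 30L)
  d <- sqrt(rowSums(diff(toy$coords)^2))
  expect_true(all(d >= 3.5 & d <= 4.0))
  # successive Calpha pseudo-dihedrals of the helix are constant to < 2 deg
  h <- toy$segments$helix
  dihedrals <- vapply(seq_len(length(h) - 3L), function(i) {
    dihedralOracle(
      toy$coords[h[i], ], toy$coords[h[i + 1L], ],
      toy$coords[h[i + 2L], ], toy$coords[h[i + 3L], ]
    )
  }, numeric(1L))
  expect_true(all(abs(dihedrals - median(dihedrals)) < 2))
  # strand spacing and pairing distance as constructed
  s1 <- toy$coords[toy$segments$strand1, ]
  s2 <- toy$coords[toy$segments$strand2, ]
  expect_equal(unname(sqrt(rowSums(diff(s1)^2))), rep(3.8, nrow(s1) - 1L),
               tolerance = 1e-9)
  expect_equal(min(as.matrix(dist(rbind(s1[1, ], s2[nrow(s2), ])))[1, 2]),
               4.8, tolerance = 1e-9)
  expect_error(makeToyNative(10), "nResidues")
})

test_that("unfolding trajectories realize the prescribed three-phase
          structure", {
  toy <- makeToyNative(30)
  sc <- unfoldingScenario(exitFrame = 50, plateauFrames = 100,
                          totalFrames = 250, expansionFactor = 1.14,
                          finalDisorder = 0.9, seed = 11)
  tr <- makeUnfoldingTrajectory(toy, sc)
  gt <- trajectoryMetadata(tr)$groundTruth
  expect_equal(gt$exitFrame, 50L)
  expect_equal(gt$plateauRange, c(50L, 149L))
  # native frames stay in a tight RMSD cluster around the native structure
  natRmsd <- vapply(1:49, function(f) {
    kabschSuperpose(toy$coords, coords(tr, frame = f))$rmsd
  }, numeric(1L))
  expect_lt(max(natRmsd), 0.5)
  # plateau frames hit the target Rg ratio
  rgN <- radiusOfGyration(toy$coords)
  rgP <- vapply(50:149, function(f) {
    radiusOfGyration(coords(tr, frame = f))
  }, numeric(1L))
  expect_gt(mean(rgP) / rgN, 1.12)
  expect_lt(mean(rgP) / rgN, 1.16)
  # plateau keeps segment-internal geometry (helix intact)
  helix <- toy$segments$helix
  dH <- sqrt(rowSums(diff(coords(tr, frame = 100)[helix, ])^2))
  expect_true(all(abs(dH - 3.83) < 0.6))
  # post-plateau native contacts decay monotonically in the mean
  nset <- nativeContacts(toy$coords)
  cs <- contactTimeseries(tr, toy, nativeSet = nset)
  post <- nativeContactCount(cs)[150:250]
  quarters <- split(post, cut(seq_along(post), 4))
  expect_true(all(diff(vapply(quarters, mean, numeric(1L))) < 0))
})

test_that("finalDisorder = 0 freezes the plateau", {
  toy <- makeToyNative(30)
  sc <- unfoldingScenario(exitFrame = 20, plateauFrames = 40,
                          totalFrames = 100, finalDisorder = 0, seed = 3)
  tr <- makeUnfoldingTrajectory(toy, sc)
  cs <- contactTimeseries(tr, toy)
  plateauQ <- mean(nativeContactCount(cs)[20:59])
  tailQ <- mean(nativeContactCount(cs)[60:100])
  expect_lt(abs(tailQ - plateauQ), 2)
  rg <- rgSeries(cs)
  expect_lt(abs(mean(rg[60:100]) - mean(rg[20:59])), 0.1)
})

test_that("phi ensembles realize the requested contact shifts", {
  toy <- makeToyNative(30)
  pert <- data.frame(mutant = c("a", "b"), tsShift = c(-5, 0),
                     fShift = c(-10, -8))
  pe <- makePhiEnsembles(toy, pert, nFrames = 15, seed = 31)
  nset <- pe$nativeSet
  wtTS <- ensembleMeanContacts(pe$wt$TS, nset)
  wtF <- ensembleMeanContacts(pe$wt$F, nset)
  expect_lt(abs((ensembleMeanContacts(pe$mutants$a$TS, nset) - wtTS) + 5),
            0.5)
  expect_lt(abs((ensembleMeanContacts(pe$mutants$a$F, nset) - wtF) + 10),
            0.5)
  expect_lt(abs(ensembleMeanContacts(pe$mutants$b$TS, nset) - wtTS), 0.5)
  # wild-type F ensemble is the unmodified native plus noise
  pe0 <- makePhiEnsembles(toy, pert, nFrames = 3, noiseSd = 0, seed = 1)
  expect_equal(ensembleMeanContacts(pe0$wt$F, pe0$nativeSet),
               nrow(pe0$nativeSet))
  # unachievable requests error
  expect_error(
    makePhiEnsembles(toy, data.frame(mutant = "x", tsShift = 2,
                                     fShift = -2)),
    "unachievable"
  )
  expect_error(
    makePhiEnsembles(toy, data.frame(mutant = "x", tsShift = -1000,
                                     fShift = -2)),
    "unachievable"
  )
})
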