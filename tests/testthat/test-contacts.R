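test_that("native contacts follow the cutoff and separation rules
          exactly", {
  chain <- cbind(3.8 * (0:9), 0, 0) # straight chain, spacing 3.8
  # |i-j| = 3 pairs sit at 11.4 A: none within 8 A
  expect_equal(nrow(nativeContacts(chain, cutoff = 8, minSeqSep = 3)), 0L)
  # at 12 A exactly the |i-j| = 3 pairs enter (11.4 <= 12 < 15.2)
  nc12 <- nativeContacts(chain, cutoff = 12, minSeqSep = 3)
  expect_equal(nrow(nc12), 7L)
  expect_true(all(nc12[, 2L] - nc12[, 1L] == 3L))
  # exhaustive pair-enumeration oracle on the toy native
  toy <- makeToyNative(30)
  nset <- nativeContacts(toy$coords)
  D <- as.matrix(dist(toy$coords))
  oracle <- 0L
  for (i in 1:27) {
    for (j in (i + 3):30) {
      if (D[i, j] <= 8) oracle <- oracle + 1L
    }
  }
  expect_equal(nrow(nset), oracle)
  expect_true(all(nset[, 1L] < nset[, 2L]))
  # two coincident residues at separation 5 form one contact
  apart <- cbind(100 * (0:6), 0, 0)
  apart[6L, ] <- apart[1L, ]
  ncC <- nativeContacts(apart, cutoff = 8, minSeqSep = 3)
  expect_equal(unname(ncC), matrix(c(1L, 6L), 1L, 2L), ignore_attr = TRUE)
})

test_that("contact series report Q, totals and Rg faithfully", {
  toy <- makeToyNative(30)
  nset <- nativeContacts(toy$coords)
  natTraj <- makeNativeTrajectory(toy, 3, noiseSd = 1e-9, seed = 1)
  cs <- contactTimeseries(natTraj, toy, nativeSet = nset)
  expect_equal(nativeContactCount(cs), rep(nrow(nset), 3L))
  expect_equal(qFraction(cs), rep(1, 3L))
  expect_true(all(nativeContactCount(cs) <= totalContactCount(cs)))
  # a fully extended conformation has no native contacts
  ext <- cbind(3.8 * (0:29), 0, 0)
  arr <- array(NA_real_, c(1L, 30L, 3L))
  arr[1L, , ] <- ext
  extTraj <- new("Trajectory",
    topology = toy$topology, coords = arr, frameInterval = 1,
    originLabel = "extended", metadata = list()
  )
  csE <- contactTimeseries(extTraj, toy, nativeSet = nset)
  expect_equal(nativeContactCount(csE), 0L)
})

test_that("plateau frames retain the segment-internal native contacts", {
  toy <- makeToyNative(30)
  sc <- unfoldingScenario(exitFrame = 20, plateauFrames = 60,
                          totalFrames = 100, seed = 17)
  tr <- makeUnfoldingTrajectory(toy, sc)
  nset <- nativeContacts(toy$coords)
  cs <- contactTimeseries(tr, toy, nativeSet = nset)
  # contacts internal to the helix or to the hairpin survive a rigid-unit
  # expansion by construction, a lower bound on plateau retention; the
  # generator records its realized retention as ground truth
  hairpin <- c(toy$segments$strand1, toy$segments$turn, toy$segments$strand2)
  helix <- toy$segments$helix
  intra <- (nset[, 1L] %in% helix & nset[, 2L] %in% helix) |
    (nset[, 1L] %in% hairpin & nset[, 2L] %in% hairpin)
  lower <- sum(intra) / nrow(nset)
  plateauQ <- mean(qFraction(cs)[20:79])
  expect_gte(plateauQ, lower - 0.02)
  gt <- trajectoryMetadata(tr)$groundTruth
  expect_lt(abs(plateauQ - gt$qRetention), 0.05)
  expect_lt(sd(qFraction(cs)[20:79]), 0.05)
})

test_that("radius of gyration matches closed forms and is rigid-motion
          invariant", {
  expect_equal(radiusOfGyration(matrix(c(5, 2, 9), 1L)), 0)
  expect_equal(radiusOfGyration(rbind(c(0, 0, 0), c(2, 0, 0))), 1)
  sq <- rbind(c(0, 0, 0), c(2, 0, 0), c(2, 2, 0), c(0, 2, 0))
  expect_equal(radiusOfGyration(sq), sqrt(2), tolerance = 1e-12)
  # mass weighting shifts the centroid
  expect_equal(
    radiusOfGyration(rbind(c(0, 0, 0), c(2, 0, 0)), masses = c(3, 1)),
    sqrt((3 * 0.5^2 + 1 * 1.5^2) / 4), tolerance = 1e-12
  )
  R <- randomRotation(11)
  moved <- sweep(sq %*% R, 2L, c(5, -3, 2), "+")
  expect_equal(radiusOfGyration(moved), radiusOfGyration(sq),
               tolerance = 1e-10)
})

test_that("secondary structure assignment recovers the constructed
          motifs", {
  toy <- makeToyNative(30)
  lab <- assignSecondaryStructure(toy$coords)
  expect_true(all(lab[toy$segments$helix] == "H"))
  # most strand residues are E; the hairpin pairing is required
  s1 <- toy$segments$strand1
  s2 <- toy$segments$strand2
  expect_gte(sum(lab[c(s1, s2)] == "E"), 8L)
  # a straight chain with no partner strand gets no E labels
  ext <- cbind(3.8 * (0:19), 0, 0)
  expect_true(all(assignSecondaryStructure(ext) == "C"))
  expect_error(assignSecondaryStructure(ext[1:4, ]), "5 residues")
})

test_that("molten-globule classification follows the stated rules", {
  mkSeries <- function(qFrac, rgRatio) {
    n <- length(qFrac)
    new("ContactSeries",
      nativeSet = cbind(1:10, 4:13), q = as.integer(round(qFrac * 10)),
      total = rep(20L, n), qFraction = qFrac,
      rg = rgRatio * 10, rgNative = 10,
      definition = list(cutoff = 8, minSeqSep = 3L)
    )
  }
  mkSS <- function(pers) {
    n <- length(pers)
    new("SecondaryStructureTimeline",
      labels = matrix("H", n, 4L), nativeLabels = rep("H", 4L),
      persistenceByResidue = rep(1, 4L), persistenceByFrame = pers
    )
  }
  cls <- classifyMoltenGlobule(
    mkSeries(c(0.95, 0.60, 0.05), c(1.00, 1.14, 1.30)),
    mkSS(c(0.95, 0.80, 0.10))
  )
  expect_equal(as.character(cls),
               c("native", "molten_globule", "unfolded"))
  expect_error(
    classifyMoltenGlobule(mkSeries(0.5, 1.1), mkSS(0.5), qLo = 1.5),
    "\\[0, 1\\]"
  )
})

test_that("transition demarcation anchors at the exit and merges gaps", {
  mkExit <- function(frame) {
    new("NativeExit",
      exitFrame = as.integer(frame), exitTime = frame * 0.01,
      threshold = 1, referenceWindow = c(1L, 25L), persistence = 10L,
      clusterRadius = 1
    )
  }
  classes <- factor(
    rep(c("native", "molten_globule", "unfolded"), c(100L, 200L, 100L)),
    levels = c("native", "molten_globule", "unfolded")
  )
  te <- demarcateTransition(mkExit(101), classes)
  expect_equal(frameRange(te), c(101L, 300L))
  expect_equal(length(memberFrames(te)), 200L)
  # an MG run broken by 3 unfolded frames merges at G = 10
  broken <- classes
  broken[150:152] <- "unfolded"
  teB <- demarcateTransition(mkExit(101), broken, gapTolerance = 10L)
  expect_equal(frameRange(teB), c(101L, 300L))
  expect_equal(length(memberFrames(teB)), 197L)
  # no MG after the exit: empty ensemble with a warning
  none <- factor(rep(c("native", "unfolded"), c(100L, 100L)),
                 levels = levels(classes))
  expect_warning(teN <- demarcateTransition(mkExit(101), none), "empty")
  expect_equal(length(memberFrames(teN)), 0L)
})

test_that("helix persistence stays high through the plateau", {
  toy <- makeToyNative(30)
  tr <- makeUnfoldingTrajectory(
    toy, unfoldingScenario(exitFrame = 20, plateauFrames = 50,
                           totalFrames = 90, seed = 23)
  )
  ss <- secondaryStructureTimeline(tr, toy)
  helix <- toy$segments$helix
  plateauLabels <- ssLabels(ss)[20:69, helix, drop = FALSE]
  expect_gte(mean(plateauLabels == "H"), 0.8)
})
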