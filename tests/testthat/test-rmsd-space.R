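test_that("Kabsch superposition is exact on rigid motions and matches the
          quaternion oracle", {
  set.seed(42)
  X <- matrix(rnorm(30), ncol = 3L)
  # identity
  fit <- kabschSuperpose(X, X)
  expect_equal(fit$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-9)
  # 90-degree rotation about z plus translation
  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3L, 3L, byrow = TRUE)
  Y <- sweep(X %*% t(Rz), 2L, c(1, 2, 3), "+")
  expect_lt(kabschSuperpose(X, Y)$rmsd, 1e-10)
  # rotations are proper: no reflection shortcut for mirrored coordinates
  Ymir <- X
  Ymir[, 1L] <- -Ymir[, 1L]
  expect_equal(det(kabschSuperpose(X, Ymir)$rotation), 1, tolerance = 1e-9)
  # unit square with one lifted corner, against brute-force quaternions
  Xs <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  Ys <- Xs
  Ys[3L, 3L] <- 1
  expect_lt(abs(kabschSuperpose(Xs, Ys)$rmsd - quatRmsdOracle(Xs, Ys)),
            1e-6)
  # degenerate selections error
  line <- cbind(1:5, 0, 0)
  expect_error(kabschSuperpose(line, line), "degenerate")
  expect_error(kabschSuperpose(X[1:2, ], X[1:2, ]), "3 selected")
})

test_that("the 2DRMSD matrix equals per-pair recomputation and is a
          metric", {
  toy <- makeToyNative(24)
  tr <- makeNativeTrajectory(toy, nFrames = 5, noiseSd = 1.5, seed = 8)
  D <- as.matrix(pairwiseRmsdMatrix(tr))
  # per-pair oracle
  for (i in 1:4) {
    for (j in (i + 1):5) {
      ref <- kabschSuperpose(coords(tr, frame = i),
                             coords(tr, frame = j))$rmsd
      expect_lt(abs(D[i, j] - ref), 1e-9)
    }
  }
  expect_equal(D, t(D))
  expect_equal(diag(D), rep(0, 5))
  # identical frames give the zero matrix
  trSame <- tr[rep(1L, 4L)]
  expect_lt(max(abs(as.matrix(pairwiseRmsdMatrix(trSame)))), 1e-9)
  # two frames: off-diagonal equals the single pair rmsd
  D2 <- as.matrix(pairwiseRmsdMatrix(tr[1:2]))
  expect_equal(D2[1L, 2L],
               kabschSuperpose(coords(tr, frame = 1),
                               coords(tr, frame = 2))$rmsd,
               tolerance = 1e-9)
  # triangle inequality over all triples of a larger fixture
  tr2 <- makeUnfoldingTrajectory(
    toy, unfoldingScenario(exitFrame = 15, plateauFrames = 15,
                           totalFrames = 40, seed = 2)
  )
  M <- as.matrix(pairwiseRmsdMatrix(tr2))
  n <- nrow(M)
  for (i in 1:(n - 2)) {
    for (j in (i + 1):(n - 1)) {
      for (k in (j + 1):n) {
        expect_lte(M[i, k], M[i, j] + M[j, k] + 1e-9)
        expect_lte(M[i, j], M[i, k] + M[j, k] + 1e-9)
        expect_lte(M[j, k], M[i, j] + M[i, k] + 1e-9)
      }
    }
  }
})

test_that("classical MDS reproduces exact Euclidean geometries", {
  # collinear points 0, 1, 3
  D <- as.matrix(dist(matrix(c(0, 1, 3), ncol = 1L)))
  emb <- classicalMDS(D, k = 1L)
  expect_equal(as.matrix(dist(coords(emb))), D, tolerance = 1e-10,
               ignore_attr = TRUE)
  # equilateral triangle, side 1
  tri <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  embT <- classicalMDS(as.matrix(dist(tri)), k = 2L)
  expect_equal(as.vector(dist(coords(embT))), rep(1, 3), tolerance = 1e-9)
  expect_equal(explainedFraction(embT), 1, tolerance = 1e-9)
  # all-zero distances put every point at the origin
  emb0 <- classicalMDS(matrix(0, 4L, 4L), k = 2L)
  expect_true(all(coords(emb0) == 0))
  # random Euclidean configuration: distances reproduced, and the
  # embedding agrees with the independent cmdscale route up to rigid motion
  set.seed(5)
  P <- matrix(rnorm(60), ncol = 3L)
  Dp <- as.matrix(dist(P))
  embP <- classicalMDS(Dp, k = 3L)
  expect_lt(max(abs(as.matrix(dist(coords(embP))) - Dp)), 1e-8)
  ref <- cmdscale(Dp, k = 3L)
  expect_lt(procrustesResidual(coords(embP), ref), 1e-8)
  expect_lt(procrustesResidual(coords(embP), P), 1e-8)
  expect_error(classicalMDS(Dp[1:3, 1:3], k = 3L), "k \\+ 1")
})

test_that("step vectors are exact consecutive differences", {
  pts <- rbind(c(0, 0), c(1, 0), c(1, 2), c(-1, 2))
  sv <- stepVectors(pts, frameInterval = 0.5)
  expect_equal(displacements(sv),
               rbind(c(1, 0), c(0, 2), c(-2, 0)))
  expect_equal(stepNorms(sv), c(1, 2, 2))
  expect_equal(terminals(sv), pts)
  # constant embedding: all norms zero
  expect_equal(stepNorms(stepVectors(matrix(1, 5L, 2L))), rep(0, 4L))
  # collinear points spaced 1 apart: all norms one
  expect_equal(stepNorms(stepVectors(cbind(0:9, 0))), rep(1, 9L))
})

test_that("native-exit detection finds planted jumps and nothing else", {
  set.seed(77)
  # stationary control: random-direction steps with norms ~ N(1, 0.05)
  dirs <- matrix(rnorm(599 * 3), ncol = 3L)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  steps <- dirs * rnorm(599, mean = 1, sd = 0.05)
  walk <- apply(rbind(0, steps), 2L, cumsum)
  svQuiet <- stepVectors(walk, frameInterval = 0.1)
  exQuiet <- detectNativeExit(svQuiet)
  expect_true(is.na(exitFrame(exQuiet)))
  # a displacement of norm 10 at frame 501, persisting thereafter
  jitter <- matrix(rnorm(600 * 3, sd = 0.05), ncol = 3L)
  pts <- jitter
  pts[501:600, 1L] <- pts[501:600, 1L] + 50
  sv <- stepVectors(pts, frameInterval = 0.1)
  ex <- detectNativeExit(sv)
  expect_equal(exitFrame(ex), 501L)
  expect_equal(exitTime(ex), 500 * 0.1)
  # invariance to rigid rotation of the embedding
  R <- randomRotation(3)
  exR <- detectNativeExit(stepVectors(pts %*% R, frameInterval = 0.1))
  expect_equal(exitFrame(exR), 501L)
  # uniform time rescaling changes the time, not the frame
  exT <- detectNativeExit(stepVectors(pts, frameInterval = 1))
  expect_equal(exitFrame(exT), 501L)
  expect_equal(exitTime(exT), 500)
  # reference window must be long enough and precede candidates
  expect_error(detectNativeExit(sv, referenceWindow = 1:5), "at least 10")
  expect_error(detectNativeExit(sv, referenceWindow = 1:600), "precede")
})

test_that("the synthetic unfolding fixture is low-dimensional in RMSD
          space", {
  toy <- makeToyNative(30)
  tr <- makeUnfoldingTrajectory(
    toy, unfoldingScenario(exitFrame = 40, plateauFrames = 60,
                           totalFrames = 150, seed = 13)
  )
  emb <- classicalMDS(pairwiseRmsdMatrix(tr), k = 3L)
  expect_gt(explainedFraction(emb), 0.7)
})
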