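#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimizing the RMSD between two
#' coordinate sets, via SVD of the cross-covariance matrix with the usual
#' determinant correction so reflections are excluded. The returned RMSD is
#' the minimum over all rigid motions.
#'
#' @param X,Y numeric n x 3 coordinate matrices (Angstrom). \code{Y} is
#'   superposed onto \code{X}.
#' @param mask optional logical or integer atom selection applied to both.
#' @return list with \code{rotation} (3 x 3, det +1), \code{translation}
#'   (length 3; the fitted coordinates are \code{Y \%*\% rotation} shifted by
#'   it) and \code{rmsd} (Angstrom).
#' @examples
#' X <- matrix(rnorm(30), ncol = 3)
#' kabschSuperpose(X, X)$rmsd
#' @export
kabschSuperpose <- function(X, Y, mask = NULL) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (!is.null(mask)) {
    X <- X[mask, , drop = FALSE]
    Y <- Y[mask, , drop = FALSE]
  }
  if (nrow(X) != nrow(Y)) stop("selections must have equal atom counts")
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 selected atoms")
  cx <- colMeans(X)
  cy <- colMeans(Y)
  Xc <- sweep(X, 2L, cx)
  Yc <- sweep(Y, 2L, cy)
  svX <- svd(Xc, nu = 0L, nv = 0L)$d
  svY <- svd(Yc, nu = 0L, nv = 0L)$d
  if (svX[2L] < 1e-9 * max(svX[1L], 1e-12) ||
      svY[2L] < 1e-9 * max(svY[1L], 1e-12)) {
    stop("degenerate selection: atoms are collinear or coincident")
  }
  C <- crossprod(Yc, Xc) # 3 x 3
  s <- svd(C)
  d <- sign(det(s$u %*% t(s$v)))
  if (d == 0) d <- 1
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  e2 <- sum(Xc^2) + sum(Yc^2) - 2 * (s$d[1L] + s$d[2L] + d * s$d[3L])
  rmsd <- sqrt(max(e2, 0) / n)
  translation <- cx - as.numeric(cy %*% R)
  list(rotation = R, translation = translation, rmsd = rmsd)
}

#' Pairwise C-alpha RMSD matrix (2DRMSD)
#'
#' Computes the full matrix of optimal-superposition RMSD values between all
#' retained frame pairs of a trajectory over the C-alpha selection (or a
#' user mask). The per-pair work is organised as one 3 x (3T) matrix product
#' per frame followed by 3 x 3 SVDs, so the quadratic cost stays tractable;
#' the default stride keeps T at or below \code{maxFrames} (memory and time
#' control for long trajectories).
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param mask optional logical/integer atom selection; default the topology
#'   C-alpha mask.
#' @param stride positive integer; default chosen so that at most
#'   \code{maxFrames} frames enter the matrix.
#' @param maxFrames cap on the matrix dimension used when \code{stride} is
#'   NULL (default 2000).
#' @return a \linkS4class{DistanceMatrix}.
#' @export
pairwiseRmsdMatrix <- function(traj, mask = NULL, stride = NULL,
                               maxFrames = 2000L) {
  stopifnot(is(traj, "Trajectory"))
  if (is.null(mask)) mask <- calphaMask(topology(traj))
  nT0 <- nFrames(traj)
  if (is.null(stride)) {
    stride <- max(1L, ceiling(nT0 / maxFrames))
  }
  stride <- .assertCount(stride, "stride")
  keep <- seq(1L, nT0, by = stride)
  nT <- length(keep)
  if (nT < 1L) stop("no frames left after stride")
  centered <- vector("list", nT)
  sq <- numeric(nT)
  for (f in seq_len(nT)) {
    Xf <- coords(traj, frame = keep[f])[mask, , drop = FALSE]
    Xf <- sweep(Xf, 2L, colMeans(Xf))
    centered[[f]] <- Xf
    sq[f] <- sum(Xf^2)
  }
  nA <- nrow(centered[[1L]])
  if (nA < 3L) stop("need at least 3 selected atoms")
  # all centered frames side by side: nA x 3T
  flat <- matrix(unlist(centered), nrow = nA)
  D <- matrix(0, nT, nT)
  for (i in seq_len(nT - 1L)) {
    P <- crossprod(centered[[i]], flat) # 3 x 3T
    for (j in seq.int(i + 1L, nT)) {
      Cij <- P[, (3L * (j - 1L) + 1L):(3L * j)]
      sv <- svd(Cij)
      d <- sign(det(sv$u %*% t(sv$v)))
      if (d == 0) d <- 1
      e2 <- sq[i] + sq[j] - 2 * (sv$d[1L] + sv$d[2L] + d * sv$d[3L])
      D[i, j] <- D[j, i] <- sqrt(max(e2, 0) / nA)
    }
  }
  new("DistanceMatrix",
    values = D, frameIndices = as.integer(keep),
    strideUsed = stride
  )
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Embeds a distance matrix in k dimensions by double centering the squared
#' distances (B = -J D^2 J / 2), eigendecomposition, and retention of the top
#' k positive eigenvalues. Negative eigenvalues (RMSD matrices are near- but
#' not exactly Euclidean) are clamped out of the embedding; their magnitude
#' fraction is kept as a diagnostic. For an exactly Euclidean matrix of
#' intrinsic dimension d <= k the embedded pairwise distances reproduce the
#' input to numerical precision.
#'
#' @param D a \linkS4class{DistanceMatrix} or a plain symmetric matrix.
#' @param k number of axes to retain (default 3, matching the usual 3D RMSD
#'   space; fewer are returned if fewer positive eigenvalues exist).
#' @return an \linkS4class{RmsdEmbedding}.
#' @export
classicalMDS <- function(D, k = 3L) {
  k <- .assertCount(k, "k")
  M <- if (is(D, "DistanceMatrix")) D@values else as.matrix(D)
  nT <- nrow(M)
  if (nT < k + 1L) stop("need at least k + 1 frames")
  D2 <- M^2
  rm <- rowMeans(D2)
  B <- -0.5 * (D2 - outer(rm, rep(1, nT)) - outer(rep(1, nT), rm) + mean(D2))
  e <- eigen(B, symmetric = TRUE)
  vals <- e$values
  tolPos <- max(abs(vals)) * 1e-12
  pos <- which(vals > tolPos)
  if (length(pos) == 0L) {
    if (max(abs(M)) < 1e-12) {
      # all distances zero: every point sits at the origin
      return(new("RmsdEmbedding",
        coords = matrix(0, nT, k), eigenvalues = rep(0, k),
        explainedFraction = 1, negativeFraction = 0, k = k
      ))
    }
    stop("no positive eigenvalues: pathological distance matrix")
  }
  kUse <- min(k, length(pos))
  idx <- pos[seq_len(kUse)]
  coords <- e$vectors[, idx, drop = FALSE] %*%
    diag(sqrt(vals[idx]), kUse)
  negativeMass <- sum(abs(vals[vals < 0]))
  totalMass <- sum(abs(vals))
  new("RmsdEmbedding",
    coords = coords,
    eigenvalues = vals[idx],
    explainedFraction = sum(vals[idx]) / sum(vals[pos]),
    negativeFraction = if (totalMass > 0) negativeMass / totalMass else 0,
    k = kUse
  )
}

#' MD step vectors
#'
#' Differences between consecutive embedded frames. The embedded points are
#' the step-vector terminals whose population map the free-energy landscape
#' is built from.
#'
#' @param emb an \linkS4class{RmsdEmbedding} (or a plain T x k coordinate
#'   matrix).
#' @param frameInterval ns between consecutive frames (default 1).
#' @return a \linkS4class{StepVectorSeries}.
#' @export
stepVectors <- function(emb, frameInterval = 1) {
  pts <- if (is(emb, "RmsdEmbedding")) coords(emb) else as.matrix(emb)
  if (nrow(pts) < 2L) stop("need at least 2 frames")
  frameInterval <- .assertPositive(frameInterval, "frameInterval")
  disp <- diff(pts)
  new("StepVectorSeries",
    displacements = disp,
    norms = sqrt(rowSums(disp^2)),
    terminals = pts,
    frameInterval = frameInterval
  )
}

#' Detect the first exit from the native-state ensemble
#'
#' Leader-style jump detection on the step-vector series: the native cluster
#' is summarized by the centroid and radius of an early reference window,
#' and the exit is the first frame whose incoming step norm exceeds
#' mean + c * SD of the reference-window norms \emph{and} which stays
#' further than the cluster radius from the centroid for at least m
#' subsequent frames (the paper-style "first precipitous change" made
#' persistent). Returns a no-exit report when no frame qualifies.
#'
#' @param series a \linkS4class{StepVectorSeries}.
#' @param referenceWindow integer vector of frames assumed native; default
#'   the first 5\% of frames (at least 10).
#' @param c threshold multiplier on the reference-window step-norm SD
#'   (default 5).
#' @param m persistence in frames (default 10).
#' @return a \linkS4class{NativeExit}.
#' @export
detectNativeExit <- function(series, referenceWindow = NULL, c = 5, m = 10L) {
  stopifnot(is(series, "StepVectorSeries"))
  pts <- series@terminals
  nT <- nrow(pts)
  if (is.null(referenceWindow)) {
    referenceWindow <- seq_len(max(10L, floor(0.05 * nT)))
  }
  referenceWindow <- sort(as.integer(referenceWindow))
  if (length(referenceWindow) < 10L) {
    stop("reference window must contain at least 10 frames")
  }
  if (max(referenceWindow) >= nT) {
    stop("reference window must precede the candidate region")
  }
  m <- .assertCount(m, "m")
  c <- .assertPositive(c, "c")
  refSteps <- referenceWindow[referenceWindow < max(referenceWindow)]
  refNorms <- series@norms[refSteps]
  threshold <- mean(refNorms) + c * stats::sd(refNorms)
  centroid <- colMeans(pts[referenceWindow, , drop = FALSE])
  distTo <- sqrt(rowSums(
    sweep(pts, 2L, centroid)^2
  ))
  radius <- max(distTo[referenceWindow])
  firstCandidate <- max(referenceWindow) + 1L
  exit <- NA_integer_
  for (f in seq.int(firstCandidate, nT)) {
    if (series@norms[f - 1L] <= threshold) next
    span <- f:min(f + m - 1L, nT)
    if (all(distTo[span] > radius)) {
      exit <- f
      break
    }
  }
  new("NativeExit",
    exitFrame = exit,
    exitTime = if (is.na(exit)) NA_real_ else {
      (exit - 1L) * series@frameInterval
    },
    threshold = threshold,
    referenceWindow = range(referenceWindow),
    persistence = m,
    clusterRadius = radius
  )
}
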