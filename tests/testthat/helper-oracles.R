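# Independent oracles used across the suite. These deliberately re-derive
# quantities along different algorithmic routes than the package takes.

# rotation matrix from a (not necessarily unit) quaternion
.quat2mat <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3L, 3L, byrow = TRUE)
}

# brute-force minimal RMSD via random quaternion search plus Nelder-Mead
# refinement; independent of the SVD route
quatRmsdOracle <- function(X, Y, nCoarse = 3000L, seed = 1L) {
  Xc <- sweep(X, 2L, colMeans(X))
  Yc <- sweep(Y, 2L, colMeans(Y))
  obj <- function(q) {
    R <- .quat2mat(q)
    sqrt(mean(rowSums((Xc - Yc %*% R)^2)))
  }
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  qs <- matrix(rnorm(4L * nCoarse), ncol = 4L)
  vals <- apply(qs, 1L, obj)
  best <- qs[which.min(vals), ]
  for (rep in 1:3) {
    o <- stats::optim(best, obj,
      method = "Nelder-Mead",
      control = list(maxit = 5000L, reltol = 1e-16)
    )
    best <- o$par
  }
  o$value
}

# flood fill over passable bins (8-connectivity) by repeated dilation
.flood <- function(pass, start) {
  nr <- nrow(pass)
  nc <- ncol(pass)
  vis <- matrix(FALSE, nr, nc)
  vis[start[1L], start[2L]] <- TRUE
  shift <- function(m, di, dj) {
    out <- matrix(FALSE, nr, nc)
    ri <- max(1L, 1L + di):min(nr, nr + di)
    rj <- max(1L, 1L + dj):min(nc, nc + dj)
    out[ri, rj] <- m[ri - di, rj - dj]
    out
  }
  repeat {
    grown <- vis
    for (di in -1:1) {
      for (dj in -1:1) {
        if (di == 0L && dj == 0L) next
        grown <- grown | shift(vis, di, dj)
      }
    }
    grown <- grown & pass
    if (identical(grown, vis)) break
    vis <- grown
  }
  vis
}

# exhaustive minimax-path oracle: the smallest deltaF threshold at which
# start and end become connected through occupied bins (binary search over
# the sorted unique deltaF values plus flood fill); equals the maximum
# deltaF along the optimal minimum-barrier route
minimaxBarrierOracle <- function(grid, start, end) {
  dF <- deltaF(grid)
  occ <- gridCounts(grid) > 0
  vals <- sort(unique(dF[occ]))
  connects <- function(thr) {
    pass <- occ & !is.na(dF) & dF <= thr
    if (!pass[start[1L], start[2L]] || !pass[end[1L], end[2L]]) return(FALSE)
    vis <- .flood(pass, start)
    vis[end[1L], end[2L]]
  }
  lo <- 1L
  hi <- length(vals)
  if (!connects(vals[hi])) return(NA_real_)
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (connects(vals[mid])) hi <- mid else lo <- mid + 1L
  }
  vals[lo]
}

# orthogonal-Procrustes residual (rotation/reflection allowed): embeddings
# are determined only up to an orthogonal transform
procrustesResidual <- function(A, B) {
  A <- sweep(A, 2L, colMeans(A))
  B <- sweep(B, 2L, colMeans(B))
  s <- svd(crossprod(B, A))
  R <- s$u %*% t(s$v)
  sqrt(sum((A - B %*% R)^2))
}

# brute-force half-open binning oracle (double loop over points and edges)
binCountOracle <- function(pts, breaksX, breaksY) {
  nx <- length(breaksX) - 1L
  ny <- length(breaksY) - 1L
  counts <- matrix(0L, nx, ny)
  for (p in seq_len(nrow(pts))) {
    ix <- NA_integer_
    for (b in seq_len(nx)) {
      hi <- if (b == nx) breaksX[b + 1L] + 1e-12 else breaksX[b + 1L]
      if (pts[p, 1L] >= breaksX[b] && pts[p, 1L] < hi) {
        ix <- b
        break
      }
    }
    iy <- NA_integer_
    for (b in seq_len(ny)) {
      hi <- if (b == ny) breaksY[b + 1L] + 1e-12 else breaksY[b + 1L]
      if (pts[p, 2L] >= breaksY[b] && pts[p, 2L] < hi) {
        iy <- b
        break
      }
    }
    counts[ix, iy] <- counts[ix, iy] + 1L
  }
  counts
}

# dihedral angle (degrees) of four points, cross-product route
dihedralOracle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- c(
    b1[2L] * b2[3L] - b1[3L] * b2[2L],
    b1[3L] * b2[1L] - b1[1L] * b2[3L],
    b1[1L] * b2[2L] - b1[2L] * b2[1L]
  )
  n2 <- c(
    b2[2L] * b3[3L] - b2[3L] * b3[2L],
    b2[3L] * b3[1L] - b2[1L] * b3[3L],
    b2[1L] * b3[2L] - b2[2L] * b3[1L]
  )
  m1 <- n1 / sqrt(sum(n1^2))
  m2 <- n2 / sqrt(sum(n2^2))
  b2u <- b2 / sqrt(sum(b2^2))
  x <- sum(m1 * m2)
  y <- sum(
    c(
      m1[2L] * m2[3L] - m1[3L] * m2[2L],
      m1[3L] * m2[1L] - m1[1L] * m2[3L],
      m1[1L] * m2[2L] - m1[2L] * m2[1L]
    ) * b2u
  )
  atan2(y, x) * 180 / pi
}

# random proper rotation matrix
randomRotation <- function(seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  M <- matrix(rnorm(9L), 3L, 3L)
  q <- qr(M)
  R <- qr.Q(q)
  if (det(R) < 0) R[, 1L] <- -R[, 1L]
  R
}

# build a LandscapeGrid directly from a counts matrix (unit-spaced bins),
# for constructed-profile tests
gridFromCounts <- function(counts, temperature = 1 / 1.9872e-3) {
  nx <- nrow(counts)
  ny <- ncol(counts)
  g <- new("LandscapeGrid",
    counts = counts,
    breaks = list(seq(0, nx), seq(0, ny)),
    midpoints = list(seq(0.5, nx - 0.5), seq(0.5, ny - 0.5)),
    deltaF = matrix(NA_real_, nx, ny),
    rt = NA_real_, temperature = NA_real_,
    nPoints = sum(counts), axes = c(1L, 2L)
  )
  freeEnergy(g, temperature)
}

# counts grid implied by Boltzmann sampling of an analytic potential
analyticCountsGrid <- function(spec, kT, xlim, ylim, nBins = 50L,
                               nTotal = 1e7) {
  bx <- seq(xlim[1L], xlim[2L], length.out = nBins + 1L)
  by <- seq(ylim[1L], ylim[2L], length.out = nBins + 1L)
  mx <- (bx[-1L] + bx[-length(bx)]) / 2
  my <- (by[-1L] + by[-length(by)]) / 2
  V <- outer(mx, my, function(x, y) potentialEnergy(spec, x, y))
  w <- exp(-V / kT)
  counts <- matrix(as.integer(round(nTotal * w / sum(w))), nBins, nBins)
  new("LandscapeGrid",
    counts = counts,
    breaks = list(bx, by),
    midpoints = list(mx, my),
    deltaF = matrix(NA_real_, nBins, nBins),
    rt = NA_real_, temperature = NA_real_,
    nPoints = sum(counts), axes = c(1L, 2L)
  )
}

# modal bin of the x > 0 (or x < 0) half of a grid, used to anchor the two
# wells of a sampled double-well landscape
halfModalBin <- function(grid, positive = TRUE) {
  cnt <- gridCounts(grid)
  mx <- grid@midpoints[[1L]]
  keep <- if (positive) mx > 0 else mx < 0
  sub <- cnt[keep, , drop = FALSE]
  lin <- which.max(sub)
  i <- (lin - 1L) %% nrow(sub) + 1L
  j <- (lin - 1L) %/% nrow(sub) + 1L
  c(which(keep)[i], j)
}
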