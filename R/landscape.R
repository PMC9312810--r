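#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Bin step-vector terminals on a 2D grid
#'
#' Histograms embedded points on a regular 2D grid over two chosen embedding
#' axes (choosing two axes of a 3D embedding marginalizes the third). All
#' frames contribute — the landscape represents 100\% of the trajectory, not
#' just the transition region. Bins are half-open with the global upper edge
#' closed, so a point on a bin's upper edge falls in the higher bin except at
#' the very top.
#'
#' @param points a \linkS4class{StepVectorSeries}, \linkS4class{RmsdEmbedding}
#'   or plain numeric matrix of points.
#' @param axes which two columns to bin (default c(1, 2)).
#' @param nBins bins per axis, scalar or length 2 (default 50).
#' @param bounds optional list of two (min, max) pairs; default the data
#'   extent padded by one bin on each side.
#' @return a \linkS4class{LandscapeGrid} with counts only (apply
#'   \code{\link{freeEnergy}} to fill deltaF).
#' @export
populationGrid <- function(points, axes = c(1L, 2L), nBins = 50L,
                           bounds = NULL) {
  pts <- if (is(points, "StepVectorSeries")) {
    points@terminals
  } else if (is(points, "RmsdEmbedding")) {
    points@coords
  } else {
    as.matrix(points)
  }
  if (nrow(pts) < 1L) stop("need at least one point")
  axes <- as.integer(axes)
  if (length(axes) != 2L || any(axes < 1L) || any(axes > ncol(pts))) {
    stop("axes must name two columns of the point set")
  }
  pts <- pts[, axes, drop = FALSE]
  nBins <- rep_len(as.integer(nBins), 2L)
  if (any(nBins < 2L)) stop("need at least 2 bins per axis")
  breaks <- vector("list", 2L)
  for (d in 1:2) {
    if (is.null(bounds)) {
      rng <- range(pts[, d])
      if (diff(rng) <= 0) stop("zero-extent axis ", d)
      pad <- diff(rng) / nBins[d]
      lo <- rng[1L] - pad
      hi <- rng[2L] + pad
    } else {
      lo <- bounds[[d]][1L]
      hi <- bounds[[d]][2L]
      if (hi <= lo) stop("zero-extent axis ", d)
    }
    breaks[[d]] <- seq(lo, hi, length.out = nBins[d] + 1L)
  }
  idx <- matrix(0L, nrow(pts), 2L)
  for (d in 1:2) {
    b <- breaks[[d]]
    w <- (b[length(b)] - b[1L]) / nBins[d]
    id <- floor((pts[, d] - b[1L]) / w) + 1L
    id[pts[, d] >= b[length(b)]] <- nBins[d] # closed top edge
    if (any(id < 1L | id > nBins[d])) {
      stop("points outside the supplied bounds on axis ", d)
    }
    idx[, d] <- id
  }
  counts <- matrix(0L, nBins[1L], nBins[2L])
  lin <- (idx[, 2L] - 1L) * nBins[1L] + idx[, 1L]
  tab <- tabulate(lin, nbins = nBins[1L] * nBins[2L])
  counts[] <- tab
  mids <- lapply(breaks, function(b) (b[-1L] + b[-length(b)]) / 2)
  new("LandscapeGrid",
    counts = counts, breaks = breaks, midpoints = mids,
    deltaF = matrix(NA_real_, nBins[1L], nBins[2L]),
    rt = NA_real_, temperature = NA_real_,
    nPoints = nrow(pts), axes = axes
  )
}

#' Statistical free energy from bin populations
#'
#' Fills deltaF = -RT log(P / P0) for every occupied bin, with P0 the
#' maximum bin population, so the modal bin sits at zero by construction.
#' Empty bins keep the NA sentinel (treated as infinitely high by path
#' extraction: paths must not cross unsampled space). R = 1.9872e-3
#' kcal/(mol K).
#'
#' @param grid a \linkS4class{LandscapeGrid} from \code{\link{populationGrid}}.
#' @param temperature analysis temperature in K.
#' @return the grid with deltaF, rt and temperature filled.
#' @export
freeEnergy <- function(grid, temperature) {
  stopifnot(is(grid, "LandscapeGrid"))
  temperature <- .assertPositive(temperature, "temperature")
  if (!any(grid@counts > 0)) stop("grid has no occupied bin")
  rt <- .RGAS * temperature
  p0 <- max(grid@counts)
  dF <- matrix(NA_real_, nrow(grid@counts), ncol(grid@counts))
  occ <- grid@counts > 0
  dF[occ] <- -rt * log(grid@counts[occ] / p0)
  grid@deltaF <- dF
  grid@rt <- rt
  grid@temperature <- temperature
  grid
}

# Chebyshev distance between two (row, col) bins.
.cheby <- function(a, b) max(abs(a - b))

# 8-connected component of `start` over the occupied bins (logical matrix).
.componentOf <- function(occ, start) {
  nr <- nrow(occ)
  nc <- ncol(occ)
  comp <- matrix(FALSE, nr, nc)
  if (!occ[start[1L], start[2L]]) return(comp)
  comp[start[1L], start[2L]] <- TRUE
  queue <- list(start)
  while (length(queue)) {
    cur <- queue[[1L]]
    queue <- queue[-1L]
    for (di in -1:1) {
      for (dj in -1:1) {
        ni <- cur[1L] + di
        nj <- cur[2L] + dj
        if (ni < 1L || ni > nr || nj < 1L || nj > nc) next
        if (occ[ni, nj] && !comp[ni, nj]) {
          comp[ni, nj] <- TRUE
          queue[[length(queue) + 1L]] <- c(ni, nj)
        }
      }
    }
  }
  comp
}

# Dijkstra-style minimax path over occupied bins: minimizes the maximum
# node deltaF along the route (ties broken by fewer hops, then lowest
# linear index), the discrete minimum-free-energy path. Returns an n x 2
# index matrix or NULL when start and end are disconnected.
.minimaxPath <- function(dF, occ, start, end) {
  nr <- nrow(dF)
  nc <- ncol(dF)
  nV <- nr * nc
  lin <- function(b) (b[2L] - 1L) * nr + b[1L]
  sL <- lin(start)
  eL <- lin(end)
  cost <- rep(Inf, nV)
  hops <- rep(Inf, nV)
  parent <- rep(NA_integer_, nV)
  visited <- rep(FALSE, nV)
  passable <- as.vector(occ)
  cost[sL] <- dF[start[1L], start[2L]]
  hops[sL] <- 0
  repeat {
    cand <- which(!visited & passable & is.finite(cost))
    if (!length(cand)) return(NULL)
    u <- cand[order(cost[cand], hops[cand], cand)][1L]
    if (u == eL) break
    visited[u] <- TRUE
    ui <- (u - 1L) %% nr + 1L
    uj <- (u - 1L) %/% nr + 1L
    for (di in -1:1) {
      for (dj in -1:1) {
        if (di == 0L && dj == 0L) next
        ni <- ui + di
        nj <- uj + dj
        if (ni < 1L || ni > nr || nj < 1L || nj > nc) next
        v <- (nj - 1L) * nr + ni
        if (!passable[v] || visited[v]) next
        newCost <- max(cost[u], dF[ni, nj])
        newHops <- hops[u] + 1
        if (newCost < cost[v] - 1e-15 ||
            (newCost <= cost[v] + 1e-15 && newHops < hops[v])) {
          cost[v] <- newCost
          hops[v] <- newHops
          parent[v] <- u
        }
      }
    }
  }
  path <- integer(0)
  v <- eL
  while (!is.na(v)) {
    path <- c(v, path)
    v <- parent[v]
    if (length(path) > nV) return(NULL)
  }
  cbind((path - 1L) %% nr + 1L, (path - 1L) %/% nr + 1L)
}

#' Extract the unfolding reaction coordinate
#'
#' Walks from the native modal bin toward the unfolded endpoint along the
#' discrete analogue of a perpendicular-to-the-contours coordinate: at each
#' step, among the 8-neighbours that make monotone progress toward the end
#' bin (strictly smaller Chebyshev distance), the one with the lowest deltaF
#' is taken (the steepest feasible direction). Empty bins are impassable.
#' On densely sampled grids this walk is the whole story; on sparsely
#' sampled ones monotone progress can be locally blocked by unsampled bins,
#' in which case the discrete minimum-free-energy route (the Dijkstra
#' minimax path over occupied bins, which the greedy walk approximates) is
#' used instead. Only genuinely disconnected endpoints raise an error,
#' naming the blocking region.
#'
#' @param grid a \linkS4class{LandscapeGrid} with deltaF filled.
#' @param startBin integer (row, col) of the start; default the modal bin
#'   (ties broken by lowest linear index).
#' @param endBin integer (row, col) of the end; default the occupied bin
#'   farthest (Euclidean grid distance) from the start within the start's
#'   connected component, ties broken by lowest linear index.
#' @return a \linkS4class{ReactionPath} (channel index unset until
#'   \code{\link{barrierStats}}).
#' @export
extractReactionPath <- function(grid, startBin = NULL, endBin = NULL) {
  stopifnot(is(grid, "LandscapeGrid"))
  if (!is.finite(grid@rt)) stop("apply freeEnergy() before path extraction")
  dF <- grid@deltaF
  nr <- nrow(dF)
  nc <- ncol(dF)
  occ <- which(grid@counts > 0, arr.ind = TRUE)
  if (is.null(startBin)) {
    lin <- which.max(grid@counts) # lowest linear index on ties
    startBin <- c((lin - 1L) %% nr + 1L, (lin - 1L) %/% nr + 1L)
  }
  startBin <- as.integer(startBin)
  if (any(startBin < 1L) || startBin[1L] > nr || startBin[2L] > nc ||
      grid@counts[startBin[1L], startBin[2L]] == 0L) {
    stop("start bin must be an occupied grid bin")
  }
  comp <- .componentOf(grid@counts > 0, startBin)
  if (is.null(endBin)) {
    occC <- which(comp, arr.ind = TRUE)
    d2 <- (occC[, 1L] - startBin[1L])^2 + (occC[, 2L] - startBin[2L])^2
    endBin <- as.integer(occC[which.max(d2), ])
  }
  endBin <- as.integer(endBin)
  if (any(endBin < 1L) || endBin[1L] > nr || endBin[2L] > nc ||
      grid@counts[endBin[1L], endBin[2L]] == 0L) {
    stop("end bin must be an occupied grid bin")
  }
  if (!comp[endBin[1L], endBin[2L]]) {
    stop(
      "start (", startBin[1L], ", ", startBin[2L], ") and end (",
      endBin[1L], ", ", endBin[2L], ") bins are disconnected: no route ",
      "through sampled bins exists; the unsampled region between the ",
      "start component (", sum(comp), " bins) and the end bin blocks ",
      "every path"
    )
  }
  path <- list(startBin)
  cur <- startBin
  while (!all(cur == endBin)) {
    curD <- .cheby(cur, endBin)
    best <- NULL
    bestF <- Inf
    bestLin <- Inf
    for (di in -1:1) {
      for (dj in -1:1) {
        if (di == 0L && dj == 0L) next
        nb <- cur + c(di, dj)
        if (nb[1L] < 1L || nb[1L] > nr || nb[2L] < 1L || nb[2L] > nc) next
        if (.cheby(nb, endBin) >= curD) next
        f <- dF[nb[1L], nb[2L]]
        if (is.na(f)) next
        linIdx <- (nb[2L] - 1L) * nr + nb[1L]
        if (f < bestF - 1e-12 ||
            (abs(f - bestF) <= 1e-12 && linIdx < bestLin)) {
          best <- nb
          bestF <- f
          bestLin <- linIdx
        }
      }
    }
    if (is.null(best)) {
      # monotone progress locally blocked by unsampled bins (typical of
      # sparsely sampled grids): fall back to the discrete minimum-free-
      # energy route, the Dijkstra minimax path over occupied bins, which
      # exists because start and end share a connected component
      path <- NULL
      break
    }
    path[[length(path) + 1L]] <- best
    cur <- best
  }
  bins <- if (is.null(path)) {
    .minimaxPath(dF, grid@counts > 0, startBin, endBin)
  } else {
    do.call(rbind, path)
  }
  profile <- dF[bins]
  mx <- grid@midpoints[[1L]][bins[, 1L]]
  my <- grid@midpoints[[2L]][bins[, 2L]]
  seg <- if (nrow(bins) > 1L) sqrt(diff(mx)^2 + diff(my)^2) else numeric(0)
  new("ReactionPath",
    binSequence = bins,
    arcLength = c(0, cumsum(seg)),
    profile = profile,
    deltaFActivation = max(profile) - profile[1L],
    channelIndex = NA_real_,
    intermediates = data.frame(),
    rt = grid@rt
  )
}

# nearest local maximum of p walking left/right from index i (plateau-aware)
.walkToMax <- function(p, i, dir) {
  n <- length(p)
  j <- i
  while (j + dir >= 1L && j + dir <= n && p[j + dir] >= p[j]) j <- j + dir
  p[j]
}

#' Barrier, channel-index and intermediate statistics of a reaction path
#'
#' Summarizes a free-energy profile: the activation free energy
#' (max(profile) - profile at start), the channel index — the fraction of
#' the path arc lying within RT of the barrier top, which separates a broad
#' flat "channel" barrier from a narrow peaked one — and post-barrier local
#' minima with their well depths. A minimum is a thermally stable
#' intermediate only if its depth exceeds the stability threshold (default
#' RT: a well much shallower than the thermal energy cannot confine the
#' chain). The path's final point is a boundary, never an intermediate.
#'
#' @param path a \linkS4class{ReactionPath}.
#' @param stabilityThreshold well depth (kcal/mol) above which a post-barrier
#'   minimum counts as a stable intermediate; default RT.
#' @return the path with \code{channelIndex} and \code{intermediates} filled.
#' @export
barrierStats <- function(path, stabilityThreshold = NULL) {
  stopifnot(is(path, "ReactionPath"))
  rt <- path@rt
  if (is.null(stabilityThreshold)) stabilityThreshold <- rt
  p <- path@profile
  n <- length(p)
  if (n == 1L) {
    path@channelIndex <- NA_real_
    path@intermediates <- data.frame(
      index = integer(0), arcLength = numeric(0), deltaF = numeric(0),
      depth = numeric(0), stable = logical(0)
    )
    return(path)
  }
  s <- path@arcLength
  # trapezoid arc attribution: each point owns half its adjacent segments
  w <- numeric(n)
  w[1L] <- (s[2L] - s[1L]) / 2
  w[n] <- (s[n] - s[n - 1L]) / 2
  if (n > 2L) w[2:(n - 1L)] <- (s[3:n] - s[1:(n - 2L)]) / 2
  top <- max(p)
  qualify <- p >= top - rt
  path@channelIndex <- sum(w[qualify]) / sum(w)
  ib <- which.max(p)
  mins <- integer(0)
  if (ib + 1L <= n - 1L) {
    for (i in seq.int(ib + 1L, n - 1L)) {
      if (p[i] <= p[i - 1L] && p[i] <= p[i + 1L] &&
          (p[i] < p[i - 1L] || p[i] < p[i + 1L])) {
        mins <- c(mins, i)
      }
    }
  }
  depth <- vapply(mins, function(i) {
    min(.walkToMax(p, i, -1L), .walkToMax(p, i, 1L)) - p[i]
  }, numeric(1L))
  path@intermediates <- data.frame(
    index = mins,
    arcLength = s[mins],
    deltaF = p[mins],
    depth = depth,
    stable = depth > stabilityThreshold
  )
  path
}

#' Transition-state-theory unfolding rate
#'
#' Evaluates k_u = prefactor * exp(-deltaF_activation / RT), the
#' protein-folding TST expression with the conventional 1e6 per-second
#' prefactor.
#'
#' @param deltaFActivation activation free energy, kcal/mol (>= 0).
#' @param temperature temperature in K.
#' @param prefactor attempt frequency in 1/s (default 1e6).
#' @return list with \code{ku} (1/s), \code{prefactor},
#'   \code{deltaFActivation}, \code{temperature} and \code{rt}.
#' @examples
#' tstRate(0, 498)$ku # the bare prefactor
#' @export
tstRate <- function(deltaFActivation, temperature, prefactor = 1e6) {
  if (!is.finite(deltaFActivation) || deltaFActivation < 0) {
    stop("deltaFActivation must be a non-negative number")
  }
  temperature <- .assertPositive(temperature, "temperature")
  prefactor <- .assertPositive(prefactor, "prefactor")
  rt <- .RGAS * temperature
  list(
    ku = prefactor * exp(-deltaFActivation / rt),
    prefactor = prefactor,
    deltaFActivation = deltaFActivation,
    temperature = temperature,
    rt = rt
  )
}
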