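#' @include AllClasses.R AllGenerics.R utils.R io.R
NULL

# Cα-only topology for an n-residue toy chain.
.toyTopology <- function(n) {
  new("Topology",
    atomNames = rep("CA", n),
    residueIndex = seq_len(n),
    residueNames = rep("ALA", n),
    masses = rep(12.011, n),
    calphaMask = rep(TRUE, n),
    sourceResno = seq_len(n),
    sourceChain = rep("A", n)
  )
}

#' Build a Cα-only toy native structure
#'
#' Constructs a deterministic model protein with one ideal alpha-helix
#' (rise 1.5 A, radius 2.3 A, 100 degrees per residue), a three-residue
#' linker, and a two-strand antiparallel hairpin (Cα spacing 3.8 A along
#' each strand, 4.8 A between strands) packed against the helix so that
#' helix-sheet tertiary contacts exist. All consecutive Cα-Cα distances lie
#' in the physical 3.5-4.0 A range. Segment indices are returned as
#' ground-truth labels for the analysis modules.
#'
#' @param nResidues chain length (>= 20).
#' @param seed kept for API symmetry with the other generators; the
#'   construction is fully deterministic.
#' @return list with \code{topology} (\linkS4class{Topology}), \code{coords}
#'   (n x 3 matrix, Angstrom) and \code{segments} (list of index vectors:
#'   helix, linker, strand1, turn, strand2).
#' @examples
#' toy <- makeToyNative(30)
#' range(sqrt(rowSums(diff(toy$coords)^2)))
#' @export
makeToyNative <- function(nResidues, seed = 1L) {
  n <- .assertCount(nResidues, "nResidues", min = 20L)
  helixLen <- max(6L, min(12L, n - 12L))
  linkerLen <- 3L
  turnLen <- 3L
  rem <- n - helixLen - linkerLen - turnLen
  s1 <- rem %/% 2L
  s2 <- rem - s1
  if (s1 < 3L) stop("nResidues too small for the helix-hairpin construction")

  coords <- matrix(NA_real_, n, 3L, dimnames = list(NULL, c("x", "y", "z")))
  # ideal helix along z
  i <- seq_len(helixLen)
  th <- (i - 1L) * 100 * pi / 180
  coords[i, ] <- cbind(2.3 * cos(th), 2.3 * sin(th), 1.5 * (i - 1L))
  helixEnd <- coords[helixLen, ]

  # strand 1 runs upward at (x, y) = (7, 0); its first residue placed so the
  # straight three-residue linker has uniform 3.8 A spacing
  span <- 3.8 * (linkerLen + 1L)
  rho2 <- (7 - helixEnd[1L])^2 + helixEnd[2L]^2
  zS <- helixEnd[3L] - sqrt(span^2 - rho2)
  s1Start <- c(7, 0, zS)
  for (k in seq_len(linkerLen)) {
    coords[helixLen + k, ] <- helixEnd + (k / (linkerLen + 1L)) *
      (s1Start - helixEnd)
  }
  s1Idx <- (helixLen + linkerLen + 1L):(helixLen + linkerLen + s1)
  coords[s1Idx, ] <- cbind(7, 0, zS + 3.8 * (seq_len(s1) - 1L))
  zTop <- zS + 3.8 * (s1 - 1L)

  # 270-degree turn arc in the z = zTop plane, bulging away from the helix;
  # radius chosen so the four 67.5-degree chords are 3.77 A
  R <- 4.8 / (2 * sin(135 * pi / 180))
  C <- c(7 + 4.8 / 2, 4.8 / 2, zTop)
  e1 <- c(-1, -1, 0) / sqrt(2)
  e2 <- c(1, -1, 0) / sqrt(2)
  tIdx <- (helixLen + linkerLen + s1 + 1L):(helixLen + linkerLen + s1 + turnLen)
  for (k in seq_len(turnLen)) {
    thk <- k * (270 / (turnLen + 1L)) * pi / 180
    coords[tIdx[k], ] <- C + R * (cos(thk) * e1 + sin(thk) * e2)
  }

  # strand 2 antiparallel, 4.8 A from strand 1
  s2Idx <- (n - s2 + 1L):n
  coords[s2Idx, ] <- cbind(7, 4.8, zTop - 3.8 * (seq_len(s2) - 1L))

  list(
    topology = .toyTopology(n),
    coords = coords,
    segments = list(
      helix = seq_len(helixLen),
      linker = (helixLen + 1L):(helixLen + linkerLen),
      strand1 = s1Idx,
      turn = tIdx,
      strand2 = s2Idx
    )
  )
}

# Unweighted Rg of a coordinate matrix (toy atoms have equal mass).
.rgPlain <- function(X) {
  ctr <- colMeans(X)
  sqrt(mean(rowSums(sweep(X, 2L, ctr)^2)))
}

# Rigid-unit expansion: translate the hairpin away from the helix until the
# target Rg ratio is met; the linker is restretched along the straight line
# between its anchors. Segment-internal geometry is untouched.
.expandNative <- function(coords, segments, factor) {
  hairpin <- c(segments$strand1, segments$turn, segments$strand2)
  helix <- segments$helix
  linker <- segments$linker
  u <- colMeans(coords[hairpin, , drop = FALSE]) -
    colMeans(coords[helix, , drop = FALSE])
  u <- u / sqrt(sum(u^2))
  rg0 <- .rgPlain(coords)
  build <- function(t, bow, w) {
    X <- coords
    X[hairpin, ] <- sweep(X[hairpin, , drop = FALSE], 2L, t * u, "+")
    a <- X[helix[length(helix)], ]
    b <- X[segments$strand1[1L], ]
    ab <- b - a
    for (k in seq_along(linker)) {
      frac <- k / (length(linker) + 1L)
      X[linker[k], ] <- a + frac * ab + bow * sin(pi * frac) * w
    }
    X
  }
  clearance <- function(X) {
    other <- setdiff(seq_len(nrow(X)), linker)
    dLink <- Inf
    for (k in linker) {
      nonNb <- setdiff(other, c(k - 1L, k + 1L))
      dLink <- min(dLink, sqrt(min(rowSums(
        sweep(X[nonNb, , drop = FALSE], 2L, X[k, ])^2
      ))))
    }
    dLink
  }
  solveT <- function(bow, w) {
    f <- function(t) .rgPlain(build(t, bow, w)) / rg0 - factor
    if (f(0) > 0) {
      stop("infeasible expansion: native already exceeds target Rg")
    }
    hi <- 10
    while (f(hi) < 0 && hi < 500) hi <- hi * 2
    stats::uniroot(f, c(0, hi), tol = 1e-10)$root
  }
  # a straight stretched linker can brush the strand it runs into almost
  # parallel; bow it along whichever perpendicular clears the structure
  # best, choosing the direction at a provisional shift and then re-solving
  t0 <- solveT(0, c(0, 0, 1))
  X0 <- build(t0, 0, c(0, 0, 1))
  ab <- X0[segments$strand1[1L], ] - X0[helix[length(helix)], ]
  ab <- ab / sqrt(sum(ab^2))
  seed <- if (abs(ab[3L]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  w1 <- seed - ab * sum(seed * ab)
  w1 <- w1 / sqrt(sum(w1^2))
  w2 <- c(
    ab[2L] * w1[3L] - ab[3L] * w1[2L],
    ab[3L] * w1[1L] - ab[1L] * w1[3L],
    ab[1L] * w1[2L] - ab[2L] * w1[1L]
  )
  cands <- list(
    list(bow = 0, w = c(0, 0, 1)),
    list(bow = 1.8, w = w1), list(bow = 1.8, w = -w1),
    list(bow = 1.8, w = w2), list(bow = 1.8, w = -w2)
  )
  scores <- vapply(cands, function(cd) {
    clearance(build(t0, cd$bow, cd$w))
  }, numeric(1L))
  pick <- cands[[which.max(scores)]]
  t <- solveT(pick$bow, pick$w)
  X <- build(t, pick$bow, pick$w)
  if (clearance(X) < 2.0 || min(stats::dist(X)) < 1.5) {
    stop("infeasible expansion: self-clash in expanded form")
  }
  list(coords = X, shift = t)
}

# Self-avoiding random coil with fixed step length, used as the disorder
# target of the unfolding schedule. Draws from the current RNG stream.
.randomCoil <- function(n, step = 3.8, minSep = 4.0, maxTry = 200L) {
  X <- matrix(NA_real_, n, 3L)
  X[1L, ] <- c(0, 0, 0)
  for (i in 2:n) {
    placed <- FALSE
    for (tr in seq_len(maxTry)) {
      v <- stats::rnorm(3L)
      v <- v / sqrt(sum(v^2)) * step
      cand <- X[i - 1L, ] + v
      prev <- X[seq_len(i - 2L), , drop = FALSE]
      if (i == 2L ||
          min(sqrt(rowSums(sweep(prev, 2L, cand)^2))) >= minSep) {
        X[i, ] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("could not grow a self-avoiding coil")
  }
  X
}

#' Define an unfolding scenario
#'
#' Parameter record for \code{\link{makeUnfoldingTrajectory}}: a three-phase
#' schedule (native cluster, expanded molten-globule plateau, progressive
#' disorder) with known ground truth. The defaults encode the phenomenology
#' the analysis modules are meant to recover: a tight native cluster, a
#' precipitous exit, a plateau expanded 14\% in Rg with secondary structure
#' intact, then monotonic loss of native contacts.
#'
#' @param exitFrame first frame of the plateau (the planted native exit).
#' @param plateauFrames number of molten-globule plateau frames.
#' @param totalFrames total trajectory length in frames.
#' @param expansionFactor target plateau Rg / native Rg (default 1.14).
#' @param finalDisorder coil-mixing fraction reached at the last frame, in
#'   [0, 1]; 0 freezes the plateau (no further unfolding).
#' @param noiseSd per-coordinate Gaussian positional noise, Angstrom.
#' @param frameInterval ns per saved frame.
#' @param seed integer seed.
#' @return a validated list of class \code{UnfoldingScenario}.
#' @export
unfoldingScenario <- function(exitFrame = 100L, plateauFrames = 250L,
                              totalFrames = 500L, expansionFactor = 1.14,
                              finalDisorder = 0.9, noiseSd = 0.15,
                              frameInterval = 0.01, seed = 1L) {
  exitFrame <- .assertCount(exitFrame, "exitFrame", min = 2L)
  plateauFrames <- .assertCount(plateauFrames, "plateauFrames")
  totalFrames <- .assertCount(totalFrames, "totalFrames")
  if (exitFrame + plateauFrames - 1L > totalFrames) {
    stop("exitFrame + plateauFrames - 1 must not exceed totalFrames")
  }
  if (!is.finite(expansionFactor) || expansionFactor <= 1) {
    stop("expansionFactor must exceed 1")
  }
  if (!is.finite(finalDisorder) || finalDisorder < 0 || finalDisorder > 1) {
    stop("finalDisorder must lie in [0, 1]")
  }
  structure(
    list(
      exitFrame = exitFrame, plateauFrames = plateauFrames,
      totalFrames = totalFrames, expansionFactor = expansionFactor,
      finalDisorder = finalDisorder,
      noiseSd = .assertPositive(noiseSd, "noiseSd"),
      frameInterval = .assertPositive(frameInterval, "frameInterval"),
      seed = as.integer(seed)
    ),
    class = "UnfoldingScenario"
  )
}

#' Generate a toy unfolding trajectory with known ground truth
#'
#' Three-phase synthetic unfolding of a \code{\link{makeToyNative}} model:
#' \enumerate{
#'   \item frames before \code{exitFrame}: native coordinates plus Gaussian
#'     noise (a tight native cluster in RMSD space);
#'   \item plateau frames: the hairpin rigidly translated away from the
#'     helix until Rg / Rg_native equals \code{expansionFactor} (segment
#'     geometry, hence secondary structure, preserved; tertiary packing
#'     lost) plus noise — an expanded molten globule;
#'   \item remaining frames: linear interpolation toward a self-avoiding
#'     random coil with mixing fraction ramping from finalDisorder / 3 to
#'     finalDisorder, so disorder sets in promptly after the plateau and
#'     native contacts decay monotonically in the mean.
#' }
#' Ground-truth labels (exit frame, plateau range, per-frame phase, the
#' rigid-shift magnitude) are stored in the trajectory metadata.
#'
#' @param native a \code{\link{makeToyNative}} result.
#' @param scenario an \code{\link{unfoldingScenario}}.
#' @return a \linkS4class{Trajectory}; \code{trajectoryMetadata(x)$groundTruth}
#'   holds the labels.
#' @export
makeUnfoldingTrajectory <- function(native, scenario) {
  stopifnot(inherits(scenario, "UnfoldingScenario"))
  n <- nrow(native$coords)
  exp <- .expandNative(native$coords, native$segments,
                       scenario$expansionFactor)
  nT <- scenario$totalFrames
  exitF <- scenario$exitFrame
  plateauEnd <- exitF + scenario$plateauFrames - 1L
  # realized plateau contact retention at the standard contact definition,
  # recorded as ground truth for the analysis modules
  nset <- nativeContacts(native$coords)
  dTS <- sqrt(rowSums((exp$coords[nset[, 1L], , drop = FALSE] -
                         exp$coords[nset[, 2L], , drop = FALSE])^2))
  qRetention <- sum(dTS <= 8) / nrow(nset)
  nPost <- nT - plateauEnd
  frames <- vector("list", nT)
  phase <- character(nT)
  .withSeed(scenario$seed, {
    coil <- .randomCoil(n)
    coil <- sweep(coil, 2L, colMeans(coil) - colMeans(exp$coords), "+")
    for (f in seq_len(nT)) {
      if (f < exitF) {
        base <- native$coords
        phase[f] <- "native"
      } else if (f <= plateauEnd) {
        base <- exp$coords
        phase[f] <- "molten_globule"
      } else {
        k <- f - plateauEnd
        lam <- if (scenario$finalDisorder == 0) 0 else {
          scenario$finalDisorder *
            (1 / 3 + (2 / 3) * (k - 1L) / max(nPost - 1L, 1L))
        }
        base <- (1 - lam) * exp$coords + lam * coil
        phase[f] <- if (lam == 0) "molten_globule" else "unfolded"
      }
      frames[[f]] <- base +
        matrix(stats::rnorm(3L * n, sd = scenario$noiseSd), n, 3L)
    }
  })
  .newTrajectory(
    native$topology, .stackFrames(frames), scenario$frameInterval,
    originLabel = "synthetic unfolding trajectory",
    metadata = list(groundTruth = list(
      exitFrame = exitF,
      plateauRange = c(exitF, plateauEnd),
      phase = phase,
      expansionFactor = scenario$expansionFactor,
      rigidShift = exp$shift,
      qRetention = qRetention,
      scenario = scenario
    ))
  )
}

#' Generate a stationary native-ensemble trajectory
#'
#' Native coordinates plus Gaussian noise for every frame — the control for
#' exit detection (no exit must be reported).
#'
#' @param native a \code{\link{makeToyNative}} result.
#' @param nFrames number of frames.
#' @param noiseSd,frameInterval,seed as in \code{\link{unfoldingScenario}}.
#' @return a \linkS4class{Trajectory}.
#' @export
makeNativeTrajectory <- function(native, nFrames, noiseSd = 0.15,
                                 frameInterval = 0.01, seed = 1L) {
  nFrames <- .assertCount(nFrames, "nFrames", min = 2L)
  n <- nrow(native$coords)
  frames <- .withSeed(seed, {
    lapply(seq_len(nFrames), function(f) {
      native$coords + matrix(stats::rnorm(3L * n, sd = noiseSd), n, 3L)
    })
  })
  .newTrajectory(
    native$topology, .stackFrames(frames), frameInterval,
    originLabel = "synthetic native ensemble",
    metadata = list(groundTruth = list(phase = rep("native", nFrames)))
  )
}

# Push every native-pair distance out of a band around the cutoff so that
# frame noise cannot flip contacts: pairs just inside the cutoff are pulled
# in, pairs just outside pushed out, preserving each pair's formed/broken
# status. Iterates because moving a residue can nudge its other pairs into
# the band; the final contact count must match the input's.
.enforceContactMargins <- function(base, nativeSet, cutoff, margin = 0.3,
                                   maxPass = 20L) {
  X <- base
  pairDist <- function(X) {
    sqrt(rowSums((X[nativeSet[, 1L], , drop = FALSE] -
                    X[nativeSet[, 2L], , drop = FALSE])^2))
  }
  formed0 <- pairDist(X) <= cutoff # each pair keeps its original status
  q0 <- sum(formed0)
  for (pass in seq_len(maxPass)) {
    d <- pairDist(X)
    inBand <- which(abs(d - cutoff) < margin |
                      (d <= cutoff) != formed0)
    if (!length(inBand)) break
    for (p in inBand) {
      i <- nativeSet[p, 1L]
      j <- nativeSet[p, 2L]
      v <- X[j, ] - X[i, ]
      dij <- sqrt(sum(v^2))
      target <- if (formed0[p]) cutoff - margin - 0.05 else {
        cutoff + margin + 0.05
      }
      if (abs(dij - target) < 1e-9) next
      X[j, ] <- X[i, ] + v / dij * target
    }
  }
  if (sum(pairDist(X) <= cutoff) != q0) {
    # margins could not be enforced without changing the contact count;
    # fall back to the unmodified frame (noise may then blur the means)
    return(base)
  }
  X
}

# Remove exactly k currently-formed native contacts from a base frame by
# relocating whole residues radially outward (each relocation removes that
# residue's formed native contacts), with a minimal single-pair displacement
# fallback for remainders. Errors when the requested shift is unreachable.
.breakContacts <- function(base, nativeSet, k, cutoff) {
  if (k == 0L) return(base)
  X <- base
  ctr <- colMeans(X)
  formedMask <- function(X) {
    d <- sqrt(rowSums((X[nativeSet[, 1L], , drop = FALSE] -
                         X[nativeSet[, 2L], , drop = FALSE])^2))
    d <= cutoff
  }
  q0 <- sum(formedMask(X))
  if (k > q0) stop("unachievable shift: only ", q0, " native contacts formed")
  remaining <- k
  movedRes <- integer(0)
  while (remaining > 0L) {
    formed <- formedMask(X)
    pairs <- nativeSet[formed, , drop = FALSE]
    deg <- tabulate(c(pairs), nbins = nrow(X))
    deg[movedRes] <- 0L
    cand <- which(deg >= 1L & deg <= remaining)
    if (length(cand)) {
      r <- cand[which.max(deg[cand])]
      v <- X[r, ] - ctr
      nv <- sqrt(sum(v^2))
      v <- if (nv > 1e-9) v / nv else c(1, 0, 0)
      # successive relocations go to distinct shells so relocated residues
      # cannot re-form native pairs with each other
      X[r, ] <- X[r, ] + (40 + 15 * length(movedRes)) * v
      movedRes <- c(movedRes, r)
      remaining <- remaining - deg[r]
    } else {
      # all remaining residues have too many contacts; peel off a single
      # pair by a minimal displacement that leaves the rest intact
      done <- FALSE
      for (pi in seq_len(nrow(pairs))) {
        for (which in 1:2) {
          r <- pairs[pi, which]
          o <- pairs[pi, 3L - which]
          if (r %in% movedRes) next
          dvec <- X[r, ] - X[o, ]
          dcur <- sqrt(sum(dvec^2))
          cand2 <- X
          cand2[r, ] <- X[o, ] + dvec / dcur * (cutoff + 0.5)
          if (sum(formedMask(cand2)) == sum(formedMask(X)) - 1L) {
            X <- cand2
            remaining <- remaining - 1L
            done <- TRUE
            break
          }
        }
        if (done) break
      }
      if (!done) stop("unachievable shift: no contact can be removed singly")
    }
  }
  if (sum(formedMask(X)) != q0 - k) {
    stop("unachievable shift: contact removal overshot the target")
  }
  X
}

#' Generate mutant/wild-type ensembles with prescribed contact shifts
#'
#' Builds, for each requested mutant, transition-state (TS) and folded (F)
#' frame ensembles whose mean native-contact counts are shifted by a
#' prescribed number of contacts relative to wild type — ground truth for
#' contact-ratio phi-values (phi = tsShift / fShift by construction). The
#' wild-type F ensemble is the native structure plus noise; the wild-type TS
#' ensemble is the expanded molten-globule conformation plus noise.
#' Contact removals are realized on the noise-free base frame (see
#' Details), so realized ensemble means sit within a fraction of a contact
#' of the request. Only non-positive shifts (contact losses) are supported;
#' a positive request errors as unachievable.
#'
#' @param native a \code{\link{makeToyNative}} result.
#' @param perturbations data.frame with columns \code{mutant} (id),
#'   \code{tsShift} and \code{fShift} (contacts, integers <= 0).
#' @param nFrames frames per ensemble (default 20).
#' @param noiseSd positional noise, Angstrom (default 0.05; 0 gives exact
#'   counts).
#' @param cutoff,minSeqSep contact definition (defaults 8 A, |i-j| >= 3).
#' @param expansionFactor Rg expansion of the TS base (default 1.14).
#' @param seed integer seed.
#' @return list with \code{wt} (list TS, F of \linkS4class{Trajectory}) and
#'   \code{mutants} (named list of lists TS, F, tsShift, fShift), plus the
#'   \code{nativeSet} used.
#' @export
makePhiEnsembles <- function(native, perturbations, nFrames = 20L,
                             noiseSd = 0.05, cutoff = 8, minSeqSep = 3L,
                             expansionFactor = 1.14, seed = 1L) {
  stopifnot(is.data.frame(perturbations),
            all(c("mutant", "tsShift", "fShift") %in% names(perturbations)))
  nFrames <- .assertCount(nFrames, "nFrames")
  if (any(perturbations$tsShift > 0) || any(perturbations$fShift > 0)) {
    stop("unachievable shift: only contact losses (shifts <= 0) are supported")
  }
  nset <- nativeContacts(native$coords, cutoff = cutoff,
                         minSeqSep = minSeqSep)
  tsBase <- .enforceContactMargins(
    .expandNative(native$coords, native$segments, expansionFactor)$coords,
    nset, cutoff
  )
  fBase <- .enforceContactMargins(native$coords, nset, cutoff)
  n <- nrow(fBase)
  mkTraj <- function(base, seedOff, label) {
    frames <- .withSeed(seed + seedOff, {
      lapply(seq_len(nFrames), function(f) {
        if (noiseSd > 0) {
          base + matrix(stats::rnorm(3L * n, sd = noiseSd), n, 3L)
        } else {
          base
        }
      })
    })
    .newTrajectory(native$topology, .stackFrames(frames), 0.1, label)
  }
  out <- list(
    wt = list(
      TS = mkTraj(tsBase, 0L, "wild-type TS ensemble"),
      F = mkTraj(fBase, 1L, "wild-type folded ensemble")
    ),
    mutants = list(),
    nativeSet = nset
  )
  for (r in seq_len(nrow(perturbations))) {
    id <- as.character(perturbations$mutant[r])
    kTS <- as.integer(-perturbations$tsShift[r])
    kF <- as.integer(-perturbations$fShift[r])
    out$mutants[[id]] <- list(
      TS = mkTraj(.breakContacts(tsBase, nset, kTS, cutoff), 2L * r,
                  paste("mutant", id, "TS ensemble")),
      F = mkTraj(.breakContacts(fBase, nset, kF, cutoff), 2L * r + 1L,
                 paste("mutant", id, "folded ensemble")),
      tsShift = -kTS,
      fShift = -kF
    )
  }
  out
}

#' @export
print.UnfoldingScenario <- function(x, ...) {
  cat(
    "UnfoldingScenario:", x$totalFrames, "frames; exit at", x$exitFrame,
    "; plateau", x$plateauFrames, "frames; Rg expansion",
    x$expansionFactor, "; final disorder", x$finalDisorder, "\n"
  )
  invisible(x)
}
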