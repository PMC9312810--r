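#' @include AllClasses.R AllGenerics.R utils.R
NULL

# Cα coordinates of one frame given a topology (or pass a matrix through,
# treating its rows as residues of a Cα-only model).
.calphaFrame <- function(x, topology = NULL) {
  X <- as.matrix(x)
  if (!is.null(topology)) X <- X[topology@calphaMask, , drop = FALSE]
  X
}

#' Native contact map
#'
#' Residue pairs (i < j) whose Cα atoms lie within the cutoff in the native
#' frame, at sequence separation |i - j| >= minSeqSep. The Cα scheme matches
#' the Cα-based remainder of the pipeline; both knobs are exposed.
#'
#' @param native an n x 3 Cα coordinate matrix (rows = residues), or a
#'   \code{\link{makeToyNative}}-style list with \code{coords}.
#' @param cutoff contact cutoff, Angstrom (default 8).
#' @param minSeqSep minimum sequence separation in residues (default 3).
#' @param topology optional \linkS4class{Topology} used to extract Cα rows
#'   when \code{native} carries more than Cα atoms.
#' @return integer m x 2 matrix of contacts, columns i, j with i < j.
#' @examples
#' chain <- cbind(3.8 * (0:9), 0, 0) # straight chain: no contacts at 8 A
#' nrow(nativeContacts(chain))
#' @export
nativeContacts <- function(native, cutoff = 8, minSeqSep = 3L,
                           topology = NULL) {
  if (is.list(native) && !is.null(native$coords)) native <- native$coords
  X <- .calphaFrame(native, topology)
  cutoff <- .assertPositive(cutoff, "cutoff")
  minSeqSep <- .assertCount(minSeqSep, "minSeqSep")
  n <- nrow(X)
  if (n < minSeqSep + 1L) stop("need at least minSeqSep + 1 residues")
  D <- as.matrix(stats::dist(X))
  pairs <- which(upper.tri(D) & D <= cutoff, arr.ind = TRUE)
  sep <- pairs[, 2L] - pairs[, 1L]
  pairs <- pairs[sep >= minSeqSep, , drop = FALSE]
  m <- matrix(as.integer(pairs), ncol = 2L,
              dimnames = list(NULL, c("i", "j")))
  m[order(m[, 1L], m[, 2L]), , drop = FALSE]
}

#' Native-contact, total-contact and Rg time series
#'
#' Per frame: Q, the number of native-set pairs currently within the cutoff;
#' the total number of contacts at the same definition; the native-contact
#' fraction Q / |native set|; and the radius of gyration. These are the
#' axes of the Pande-Rokhsar native-vs-total contact plane and the Rg trace.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param native native Cα coordinates (matrix or
#'   \code{\link{makeToyNative}} list).
#' @param nativeSet optional precomputed contact map; computed from
#'   \code{native} when NULL.
#' @param cutoff,minSeqSep contact definition (defaults 8 A, 3).
#' @return a \linkS4class{ContactSeries}.
#' @export
contactTimeseries <- function(traj, native, nativeSet = NULL, cutoff = 8,
                              minSeqSep = 3L) {
  stopifnot(is(traj, "Trajectory"))
  if (is.list(native) && !is.null(native$coords)) native <- native$coords
  topo <- topology(traj)
  natCa <- .calphaFrame(native, if (nrow(as.matrix(native)) ==
                                    nAtoms(traj)) topo else NULL)
  if (is.null(nativeSet)) {
    nativeSet <- nativeContacts(natCa, cutoff = cutoff,
                                minSeqSep = minSeqSep)
  }
  nT <- nFrames(traj)
  q <- integer(nT)
  total <- integer(nT)
  rg <- numeric(nT)
  masses <- topo@masses[topo@calphaMask]
  for (f in seq_len(nT)) {
    Xf <- coords(traj, frame = f)[topo@calphaMask, , drop = FALSE]
    D <- as.matrix(stats::dist(Xf))
    dNative <- D[nativeSet]
    q[f] <- sum(dNative <= cutoff)
    sepOk <- outer(seq_len(nrow(Xf)), seq_len(nrow(Xf)),
                   function(a, b) b - a >= minSeqSep)
    total[f] <- sum(D[sepOk] <= cutoff)
    rg[f] <- radiusOfGyration(Xf, masses = masses)
  }
  new("ContactSeries",
    nativeSet = nativeSet,
    q = q, total = total,
    qFraction = if (nrow(nativeSet) > 0) q / nrow(nativeSet) else
      rep(0, nT),
    rg = rg,
    rgNative = radiusOfGyration(natCa, masses = masses),
    definition = list(cutoff = cutoff, minSeqSep = minSeqSep)
  )
}

#' Radius of gyration
#'
#' Mass-weighted RMS distance of the selected atoms from their mass-weighted
#' centroid: Rg = sqrt(sum m_i |r_i - rbar|^2 / sum m_i).
#'
#' @param frame an atoms x 3 coordinate matrix.
#' @param mask optional atom selection.
#' @param masses optional masses (default equal weights).
#' @return Rg in Angstrom.
#' @examples
#' radiusOfGyration(rbind(c(0, 0, 0), c(2, 0, 0))) # 1
#' @export
radiusOfGyration <- function(frame, mask = NULL, masses = NULL) {
  X <- as.matrix(frame)
  if (!is.null(mask)) X <- X[mask, , drop = FALSE]
  n <- nrow(X)
  if (n < 1L) stop("need at least one selected atom")
  if (is.null(masses)) masses <- rep(1, n)
  if (length(masses) != n) {
    if (!is.null(mask)) masses <- masses[mask]
    if (length(masses) != n) stop("masses must match the selection")
  }
  ctr <- colSums(X * masses) / sum(masses)
  sqrt(sum(masses * rowSums(sweep(X, 2L, ctr)^2)) / sum(masses))
}

#' Cα-geometry secondary-structure assignment
#'
#' Assigns one of H (helix), E (extended strand) or C (coil) to every
#' residue of a Cα trace, using pseudo-geometry only (the toy models carry
#' no backbone N/O, so no hydrogen bonds are available):
#' \itemize{
#'   \item helix: residue windows where d(i, i+3) lies in [4.8, 5.6] A and
#'     d(i, i+4) in [5.8, 6.6] A (the Cα signature of an ideal alpha
#'     helix); every residue covered by such a 5-residue window is H.
#'   \item strand: residues whose local trace is extended
#'     (d(i-1, i+1) >= 6.4 A) \emph{and} which have a non-local partner
#'     (|i - j| >= 4) within 5.5 A, in runs of at least 3 consecutive such
#'     residues, are E. An isolated extended stretch with no partner strand
#'     stays C.
#'   \item everything else, including terminal residues that cannot satisfy
#'     the window rules, is C. H takes precedence over E.
#' }
#'
#' @param frame an n x 3 Cα coordinate matrix.
#' @param helix3,helix4 the d(i, i+3) and d(i, i+4) helix windows.
#' @param extendMin minimum d(i-1, i+1) for an extended residue.
#' @param pairMax maximum Cα distance to a partner strand residue.
#' @param pairMinSep minimum sequence separation of a strand partner.
#' @return character vector of per-residue labels in {H, E, C}.
#' @export
assignSecondaryStructure <- function(frame, helix3 = c(4.8, 5.6),
                                     helix4 = c(5.8, 6.6),
                                     extendMin = 6.4, pairMax = 5.5,
                                     pairMinSep = 4L) {
  X <- as.matrix(frame)
  n <- nrow(X)
  if (n < 5L) stop("need at least 5 residues")
  D <- as.matrix(stats::dist(X))
  labels <- rep("C", n)

  # helix windows
  hWin <- rep(FALSE, n)
  for (i in seq_len(n - 4L)) {
    if (D[i, i + 3L] >= helix3[1L] && D[i, i + 3L] <= helix3[2L] &&
        D[i, i + 4L] >= helix4[1L] && D[i, i + 4L] <= helix4[2L]) {
      hWin[i] <- TRUE
    }
  }
  for (i in which(hWin)) labels[i:(i + 4L)] <- "H"

  # strand candidates: locally extended and non-locally paired
  extended <- rep(FALSE, n)
  for (i in 2:(n - 1L)) extended[i] <- D[i - 1L, i + 1L] >= extendMin
  paired <- rep(FALSE, n)
  for (i in seq_len(n)) {
    js <- which(abs(seq_len(n) - i) >= pairMinSep & D[i, ] <= pairMax)
    paired[i] <- length(js) > 0L
  }
  eligible <- extended & paired & labels != "H"
  r <- rle(eligible)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (b in which(r$values & r$lengths >= 3L)) {
    labels[starts[b]:ends[b]] <- "E"
  }
  labels
}

#' Secondary-structure timeline of a trajectory
#'
#' Applies \code{\link{assignSecondaryStructure}} to every frame and scores
#' persistence of the native labels. Frame-level persistence is computed
#' over the natively structured residues only (native label H or E):
#' natively-coil residues would otherwise keep "matching" C even in fully
#' unfolded frames and put a floor under the score.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param native native Cα coordinates (matrix or
#'   \code{\link{makeToyNative}} list).
#' @param ... window parameters passed to
#'   \code{\link{assignSecondaryStructure}}.
#' @return a \linkS4class{SecondaryStructureTimeline}.
#' @export
secondaryStructureTimeline <- function(traj, native, ...) {
  stopifnot(is(traj, "Trajectory"))
  if (is.list(native) && !is.null(native$coords)) native <- native$coords
  topo <- topology(traj)
  natCa <- .calphaFrame(native, if (nrow(as.matrix(native)) ==
                                    nAtoms(traj)) topo else NULL)
  nativeLabels <- assignSecondaryStructure(natCa, ...)
  nT <- nFrames(traj)
  labels <- matrix("C", nT, length(nativeLabels))
  for (f in seq_len(nT)) {
    Xf <- coords(traj, frame = f)[topo@calphaMask, , drop = FALSE]
    labels[f, ] <- assignSecondaryStructure(Xf, ...)
  }
  structured <- nativeLabels != "C"
  perFrame <- if (any(structured)) {
    rowMeans(labels[, structured, drop = FALSE] ==
               matrix(nativeLabels[structured], nT, sum(structured),
                      byrow = TRUE))
  } else {
    rep(NA_real_, nT)
  }
  new("SecondaryStructureTimeline",
    labels = labels,
    nativeLabels = nativeLabels,
    persistenceByResidue = colMeans(
      labels == matrix(nativeLabels, nT, length(nativeLabels), byrow = TRUE)
    ),
    persistenceByFrame = perFrame
  )
}

#' Classify frames as native, molten globule or unfolded
#'
#' Frame classification in the spirit of the native-vs-total contact plane:
#' a frame is \emph{native} when its native-contact fraction is high
#' (>= qHi) and it is not expanded (Rg / Rg_native < expansionMin); it is a
#' \emph{molten globule} when native-like secondary structure persists
#' (frame persistence >= qLo) while the chain is expanded
#' (Rg ratio >= expansionMin) yet retains a floor of native contacts
#' (>= qFloor) — native-like secondary structure without native packing;
#' anything else is \emph{unfolded}.
#'
#' @param series a \linkS4class{ContactSeries}.
#' @param ss the aligned \linkS4class{SecondaryStructureTimeline}.
#' @param qLo minimum frame-level secondary-structure persistence for a
#'   molten globule (default 0.6).
#' @param expansionMin minimum Rg ratio counting as expanded (default 1.05).
#' @param qFloor minimum native-contact fraction of a molten globule
#'   (default 0.3).
#' @param qHi minimum native-contact fraction of a native frame
#'   (default 0.8).
#' @return factor with levels native, molten_globule, unfolded.
#' @export
classifyMoltenGlobule <- function(series, ss, qLo = 0.6,
                                  expansionMin = 1.05, qFloor = 0.3,
                                  qHi = 0.8) {
  stopifnot(is(series, "ContactSeries"),
            is(ss, "SecondaryStructureTimeline"))
  if (nFrames(series) != nrow(ss@labels)) {
    stop("contact series and secondary-structure timeline must be aligned")
  }
  for (v in c(qLo = qLo, qFloor = qFloor, qHi = qHi)) {
    if (!is.finite(v) || v < 0 || v > 1) {
      stop("classification thresholds must lie in [0, 1]")
    }
  }
  ratio <- series@rg / series@rgNative
  pers <- ss@persistenceByFrame
  cls <- ifelse(
    series@qFraction >= qHi & ratio < expansionMin, "native",
    ifelse(
      pers >= qLo & ratio >= expansionMin & series@qFraction >= qFloor,
      "molten_globule", "unfolded"
    )
  )
  factor(cls, levels = c("native", "molten_globule", "unfolded"))
}

#' Demarcate the transition-state ensemble
#'
#' The transition region starts at the native exit and ends at the upper
#' bound of the molten-globule region: the end of the last contiguous
#' molten-globule run that starts within \code{gapTolerance} frames of the
#' exit, where runs separated by at most \code{gapTolerance} non-MG frames
#' are merged (frame-level classification flickers; the demarcation should
#' not).
#'
#' @param exit a \linkS4class{NativeExit} with a detected exit frame.
#' @param classes per-frame factor from \code{\link{classifyMoltenGlobule}}.
#' @param gapTolerance merge gap G in frames (default 10).
#' @return a \linkS4class{TransitionEnsemble}; empty (with a warning) when
#'   no molten-globule frame follows the exit.
#' @export
demarcateTransition <- function(exit, classes, gapTolerance = 10L) {
  stopifnot(is(exit, "NativeExit"))
  gapTolerance <- .assertCount(gapTolerance, "gapTolerance", min = 0L)
  ef <- exit@exitFrame
  if (is.na(ef)) stop("no native exit was detected")
  nT <- length(classes)
  if (ef >= nT) stop("exit frame must precede the trajectory end")
  isMG <- as.character(classes) == "molten_globule"
  crit <- list(gapTolerance = gapTolerance)
  mgAfter <- which(isMG & seq_len(nT) >= ef)
  if (length(mgAfter) == 0L) {
    warning("no molten-globule frames after the exit; empty ensemble")
    return(new("TransitionEnsemble",
      frameRange = c(ef, ef), memberFrames = integer(0), criteria = crit
    ))
  }
  # contiguous MG runs, merged across gaps <= G
  r <- rle(isMG)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  merged <- runs[1L, , drop = FALSE]
  if (nrow(runs) > 1L) {
    for (k in 2:nrow(runs)) {
      if (runs[k, 1L] - merged[nrow(merged), 2L] - 1L <= gapTolerance) {
        merged[nrow(merged), 2L] <- runs[k, 2L]
      } else {
        merged <- rbind(merged, runs[k, ])
      }
    }
  }
  anchored <- merged[merged[, 1L] <= ef + gapTolerance &
                       merged[, 2L] >= ef, , drop = FALSE]
  if (nrow(anchored) == 0L) {
    warning("no molten-globule run anchored at the exit; empty ensemble")
    return(new("TransitionEnsemble",
      frameRange = c(ef, ef), memberFrames = integer(0), criteria = crit
    ))
  }
  upper <- anchored[nrow(anchored), 2L]
  members <- which(isMG)
  members <- members[members >= ef & members <= upper]
  new("TransitionEnsemble",
    frameRange = c(ef, as.integer(upper)),
    memberFrames = as.integer(members),
    criteria = crit
  )
}
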