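#' @import methods
NULL

#' Topology of a molecular system
#'
#' Atom-level description of the molecule a trajectory refers to: atom names,
#' the (1-based, internal) residue index of every atom, residue names, masses
#' and a C-alpha mask. Internal indices are contiguous along the chain;
#' user-facing reports use the source PDB numbering kept in
#' \code{sourceResno}/\code{sourceChain}.
#'
#' @slot atomNames character, one PDB atom name per atom.
#' @slot residueIndex integer, internal (1-based) residue index per atom,
#'   non-decreasing along the atom list.
#' @slot residueNames character, residue name per atom.
#' @slot masses numeric, atomic masses in amu, all positive.
#' @slot calphaMask logical, selects exactly one CA atom per residue that has
#'   one, and no atom otherwise.
#' @slot sourceResno integer, residue number in the source PDB per atom.
#' @slot sourceChain character, chain identifier in the source PDB per atom.
#'
#' @exportClass Topology
setClass("Topology", representation(
  atomNames = "character",
  residueIndex = "integer",
  residueNames = "character",
  masses = "numeric",
  calphaMask = "logical",
  sourceResno = "integer",
  sourceChain = "character"
))

setValidity("Topology", function(object) {
  n <- length(object@atomNames)
  lens <- c(
    length(object@residueIndex), length(object@residueNames),
    length(object@masses), length(object@calphaMask),
    length(object@sourceResno), length(object@sourceChain)
  )
  if (any(lens != n)) {
    return("all per-atom slots must have the same length")
  }
  if (n == 0L) {
    return("topology must contain at least one atom")
  }
  if (any(diff(object@residueIndex) < 0L)) {
    return("residue indices must be non-decreasing along the atom list")
  }
  if (any(!is.finite(object@masses)) || any(object@masses <= 0)) {
    return("all masses must be positive")
  }
  ca <- object@residueIndex[object@calphaMask]
  if (anyDuplicated(ca)) {
    return("calphaMask must select at most one atom per residue")
  }
  if (!all(object@atomNames[object@calphaMask] == "CA")) {
    return("calphaMask must select only CA atoms")
  }
  TRUE
})

#' Coordinate trajectory
#'
#' Ordered frames of atomic coordinates (Angstrom) over a fixed
#' \linkS4class{Topology}, saved every \code{frameInterval} ns.
#'
#' @slot topology a \linkS4class{Topology}.
#' @slot coords numeric array, frames x atoms x 3, Angstrom, all finite.
#' @slot frameInterval single positive numeric, ns between saved frames.
#' @slot originLabel character scalar naming the source file or generator.
#' @slot metadata list of free-form annotations (synthetic generators record
#'   their ground-truth labels here).
#'
#' @exportClass Trajectory
setClass("Trajectory", representation(
  topology = "Topology",
  coords = "array",
  frameInterval = "numeric",
  originLabel = "character",
  metadata = "list"
))

setValidity("Trajectory", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L || d[3] != 3L) {
    return("coords must be a frames x atoms x 3 array")
  }
  if (d[2] != length(object@topology@atomNames)) {
    return("every frame must have the same atom count as the topology")
  }
  if (d[1] < 1L) {
    return("trajectory must contain at least one frame")
  }
  if (any(!is.finite(object@coords))) {
    return("coordinates must be finite")
  }
  if (length(object@frameInterval) != 1L || !is.finite(object@frameInterval) ||
      object@frameInterval <= 0) {
    return("frameInterval must be a single positive number")
  }
  TRUE
})

#' Pairwise C-alpha RMSD matrix (2DRMSD)
#'
#' Symmetric matrix of optimal-superposition C-alpha RMSD values (Angstrom)
#' between all retained frame pairs of a trajectory.
#'
#' @slot values numeric T x T matrix; symmetric, zero diagonal, non-negative.
#' @slot frameIndices integer, original frame index of each row/column.
#' @slot strideUsed integer, stride applied when subsampling frames.
#'
#' @exportClass DistanceMatrix
setClass("DistanceMatrix", representation(
  values = "matrix",
  frameIndices = "integer",
  strideUsed = "integer"
))

setValidity("DistanceMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("values must be square")
  if (nrow(v) != length(object@frameIndices)) {
    return("frameIndices must match matrix dimension")
  }
  if (any(v < -1e-12)) return("RMSD values must be non-negative")
  if (max(abs(diag(v))) > 1e-9) return("diagonal must be zero")
  if (max(abs(v - t(v))) > 1e-9) return("values must be symmetric")
  TRUE
})

#' Classical-MDS embedding of a distance matrix
#'
#' Low-dimensional RMSD-space coordinates obtained by Torgerson double
#' centering and eigendecomposition. Coordinates are centered; eigenvalues
#' are the retained (positive) ones in non-increasing order.
#'
#' @slot coords numeric T x k matrix of embedded coordinates (Angstrom).
#' @slot eigenvalues numeric, retained eigenvalues, non-increasing.
#' @slot explainedFraction fraction of the positive eigenvalue mass retained.
#' @slot negativeFraction |negative eigenvalue mass| / total absolute mass,
#'   a diagnostic of how non-Euclidean the input matrix was.
#' @slot k integer, number of retained axes.
#'
#' @exportClass RmsdEmbedding
setClass("RmsdEmbedding", representation(
  coords = "matrix",
  eigenvalues = "numeric",
  explainedFraction = "numeric",
  negativeFraction = "numeric",
  k = "integer"
))

setValidity("RmsdEmbedding", function(object) {
  if (ncol(object@coords) != object@k) return("coords must have k columns")
  if (length(object@eigenvalues) != object@k) {
    return("eigenvalues must have length k")
  }
  if (object@k > 1L && any(diff(object@eigenvalues) > 1e-9)) {
    return("eigenvalues must be non-increasing")
  }
  if (nrow(object@coords) > 0L && object@k > 0L &&
      max(abs(colMeans(object@coords))) > 1e-6) {
    return("embedded coordinates must be column-centered")
  }
  ef <- object@explainedFraction
  if (!is.finite(ef) || ef < -1e-9 || ef > 1 + 1e-9) {
    return("explainedFraction must lie in [0, 1]")
  }
  TRUE
})

#' MD step-vector series
#'
#' Displacements between consecutive embedded frames ("MD step vectors");
#' the embedded points themselves are the step-vector terminals.
#'
#' @slot displacements numeric (T-1) x k matrix of consecutive differences.
#' @slot norms numeric, Euclidean length of each displacement.
#' @slot terminals numeric T x k matrix, the embedded frame positions.
#' @slot frameInterval single positive numeric, ns between frames.
#'
#' @exportClass StepVectorSeries
setClass("StepVectorSeries", representation(
  displacements = "matrix",
  norms = "numeric",
  terminals = "matrix",
  frameInterval = "numeric"
))

setValidity("StepVectorSeries", function(object) {
  t <- nrow(object@terminals)
  if (nrow(object@displacements) != t - 1L) {
    return("displacements must have T - 1 rows")
  }
  if (length(object@norms) != t - 1L) return("norms must have length T - 1")
  recon <- object@terminals[-1L, , drop = FALSE] -
    object@terminals[-t, , drop = FALSE]
  if (max(abs(recon - object@displacements)) > 1e-9) {
    return("terminals[i+1] - terminals[i] must equal displacements[i]")
  }
  if (max(abs(sqrt(rowSums(object@displacements^2)) - object@norms)) > 1e-9) {
    return("norms must equal the Euclidean displacement lengths")
  }
  TRUE
})

#' Native-exit report
#'
#' First departure from the native-state cluster detected on a step-vector
#' series by a leader-style jump rule. \code{exitFrame} is \code{NA} when no
#' exit was found.
#'
#' @slot exitFrame integer frame index of the first exit (NA if none).
#' @slot exitTime exit time in ns ((exitFrame - 1) * frameInterval).
#' @slot threshold step-norm threshold used (mean + c * SD of the reference
#'   window norms).
#' @slot referenceWindow integer range (first, last) of the reference window.
#' @slot persistence integer, frames the exit must stay outside the cluster.
#' @slot clusterRadius radius of the native cluster around its centroid.
#'
#' @exportClass NativeExit
setClass("NativeExit", representation(
  exitFrame = "integer",
  exitTime = "numeric",
  threshold = "numeric",
  referenceWindow = "integer",
  persistence = "integer",
  clusterRadius = "numeric"
))

setValidity("NativeExit", function(object) {
  if (length(object@threshold) != 1L || !is.finite(object@threshold) ||
      object@threshold <= 0) {
    return("threshold must be a single positive number")
  }
  if (length(object@referenceWindow) != 2L) {
    return("referenceWindow must be (first, last)")
  }
  TRUE
})

#' Statistical free-energy landscape grid
#'
#' 2D histogram of step-vector terminals with, once \code{\link{freeEnergy}}
#' has been applied, the statistical free energy
#' deltaF = -RT log(P / P0) per occupied bin (kcal/mol). Empty bins carry
#' \code{NA}, treated as infinitely high by path extraction.
#'
#' @slot counts integer matrix of bin occupancies.
#' @slot breaks list of two numeric break vectors (x, y), Angstrom.
#' @slot midpoints list of two numeric bin-center vectors.
#' @slot deltaF numeric matrix of free energies (all NA before freeEnergy).
#' @slot rt RT in kcal/mol (NA before freeEnergy).
#' @slot temperature analysis temperature in K (NA before freeEnergy).
#' @slot nPoints number of points binned.
#' @slot axes the two embedding axes the grid was built on.
#'
#' @exportClass LandscapeGrid
setClass("LandscapeGrid", representation(
  counts = "matrix",
  breaks = "list",
  midpoints = "list",
  deltaF = "matrix",
  rt = "numeric",
  temperature = "numeric",
  nPoints = "numeric",
  axes = "integer"
))

setValidity("LandscapeGrid", function(object) {
  if (sum(object@counts) != object@nPoints) {
    return("grid counts must sum to the number of binned points")
  }
  if (any(object@counts < 0)) return("counts must be non-negative")
  if (!identical(dim(object@counts), dim(object@deltaF))) {
    return("deltaF must have the same shape as counts")
  }
  if (is.finite(object@rt)) {
    occ <- object@counts > 0
    if (any(is.na(object@deltaF[occ]))) {
      return("occupied bins must carry a finite deltaF")
    }
    if (abs(min(object@deltaF[occ])) > 1e-9) {
      return("the modal bin must have deltaF = 0")
    }
  }
  TRUE
})

#' Unfolding reaction path
#'
#' Ordered bin sequence from the native modal bin toward the unfolded region,
#' with the 1D free-energy profile along it and barrier statistics.
#'
#' @slot binSequence integer n x 2 matrix of (row, col) bin indices;
#'   consecutive bins are grid neighbours.
#' @slot arcLength numeric, cumulative Euclidean arc length (Angstrom),
#'   strictly increasing.
#' @slot profile numeric, deltaF at each path bin (kcal/mol).
#' @slot deltaFActivation max(profile) - profile[1], kcal/mol.
#' @slot channelIndex fraction of the path arc within RT of the barrier top
#'   (NA until \code{\link{barrierStats}} is applied, or for one-bin paths).
#' @slot intermediates data.frame of post-barrier local minima (index,
#'   arcLength, deltaF, depth, stable).
#' @slot rt RT (kcal/mol) inherited from the grid.
#'
#' @exportClass ReactionPath
setClass("ReactionPath", representation(
  binSequence = "matrix",
  arcLength = "numeric",
  profile = "numeric",
  deltaFActivation = "numeric",
  channelIndex = "numeric",
  intermediates = "data.frame",
  rt = "numeric"
))

setValidity("ReactionPath", function(object) {
  n <- nrow(object@binSequence)
  if (length(object@profile) != n || length(object@arcLength) != n) {
    return("profile and arcLength must match the bin sequence length")
  }
  if (n > 1L) {
    steps <- abs(diff(object@binSequence))
    if (any(steps > 1L) || any(rowSums(steps) == 0L)) {
      return("consecutive bins must be distinct grid neighbours")
    }
    if (any(diff(object@arcLength) <= 0)) {
      return("arc length must be strictly increasing")
    }
  }
  target <- max(object@profile) - object@profile[1L]
  if (abs(object@deltaFActivation - target) > 1e-9) {
    return("deltaFActivation must equal max(profile) - profile[1]")
  }
  TRUE
})

#' Native-contact and compactness time series
#'
#' Per-frame native-contact count Q, total contact count, native-contact
#' fraction and radius of gyration for a trajectory, relative to a native
#' reference frame (the Pande-Rokhsar plane inputs).
#'
#' @slot nativeSet integer m x 2 matrix of native residue pairs (i < j).
#' @slot q integer, native contacts present per frame.
#' @slot total integer, all contacts per frame at the same definition.
#' @slot qFraction numeric, q / nrow(nativeSet).
#' @slot rg numeric, radius of gyration per frame (Angstrom).
#' @slot rgNative radius of gyration of the native frame.
#' @slot definition list(cutoff, minSeqSep) used.
#'
#' @exportClass ContactSeries
setClass("ContactSeries", representation(
  nativeSet = "matrix",
  q = "integer",
  total = "integer",
  qFraction = "numeric",
  rg = "numeric",
  rgNative = "numeric",
  definition = "list"
))

setValidity("ContactSeries", function(object) {
  t <- length(object@q)
  if (length(object@total) != t || length(object@qFraction) != t ||
      length(object@rg) != t) {
    return("per-frame slots must have equal length")
  }
  if (any(object@q > object@total)) {
    return("native contacts cannot exceed total contacts")
  }
  if (nrow(object@nativeSet) > 0L && any(object@q > nrow(object@nativeSet))) {
    return("q cannot exceed the native-set size")
  }
  if (any(object@qFraction < -1e-9 | object@qFraction > 1 + 1e-9)) {
    return("qFraction must lie in [0, 1]")
  }
  TRUE
})

#' Transition-state ensemble demarcation
#'
#' The frame set between the native exit and the upper bound of the
#' molten-globule region.
#'
#' @slot frameRange integer (first, last); first is the native-exit frame.
#' @slot memberFrames integer, molten-globule frames inside the range.
#' @slot criteria list of the thresholds used.
#'
#' @exportClass TransitionEnsemble
setClass("TransitionEnsemble", representation(
  frameRange = "integer",
  memberFrames = "integer",
  criteria = "list"
))

setValidity("TransitionEnsemble", function(object) {
  if (length(object@frameRange) != 2L) return("frameRange must be (first, last)")
  if (object@frameRange[2L] < object@frameRange[1L]) {
    return("last frame must not precede first frame")
  }
  m <- object@memberFrames
  if (length(m) && (any(m < object@frameRange[1L]) ||
                    any(m > object@frameRange[2L]))) {
    return("all member frames must lie within the frame range")
  }
  TRUE
})

#' Secondary-structure timeline
#'
#' Per-frame, per-residue labels in {H, E, C} assigned from C-alpha geometry,
#' with persistence of the native labels.
#'
#' @slot labels character frames x residues matrix with entries H, E or C.
#' @slot nativeLabels character, label of each residue in the native frame.
#' @slot persistenceByResidue fraction of frames each residue keeps its
#'   native label.
#' @slot persistenceByFrame per-frame fraction of natively structured
#'   residues (native label H or E) that keep their native label.
#'
#' @exportClass SecondaryStructureTimeline
setClass("SecondaryStructureTimeline", representation(
  labels = "matrix",
  nativeLabels = "character",
  persistenceByResidue = "numeric",
  persistenceByFrame = "numeric"
))

setValidity("SecondaryStructureTimeline", function(object) {
  if (ncol(object@labels) != length(object@nativeLabels)) {
    return("labels must have one column per residue")
  }
  if (!all(object@labels %in% c("H", "E", "C"))) {
    return("labels must be H, E or C")
  }
  if (length(object@persistenceByFrame) != nrow(object@labels)) {
    return("persistenceByFrame must have one value per frame")
  }
  TRUE
})

#' Analytic potential-energy surface
#'
#' Closed-form 2D free-energy surface used as ground truth by the Brownian
#' sampler: an isotropic harmonic well, a quartic double well
#' V(x, y) = h ((x/a)^2 - 1)^2 + kappa y^2 / 2 (+ tilt * x), or a "channel"
#' variant whose barrier top is replaced by a flat plateau of length L at
#' V = h.
#'
#' @slot kind one of "harmonic", "double_well", "channel".
#' @slot parameters named list of the surface parameters (kappa, h, a, L,
#'   tilt as applicable; kcal/mol and Angstrom units).
#' @slot analyticBarrier closed-form activation free energy implied by the
#'   parameters (kcal/mol; 0 for the harmonic well, h for the others at
#'   tilt = 0).
#'
#' @exportClass PotentialSpec
setClass("PotentialSpec", representation(
  kind = "character",
  parameters = "list",
  analyticBarrier = "numeric"
))

setValidity("PotentialSpec", function(object) {
  if (!object@kind %in% c("harmonic", "double_well", "channel")) {
    return("kind must be harmonic, double_well or channel")
  }
  p <- object@parameters
  scalePars <- intersect(names(p), c("kappa", "h", "a", "L"))
  vals <- unlist(p[scalePars])
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    return("all scale parameters must be positive")
  }
  TRUE
})
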