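#' @include AllClasses.R AllGenerics.R
NULL

## ---- Topology -------------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("nAtoms", "Topology", function(x) length(x@atomNames))

#' @rdname accessors
#' @export
setMethod("nResidues", "Topology", function(x) length(unique(x@residueIndex)))

#' @rdname accessors
#' @export
setMethod("calphaMask", "Topology", function(x) x@calphaMask)

setMethod("show", "Topology", function(object) {
  cat(
    "Topology:", nAtoms(object), "atoms,", nResidues(object), "residues,",
    sum(object@calphaMask), "C-alpha\n"
  )
})

## ---- Trajectory -----------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("topology", "Trajectory", function(x) x@topology)

#' @rdname accessors
#' @param frame optional single frame index; if given, the atoms x 3
#'   coordinate matrix of that frame is returned instead of the full array.
#' @export
setMethod("coords", "Trajectory", function(x, frame = NULL) {
  if (is.null(frame)) {
    return(x@coords)
  }
  frame <- .assertCount(frame, "frame")
  if (frame > dim(x@coords)[1L]) {
    stop("frame ", frame, " out of range (", dim(x@coords)[1L], " frames)")
  }
  matrix(x@coords[frame, , ], ncol = 3L,
         dimnames = list(NULL, c("x", "y", "z")))
})

#' @rdname accessors
#' @export
setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[1L])

#' @rdname accessors
#' @export
setMethod("nAtoms", "Trajectory", function(x) dim(x@coords)[2L])

#' @rdname accessors
#' @export
setMethod("frameInterval", "Trajectory", function(x) x@frameInterval)

#' @rdname accessors
#' @export
setMethod("trajectoryMetadata", "Trajectory", function(x) x@metadata)

#' Subset a trajectory by frame
#'
#' @param x a \linkS4class{Trajectory}.
#' @param i integer vector of frame indices to keep (in the given order).
#' @param j,...,drop ignored.
#' @return a \linkS4class{Trajectory} with the selected frames.
#' @export
setMethod("[", "Trajectory", function(x, i, j, ..., drop = FALSE) {
  i <- as.integer(i)
  if (any(i < 1L) || any(i > nFrames(x))) stop("frame index out of range")
  new("Trajectory",
    topology = x@topology,
    coords = x@coords[i, , , drop = FALSE],
    frameInterval = x@frameInterval,
    originLabel = x@originLabel,
    metadata = x@metadata
  )
})

setMethod("show", "Trajectory", function(object) {
  cat(
    "Trajectory:", nFrames(object), "frames x", nAtoms(object), "atoms;",
    "frame interval", object@frameInterval, "ns\n",
    " origin:", object@originLabel, "\n"
  )
})

## ---- DistanceMatrix -------------------------------------------------------

#' @export
#' @method as.matrix DistanceMatrix
as.matrix.DistanceMatrix <- function(x, ...) x@values

setMethod("show", "DistanceMatrix", function(object) {
  cat(
    "DistanceMatrix (pairwise C-alpha RMSD):", nrow(object@values), "x",
    ncol(object@values), "frames; stride", object@strideUsed, "\n",
    " range [", round(min(object@values), 3), ",",
    round(max(object@values), 3), "] Angstrom\n"
  )
})

## ---- RmsdEmbedding --------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("coords", "RmsdEmbedding", function(x, ...) x@coords)

#' @rdname accessors
#' @export
setMethod("eigenvalues", "RmsdEmbedding", function(x) x@eigenvalues)

#' @rdname accessors
#' @export
setMethod("explainedFraction", "RmsdEmbedding", function(x) x@explainedFraction)

#' @rdname accessors
#' @export
setMethod("nFrames", "RmsdEmbedding", function(x) nrow(x@coords))

setMethod("show", "RmsdEmbedding", function(object) {
  cat(
    "RmsdEmbedding: ", nrow(object@coords), " frames in ", object@k,
    " dimensions\n  explained fraction ",
    round(object@explainedFraction, 4),
    "; negative eigenvalue mass ", round(object@negativeFraction, 4), "\n",
    sep = ""
  )
})

## ---- StepVectorSeries -----------------------------------------------------

#' @rdname accessors
#' @export
setMethod("terminals", "StepVectorSeries", function(x) x@terminals)

#' @rdname accessors
#' @export
setMethod("displacements", "StepVectorSeries", function(x) x@displacements)

#' @rdname accessors
#' @export
setMethod("stepNorms", "StepVectorSeries", function(x) x@norms)

#' @rdname accessors
#' @export
setMethod("nFrames", "StepVectorSeries", function(x) nrow(x@terminals))

#' @rdname accessors
#' @export
setMethod("frameInterval", "StepVectorSeries", function(x) x@frameInterval)

setMethod("show", "StepVectorSeries", function(object) {
  cat(
    "StepVectorSeries:", length(object@norms), "steps over",
    nrow(object@terminals), "frames; median step norm",
    round(stats::median(object@norms), 4), "Angstrom\n"
  )
})

## ---- NativeExit -----------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("exitFrame", "NativeExit", function(x) x@exitFrame)

#' @rdname accessors
#' @export
setMethod("exitTime", "NativeExit", function(x) x@exitTime)

setMethod("show", "NativeExit", function(object) {
  if (is.na(object@exitFrame)) {
    cat("NativeExit: no exit detected\n")
  } else {
    cat(
      "NativeExit: frame", object@exitFrame, "(",
      signif(object@exitTime, 4), "ns )\n"
    )
  }
  cat(
    "  step-norm threshold", signif(object@threshold, 4),
    "; cluster radius", signif(object@clusterRadius, 4),
    "; persistence", object@persistence, "frames\n"
  )
})

## ---- LandscapeGrid --------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("gridCounts", "LandscapeGrid", function(x) x@counts)

#' @rdname accessors
#' @export
setMethod("deltaF", "LandscapeGrid", function(x) x@deltaF)

setMethod("show", "LandscapeGrid", function(object) {
  cat(
    "LandscapeGrid:", nrow(object@counts), "x", ncol(object@counts),
    "bins;", object@nPoints, "points;", sum(object@counts > 0),
    "occupied bins\n"
  )
  if (is.finite(object@rt)) {
    cat(
      "  deltaF filled at T =", object@temperature, "K (RT =",
      signif(object@rt, 4), "kcal/mol); max occupied deltaF",
      round(max(object@deltaF[object@counts > 0]), 3), "kcal/mol\n"
    )
  } else {
    cat("  counts only (apply freeEnergy() for deltaF)\n")
  }
})

## ---- ReactionPath ---------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("pathProfile", "ReactionPath", function(x) x@profile)

#' @rdname accessors
#' @export
setMethod("arcLength", "ReactionPath", function(x) x@arcLength)

#' @rdname accessors
#' @export
setMethod("deltaFActivation", "ReactionPath", function(x) x@deltaFActivation)

#' @rdname accessors
#' @export
setMethod("channelIndex", "ReactionPath", function(x) x@channelIndex)

#' @rdname accessors
#' @export
setMethod("intermediates", "ReactionPath", function(x) x@intermediates)

setMethod("show", "ReactionPath", function(object) {
  cat(
    "ReactionPath:", nrow(object@binSequence), "bins, arc length",
    round(max(object@arcLength), 3), "Angstrom\n",
    " deltaF_activation", round(object@deltaFActivation, 3), "kcal/mol"
  )
  if (!is.na(object@channelIndex)) {
    cat("; channel index", round(object@channelIndex, 3))
  }
  cat("\n")
  if (nrow(object@intermediates)) {
    cat(
      "  post-barrier minima:", nrow(object@intermediates), "(",
      sum(object@intermediates$stable), "stable )\n"
    )
  }
})

## ---- ContactSeries --------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("nativeSet", "ContactSeries", function(x) x@nativeSet)

#' @rdname accessors
#' @export
setMethod("qFraction", "ContactSeries", function(x) x@qFraction)

#' @rdname accessors
#' @export
setMethod("nativeContactCount", "ContactSeries", function(x) x@q)

#' @rdname accessors
#' @export
setMethod("totalContactCount", "ContactSeries", function(x) x@total)

#' @rdname accessors
#' @export
setMethod("rgSeries", "ContactSeries", function(x) x@rg)

#' @rdname accessors
#' @export
setMethod("nFrames", "ContactSeries", function(x) length(x@q))

setMethod("show", "ContactSeries", function(object) {
  cat(
    "ContactSeries:", length(object@q), "frames;", nrow(object@nativeSet),
    "native contacts (cutoff", object@definition$cutoff, "Angstrom, |i-j| >=",
    object@definition$minSeqSep, ")\n",
    " mean q-fraction", round(mean(object@qFraction), 3),
    "; Rg native", round(object@rgNative, 2), "Angstrom\n"
  )
})

## ---- TransitionEnsemble ---------------------------------------------------

#' @rdname accessors
#' @export
setMethod("memberFrames", "TransitionEnsemble", function(x) x@memberFrames)

#' @rdname accessors
#' @export
setMethod("frameRange", "TransitionEnsemble", function(x) x@frameRange)

setMethod("show", "TransitionEnsemble", function(object) {
  cat(
    "TransitionEnsemble: frames", object@frameRange[1L], "-",
    object@frameRange[2L], ";", length(object@memberFrames),
    "molten-globule members\n"
  )
})

## ---- SecondaryStructureTimeline -------------------------------------------

#' @rdname accessors
#' @export
setMethod("ssLabels", "SecondaryStructureTimeline", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("persistenceByFrame", "SecondaryStructureTimeline",
          function(x) x@persistenceByFrame)

#' @rdname accessors
#' @export
setMethod("persistenceByResidue", "SecondaryStructureTimeline",
          function(x) x@persistenceByResidue)

setMethod("show", "SecondaryStructureTimeline", function(object) {
  cat(
    "SecondaryStructureTimeline:", nrow(object@labels), "frames x",
    ncol(object@labels), "residues; native H/E/C =",
    sum(object@nativeLabels == "H"), "/", sum(object@nativeLabels == "E"),
    "/", sum(object@nativeLabels == "C"), "\n"
  )
})

## ---- PotentialSpec --------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("analyticBarrier", "PotentialSpec", function(x) x@analyticBarrier)

setMethod("show", "PotentialSpec", function(object) {
  p <- object@parameters
  cat(
    "PotentialSpec <", object@kind, ">: ",
    paste(names(p), unlist(p), sep = " = ", collapse = ", "),
    "; analytic barrier ", object@analyticBarrier, " kcal/mol\n",
    sep = ""
  )
})
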