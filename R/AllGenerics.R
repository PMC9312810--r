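#' @include AllClasses.R
NULL

#' Accessor generics
#'
#' Small accessor family for the package's S4 containers. Each returns the
#' slot content documented on the class page.
#'
#' @param x,object an object of one of the package's S4 classes.
#' @param ... passed on to methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))

#' @rdname accessors
#' @export
setGeneric("coords", function(x, ...) standardGeneric("coords"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname accessors
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' @rdname accessors
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' @rdname accessors
#' @export
setGeneric("calphaMask", function(x) standardGeneric("calphaMask"))

#' @rdname accessors
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))

#' @rdname accessors
#' @export
setGeneric("explainedFraction", function(x) standardGeneric("explainedFraction"))

#' @rdname accessors
#' @export
setGeneric("terminals", function(x) standardGeneric("terminals"))

#' @rdname accessors
#' @export
setGeneric("displacements", function(x) standardGeneric("displacements"))

#' @rdname accessors
#' @export
setGeneric("stepNorms", function(x) standardGeneric("stepNorms"))

#' @rdname accessors
#' @export
setGeneric("exitFrame", function(x) standardGeneric("exitFrame"))

#' @rdname accessors
#' @export
setGeneric("exitTime", function(x) standardGeneric("exitTime"))

#' @rdname accessors
#' @export
setGeneric("gridCounts", function(x) standardGeneric("gridCounts"))

#' @rdname accessors
#' @export
setGeneric("deltaF", function(x) standardGeneric("deltaF"))

#' @rdname accessors
#' @export
setGeneric("pathProfile", function(x) standardGeneric("pathProfile"))

#' @rdname accessors
#' @export
setGeneric("arcLength", function(x) standardGeneric("arcLength"))

#' @rdname accessors
#' @export
setGeneric("deltaFActivation", function(x) standardGeneric("deltaFActivation"))

#' @rdname accessors
#' @export
setGeneric("channelIndex", function(x) standardGeneric("channelIndex"))

#' @rdname accessors
#' @export
setGeneric("intermediates", function(x) standardGeneric("intermediates"))

#' @rdname accessors
#' @export
setGeneric("nativeSet", function(x) standardGeneric("nativeSet"))

#' @rdname accessors
#' @export
setGeneric("qFraction", function(x) standardGeneric("qFraction"))

#' @rdname accessors
#' @export
setGeneric("nativeContactCount", function(x) standardGeneric("nativeContactCount"))

#' @rdname accessors
#' @export
setGeneric("totalContactCount", function(x) standardGeneric("totalContactCount"))

#' @rdname accessors
#' @export
setGeneric("rgSeries", function(x) standardGeneric("rgSeries"))

#' @rdname accessors
#' @export
setGeneric("memberFrames", function(x) standardGeneric("memberFrames"))

#' @rdname accessors
#' @export
setGeneric("frameRange", function(x) standardGeneric("frameRange"))

#' @rdname accessors
#' @export
setGeneric("ssLabels", function(x) standardGeneric("ssLabels"))

#' @rdname accessors
#' @export
setGeneric("persistenceByFrame", function(x) standardGeneric("persistenceByFrame"))

#' @rdname accessors
#' @export
setGeneric("persistenceByResidue", function(x) standardGeneric("persistenceByResidue"))

#' @rdname accessors
#' @export
setGeneric("analyticBarrier", function(x) standardGeneric("analyticBarrier"))

#' @rdname accessors
#' @export
setGeneric("trajectoryMetadata", function(x) standardGeneric("trajectoryMetadata"))
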