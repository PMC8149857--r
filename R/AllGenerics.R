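#' Accessor generics
#'
#' Small accessor generics for the package's S4 classes: pattern containers
#' ([`PatternSet`][PatternSet-class], [`Pattern`][Pattern-class]), networks,
#' response grids and training results. Accessors are the supported way to
#' reach slot contents.
#'
#' @param x an object of the documented classes.
#' @param object an object of the documented classes.
#' @param ... further arguments for methods.
#' @return The accessed component; see the class documentation.
#' @name accessors
#' @aliases patternValues patternCategory noiseIndex gridSize nBits nPatterns
#'   provenance signedWeights eyfp weightedSums learnedWeights lossTrajectory
#'   isConverged
NULL

#' @rdname accessors
#' @export
setGeneric("patternValues", function(x) standardGeneric("patternValues"))

#' @rdname accessors
#' @export
setGeneric("patternCategory", function(x) standardGeneric("patternCategory"))

#' @rdname accessors
#' @export
setGeneric("noiseIndex", function(x) standardGeneric("noiseIndex"))

#' @rdname accessors
#' @export
setGeneric("gridSize", function(x) standardGeneric("gridSize"))

#' @rdname accessors
#' @export
setGeneric("nBits", function(x) standardGeneric("nBits"))

#' @rdname accessors
#' @export
setGeneric("nPatterns", function(x) standardGeneric("nPatterns"))

#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname accessors
#' @export
setGeneric("signedWeights", function(x) standardGeneric("signedWeights"))

#' @rdname accessors
#' @export
setGeneric("eyfp", function(x) standardGeneric("eyfp"))

#' @rdname accessors
#' @export
setGeneric("weightedSums", function(x) standardGeneric("weightedSums"))

#' @rdname accessors
#' @export
setGeneric("learnedWeights", function(x) standardGeneric("learnedWeights"))

#' @rdname accessors
#' @export
setGeneric("lossTrajectory", function(x) standardGeneric("lossTrajectory"))

#' @rdname accessors
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))
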