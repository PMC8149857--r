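#' @import methods
NULL

#' Hill transfer-function parameterizations
#'
#' `HillActivatorParams` holds the parameters of an activating Hill transfer
#' function \deqn{f(x) = \beta_m \frac{(x/K_d)^n}{1 + (x/K_d)^n} + \beta_m
#' \beta_0,} the form used for sender P_lux activator promoters and for the
#' receiver P_cin activation function. `HillRepressorParams` holds the
#' parameters of the repressing form \deqn{f(x) = \frac{\alpha_m}{1 +
#' (x/K_d)^n} + \alpha_0 \alpha_m,} used for the P_lux repressor promoter that
#' implements a negative perceptron weight.
#'
#' @slot Kd dissociation constant, in the units of the input axis (uM inducer
#'   for sender/receiver rows, mCherry arbitrary units for the receiver
#'   activation function).
#' @slot n Hill coefficient (dimensionless, > 0).
#' @slot label registry name of the parameter set (e.g. `"R_PF"`).
#' @slot inputUnit unit of the input axis; operations that combine senders and
#'   receivers refuse to mix units.
#'
#' @seealso [hillActivator()], [hillRepressor()], [defaultRegistry()]
#' @name HillParams-classes
#' @aliases HillParams-class HillActivatorParams-class HillRepressorParams-class
NULL

setClass("HillParams",
  representation("VIRTUAL",
    Kd = "numeric", n = "numeric", label = "character",
    inputUnit = "character"))

#' @slot betaM maximal promoter activity (fluorescence arb. units).
#' @slot beta0 basal fraction (dimensionless, >= 0); basal activity is
#'   `betaM * beta0`.
#' @rdname HillParams-classes
setClass("HillActivatorParams", contains = "HillParams",
  representation(betaM = "numeric", beta0 = "numeric"))

#' @slot alphaM maximal activity of the repressor promoter (arb. units); the
#'   signed weight is `-alphaM`.
#' @slot alpha0 minimal-activity fraction (dimensionless, >= 0).
#' @rdname HillParams-classes
setClass("HillRepressorParams", contains = "HillParams",
  representation(alphaM = "numeric", alpha0 = "numeric"))

.validHillCommon <- function(object) {
  msg <- character()
  if (length(object@Kd) != 1L || !is.finite(object@Kd) || object@Kd <= 0)
    msg <- c(msg, "'Kd' must be a single positive number")
  if (length(object@n) != 1L || !is.finite(object@n) || object@n <= 0)
    msg <- c(msg, "'n' must be a single positive number")
  if (length(object@label) != 1L)
    msg <- c(msg, "'label' must be a single string")
  if (length(object@inputUnit) != 1L)
    msg <- c(msg, "'inputUnit' must be a single string")
  msg
}

setValidity("HillActivatorParams", function(object) {
  msg <- .validHillCommon(object)
  if (length(object@betaM) != 1L || !is.finite(object@betaM) || object@betaM <= 0)
    msg <- c(msg, "'betaM' must be a single positive number")
  if (length(object@beta0) != 1L || !is.finite(object@beta0) || object@beta0 < 0)
    msg <- c(msg, "'beta0' must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

setValidity("HillRepressorParams", function(object) {
  msg <- .validHillCommon(object)
  if (length(object@alphaM) != 1L || !is.finite(object@alphaM) || object@alphaM <= 0)
    msg <- c(msg, "'alphaM' must be a single positive number")
  if (length(object@alpha0) != 1L || !is.finite(object@alpha0) || object@alpha0 < 0)
    msg <- c(msg, "'alpha0' must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

#' A single input pattern
#'
#' One category-labelled input pattern: a flattened (row-major) grid of
#' OC6-induction states, binary or graded, together with the position of the
#' flipped bit for noisy variants.
#'
#' @slot category category label (`"z"`, `"v"`, `"n"`, or `"free"`).
#' @slot gridSize bits per side for square N x N grids; `NA` for flat vectors
#'   such as the 4-bit patterns.
#' @slot values numeric vector in `[0, 1]`, length `gridSize^2` (or arbitrary
#'   for flat patterns).
#' @slot noiseIndex `-1L` for the clean (ideal) pattern, otherwise the 1-based
#'   position of the single flipped bit.
#' @seealso [makeCleanPattern()], [expandNoisy()]
#' @aliases Pattern-class
#' @name Pattern-class
setClass("Pattern",
  representation(category = "character", gridSize = "integer",
    values = "numeric", noiseIndex = "integer"))

setValidity("Pattern", function(object) {
  msg <- character()
  v <- object@values
  if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
    msg <- c(msg, "'values' must lie in [0, 1]")
  if (!is.na(object@gridSize) && length(v) != object@gridSize^2)
    msg <- c(msg, "'values' length must equal gridSize^2")
  if (object@noiseIndex != -1L &&
      (object@noiseIndex < 1L || object@noiseIndex > length(v)))
    msg <- c(msg, "'noiseIndex' must be -1 or a valid bit position")
  if (length(msg)) msg else TRUE
})

#' A set of input patterns
#'
#' Container for a collection of patterns sharing one bit layout: the rows of
#' `values` are flattened patterns, ordered category-major with the clean
#' pattern first and its single-bit-flip variants in raster order. The
#' `provenance` list records how the set was built (kind `"binary"` or
#' `"graded"`, the seed, and the shared scaling vector for graded sets).
#'
#' @slot gridSize bits per side (`NA` for flat sets such as the 4-bit
#'   enumeration).
#' @slot nBits number of bits per pattern.
#' @slot values numeric matrix, one row per pattern, entries in `[0, 1]`.
#' @slot category character vector of per-pattern category labels.
#' @slot noiseIndex integer vector; `-1L` for clean patterns, else the flipped
#'   1-based bit position.
#' @slot provenance list describing construction.
#' @seealso [makePatternSet()], [makeNonbinary()], [enumerate4bit()]
#' @aliases PatternSet-class
#' @name PatternSet-class
setClass("PatternSet",
  representation(gridSize = "integer", nBits = "integer", values = "matrix",
    category = "character", noiseIndex = "integer", provenance = "list"))

setValidity("PatternSet", function(object) {
  msg <- character()
  v <- object@values
  if (nrow(v) != length(object@category))
    msg <- c(msg, "one category label per pattern required")
  if (nrow(v) != length(object@noiseIndex))
    msg <- c(msg, "one noiseIndex per pattern required")
  if (ncol(v) != object@nBits)
    msg <- c(msg, "'values' must have nBits columns")
  if (nrow(v) > 0 && (any(!is.finite(v)) || any(v < 0) || any(v > 1)))
    msg <- c(msg, "pattern values must lie in [0, 1]")
  if (!is.na(object@gridSize) && object@nBits != object@gridSize^2)
    msg <- c(msg, "nBits must equal gridSize^2 for square sets")
  if (length(msg)) msg else TRUE
})

#' Sender specification
#'
#' One sender group implementing a single perceptron weight: a P_lux-driven
#' E. coli population whose mCherry output at the induction OC6 level is the
#' weight magnitude. The sign is `+1` for activator promoters and `-1` for the
#' P_lux repressor promoter.
#'
#' @slot label sender name.
#' @slot sign `+1` (activator) or `-1` (repressor).
#' @slot params `HillActivatorParams`, `HillRepressorParams`, or `NULL` for a
#'   calibrated weight with no attached transfer function.
#' @slot inductionLevel OC6 concentration (uM) representing an input bit of 1.
#' @slot weightValue non-negative weight magnitude (mCherry arb. units); the
#'   signed weight is `sign * weightValue`.
#' @seealso [senderSpec()], [consortiumNetwork()]
#' @aliases SenderSpec-class
#' @name SenderSpec-class
setClass("SenderSpec",
  representation(label = "character", sign = "numeric", params = "ANY",
    inductionLevel = "numeric", weightValue = "numeric"))

setValidity("SenderSpec", function(object) {
  msg <- character()
  if (!object@sign %in% c(-1, 1))
    msg <- c(msg, "'sign' must be +1 or -1")
  if (!is.finite(object@weightValue) || object@weightValue < 0)
    msg <- c(msg, "'weightValue' must be a non-negative number")
  if (!is.finite(object@inductionLevel) || object@inductionLevel < 0)
    msg <- c(msg, "'inductionLevel' must be non-negative")
  if (!is.null(object@params) && !is(object@params, "HillParams"))
    msg <- c(msg, "'params' must be NULL or Hill parameters")
  if (length(msg)) msg else TRUE
})

#' Sender-receiver consortium network
#'
#' Forward model of the perceptron: an ordered list of senders (one per input
#' bit), the receiver activation function on the mCherry-equivalent axis, the
#' policy for "0" bits (aTc-suppressed senders contribute nothing by default;
#' `"leaky"` adds sender basal activity), and an optional multiplicative
#' weight-noise model.
#'
#' @slot senders list of [`SenderSpec`][SenderSpec-class] objects.
#' @slot receiver `HillActivatorParams` for the receiver activation function
#'   (EYFP as a function of collective sender mCherry).
#' @slot bitZeroPolicy `"zero"` or `"leaky"`.
#' @slot noiseCV coefficient of variation of multiplicative weight noise
#'   (0 disables noise).
#' @slot noiseSeed integer seed used when noise is enabled.
#' @seealso [consortiumNetwork()], [forwardResponse()]
#' @aliases ConsortiumNetwork-class
#' @name ConsortiumNetwork-class
setClass("ConsortiumNetwork",
  representation(senders = "list", receiver = "HillActivatorParams",
    bitZeroPolicy = "character", noiseCV = "numeric", noiseSeed = "integer"))

setValidity("ConsortiumNetwork", function(object) {
  msg <- character()
  if (!all(vapply(object@senders, is, logical(1), "SenderSpec")))
    msg <- c(msg, "all senders must be SenderSpec objects")
  if (!object@bitZeroPolicy %in% c("zero", "leaky"))
    msg <- c(msg, "'bitZeroPolicy' must be \"zero\" or \"leaky\"")
  if (!is.finite(object@noiseCV) || object@noiseCV < 0)
    msg <- c(msg, "'noiseCV' must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Simulated receiver responses for weight vectors x patterns
#'
#' Grid of simulated receiver EYFP outputs, one row per weight vector and one
#' column per pattern, together with the underlying weighted sums (collective
#' OHC14 proxy on the mCherry-equivalent axis) and the weight vectors
#' themselves.
#'
#' @slot eyfp numeric matrix of simulated receiver EYFP (arb. units).
#' @slot sums numeric matrix of weighted sums before clamping.
#' @slot weights numeric matrix, one row per weight vector.
#' @slot patternIds character vector of pattern identifiers.
#' @seealso [responseMatrix()], [countUniqueProducts()]
#' @aliases ResponseMatrix-class
#' @name ResponseMatrix-class
setClass("ResponseMatrix",
  representation(eyfp = "matrix", sums = "matrix", weights = "matrix",
    patternIds = "character"))

setValidity("ResponseMatrix", function(object) {
  msg <- character()
  if (!identical(dim(object@eyfp), dim(object@sums)))
    msg <- c(msg, "'eyfp' and 'sums' must have identical dimensions")
  if (nrow(object@eyfp) != nrow(object@weights))
    msg <- c(msg, "one weight vector per response row required")
  if (ncol(object@eyfp) != length(object@patternIds))
    msg <- c(msg, "one pattern id per column required")
  if (length(msg)) msg else TRUE
})

#' Weight-learning configuration
#'
#' Hyperparameters of the gradient-descent weight-learning algorithm with
#' discrete-level constraints. See [trainingConfig()] for defaults and
#' parameter meanings.
#'
#' @slot eta learning rate (dimensionless).
#' @slot maxIter maximum gradient iterations.
#' @slot lossTol convergence threshold on the span-normalized loss.
#' @slot gradStep finite-difference step (weight arb. units).
#' @slot palette sorted vector of allowed discrete signed weight levels.
#' @slot mode `"discrete"` or `"continuous-positive"`.
#' @slot projectionCadence `"converged"` or `"everyStep"`.
#' @slot directSearchRadius neighbourhood half-width in palette index steps.
#' @slot directSearchBudget maximum neighbourhood size evaluated exhaustively.
#' @slot seed integer RNG seed.
#' @slot initPolicy `"uniform"` (seeded uniform in the positive palette range).
#' @aliases TrainingConfig-class
#' @name TrainingConfig-class
setClass("TrainingConfig",
  representation(eta = "numeric", maxIter = "integer", lossTol = "numeric",
    gradStep = "numeric", palette = "numeric", mode = "character",
    projectionCadence = "character", directSearchRadius = "integer",
    directSearchBudget = "numeric", seed = "integer", initPolicy = "character"))

setValidity("TrainingConfig", function(object) {
  msg <- character()
  if (!is.finite(object@eta) || object@eta <= 0)
    msg <- c(msg, "'eta' must be positive")
  if (object@mode == "discrete" && length(object@palette) == 0)
    msg <- c(msg, "discrete mode requires a non-empty palette")
  if (length(object@palette) && is.unsorted(object@palette))
    msg <- c(msg, "'palette' must be sorted increasing")
  if (object@directSearchRadius < 1L)
    msg <- c(msg, "'directSearchRadius' must be >= 1")
  if (!object@mode %in% c("discrete", "continuous-positive"))
    msg <- c(msg, "'mode' must be \"discrete\" or \"continuous-positive\"")
  if (!object@projectionCadence %in% c("converged", "everyStep"))
    msg <- c(msg, "'projectionCadence' must be \"converged\" or \"everyStep\"")
  if (length(msg)) msg else TRUE
})

#' Result of a training run
#'
#' @slot weights learned weight vector.
#' @slot lossTrajectory span-normalized loss per accepted iteration.
#' @slot converged logical; `TRUE` when the loss tolerance was reached or the
#'   trajectory stalled at a stationary point.
#' @slot diverged logical; `TRUE` when the loss became non-finite.
#' @slot nSearchEvals number of candidate weight vectors evaluated during
#'   discrete refinement (projection + direct/coordinate search).
#' @slot responses final simulated receiver responses, one per pattern.
#' @slot targets numeric target vector the responses were trained towards.
#' @slot seed seed used for initialization.
#' @slot config the [`TrainingConfig`][TrainingConfig-class] used.
#' @aliases TrainingResult-class
#' @name TrainingResult-class
setClass("TrainingResult",
  representation(weights = "numeric", lossTrajectory = "numeric",
    converged = "logical", diverged = "logical", nSearchEvals = "numeric",
    responses = "numeric", targets = "numeric", seed = "integer",
    config = "TrainingConfig"))
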