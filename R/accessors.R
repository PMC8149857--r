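#' @rdname accessors
#' @export
setMethod("patternValues", "Pattern", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("patternValues", "PatternSet", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("patternCategory", "Pattern", function(x) x@category)

#' @rdname accessors
#' @export
setMethod("patternCategory", "PatternSet", function(x) x@category)

#' @rdname accessors
#' @export
setMethod("noiseIndex", "Pattern", function(x) x@noiseIndex)

#' @rdname accessors
#' @export
setMethod("noiseIndex", "PatternSet", function(x) x@noiseIndex)

#' @rdname accessors
#' @export
setMethod("gridSize", "Pattern", function(x) x@gridSize)

#' @rdname accessors
#' @export
setMethod("gridSize", "PatternSet", function(x) x@gridSize)

#' @rdname accessors
#' @export
setMethod("nBits", "Pattern", function(x) length(x@values))

#' @rdname accessors
#' @export
setMethod("nBits", "PatternSet", function(x) x@nBits)

#' @rdname accessors
#' @export
setMethod("nPatterns", "PatternSet", function(x) nrow(x@values))

#' @rdname accessors
#' @export
setMethod("provenance", "PatternSet", function(x) x@provenance)

#' @rdname accessors
#' @export
setMethod("signedWeights", "ConsortiumNetwork", function(x) {
  vapply(x@senders, function(s) s@sign * s@weightValue, numeric(1))
})

#' @rdname accessors
#' @export
setMethod("eyfp", "ResponseMatrix", function(x) x@eyfp)

#' @rdname accessors
#' @export
setMethod("weightedSums", "ResponseMatrix", function(x) x@sums)

#' @rdname accessors
#' @export
setMethod("learnedWeights", "TrainingResult", function(x) x@weights)

#' @rdname accessors
#' @export
setMethod("lossTrajectory", "TrainingResult", function(x) x@lossTrajectory)

#' @rdname accessors
#' @export
setMethod("isConverged", "TrainingResult", function(x) x@converged)

#' Subset a pattern set
#'
#' @param x a [`PatternSet`][PatternSet-class].
#' @param i pattern indices (logical or integer).
#' @param j unused.
#' @param ... unused.
#' @param drop unused.
#' @return A `PatternSet` with the selected patterns, provenance preserved.
#' @export
setMethod("[", "PatternSet", function(x, i, j, ..., drop = FALSE) {
  new("PatternSet", gridSize = x@gridSize, nBits = x@nBits,
    values = x@values[i, , drop = FALSE], category = x@category[i],
    noiseIndex = x@noiseIndex[i], provenance = x@provenance)
})

#' Extract one pattern from a set
#'
#' @param x a [`PatternSet`][PatternSet-class].
#' @param i single pattern index.
#' @return A [`Pattern`][Pattern-class].
#' @export
getPattern <- function(x, i) {
  stopifnot(is(x, "PatternSet"), length(i) == 1L, i >= 1L, i <= nPatterns(x))
  new("Pattern", category = x@category[i], gridSize = x@gridSize,
    values = as.numeric(x@values[i, ]), noiseIndex = x@noiseIndex[i])
}

setMethod("show", "HillActivatorParams", function(object) {
  cat(sprintf(
    "Hill activator '%s': Kd = %g %s, n = %g, betaM = %g, beta0 = %g\n",
    object@label, object@Kd, object@inputUnit, object@n, object@betaM,
    object@beta0))
})

setMethod("show", "HillRepressorParams", function(object) {
  cat(sprintf(
    "Hill repressor '%s': Kd = %g %s, n = %g, alphaM = %g (weight %g), alpha0 = %g\n",
    object@label, object@Kd, object@inputUnit, object@n, object@alphaM,
    -object@alphaM, object@alpha0))
})

setMethod("show", "Pattern", function(object) {
  tag <- if (object@noiseIndex == -1L) "clean" else
    sprintf("bit %d flipped", object@noiseIndex)
  cat(sprintf("Pattern '%s' (%s), %d bits\n", object@category, tag,
    length(object@values)))
  if (!is.na(object@gridSize)) {
    m <- matrix(object@values, object@gridSize, object@gridSize, byrow = TRUE)
    apply(m, 1L, function(r) cat(" ", paste(format(r, digits = 3)), "\n"))
  }
  invisible(NULL)
})

setMethod("show", "PatternSet", function(object) {
  cat(sprintf("PatternSet: %d patterns x %d bits (%s)\n",
    nPatterns(object), nBits(object),
    if (is.na(object@gridSize)) "flat" else
      sprintf("%dx%d grid", object@gridSize, object@gridSize)))
  tab <- table(object@category)
  cat("  categories:",
    paste(sprintf("%s (%d)", names(tab), as.integer(tab)), collapse = ", "),
    "\n")
  cat("  kind:", object@provenance$kind %||% "binary", "\n")
})

setMethod("show", "SenderSpec", function(object) {
  cat(sprintf("Sender '%s': sign %+d, weight %g (OC6 %g uM)\n", object@label,
    as.integer(object@sign), object@weightValue, object@inductionLevel))
})

setMethod("show", "ConsortiumNetwork", function(object) {
  w <- signedWeights(object)
  cat(sprintf("ConsortiumNetwork: %d senders -> receiver '%s'\n",
    length(object@senders), object@receiver@label))
  cat("  signed weights:", paste(format(w), collapse = ", "), "\n")
  cat(sprintf("  bit-0 policy: %s; weight noise CV: %g\n",
    object@bitZeroPolicy, object@noiseCV))
})

setMethod("show", "ResponseMatrix", function(object) {
  cat(sprintf("ResponseMatrix: %d weight vector(s) x %d pattern(s)\n",
    nrow(object@eyfp), ncol(object@eyfp)))
  if (length(object@eyfp))
    cat(sprintf("  EYFP range: [%g, %g]\n", min(object@eyfp),
      max(object@eyfp)))
})

setMethod("show", "TrainingConfig", function(object) {
  cat(sprintf(
    "TrainingConfig: mode %s, eta %g, maxIter %d, lossTol %g, seed %d\n",
    object@mode, object@eta, object@maxIter, object@lossTol, object@seed))
  if (length(object@palette))
    cat("  palette:", paste(object@palette, collapse = ", "), "\n")
})

setMethod("show", "TrainingResult", function(object) {
  cat(sprintf(
    "TrainingResult: %s after %d iteration(s), final loss %.6g\n",
    if (object@diverged) "diverged" else if (object@converged) "converged"
    else "stopped",
    length(object@lossTrajectory),
    if (length(object@lossTrajectory)) utils::tail(object@lossTrajectory, 1)
    else NA_real_))
  cat("  weights:", paste(format(object@weights), collapse = ", "), "\n")
})
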