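# Forward model of the sender-receiver consortium: pattern -> signed weighted
# sum (collective OHC14 proxy on the mCherry-equivalent axis) -> receiver
# activation function -> simulated EYFP.

#' Construct a sender specification
#'
#' A sender implements one perceptron weight. The weight magnitude is either
#' supplied directly (a calibrated mCherry level) or evaluated from the
#' sender's fitted transfer function at the induction OC6 level; for
#' repressor senders the magnitude defaults to `alphaM` (the signed weight
#' `alphaHatM = -alphaM`) and the sign is `-1`.
#'
#' @param label sender name.
#' @param params optional [`HillActivatorParams`][HillParams-classes] or
#'   [`HillRepressorParams`][HillParams-classes]; determines the default sign
#'   and weight.
#' @param sign `+1` or `-1`; defaults to the sign implied by `params` (or
#'   `+1`).
#' @param inductionLevel OC6 concentration (uM) representing an input bit of
#'   1; 33 uM is the protocol level in the high-inducer analog range.
#' @param weightValue optional non-negative weight magnitude override
#'   (mCherry arb. units).
#' @return A [`SenderSpec`][SenderSpec-class].
#' @export
#' @examples
#' senderSpec("mut8", params = registryRow("S_mut8"))       # evaluated weight
#' senderSpec("w2", weightValue = 3500)                     # calibrated
senderSpec <- function(label, params = NULL, sign = NULL,
                       inductionLevel = 33, weightValue = NULL) {
  if (is.null(sign))
    sign <- if (is(params, "HillRepressorParams")) -1 else 1
  if (is.null(weightValue)) {
    if (is.null(params))
      stop("either 'params' or 'weightValue' must be given")
    weightValue <- if (is(params, "HillRepressorParams")) params@alphaM
      else evalActivator(params, inductionLevel)
  }
  new("SenderSpec", label = as.character(label), sign = as.numeric(sign),
    params = params, inductionLevel = as.numeric(inductionLevel),
    weightValue = as.numeric(weightValue))
}

#' Construct a consortium network
#'
#' Builds the forward model from either a signed weight vector (senders are
#' created with `weightValue = abs(w)` and `sign = sign(w)`) or an explicit
#' list of [`SenderSpec`][SenderSpec-class] objects. The receiver activation
#' function must live on the mCherry-equivalent axis, since the weighted sum
#' of sender mCherry outputs is its input; mixing input units is refused
#' unless `checkUnits = FALSE`.
#'
#' @param weights signed numeric weight vector (ignored when `senders` is
#'   given).
#' @param receiver [`HillActivatorParams`][HillParams-classes] of the
#'   receiver activation function; default the registry row `R_mCh`.
#' @param senders optional list of `SenderSpec` objects, one per input bit.
#' @param bitZeroPolicy contribution of a 0 bit: `"zero"` (default; models
#'   the aTc-suppressed state) or `"leaky"` (adds sender basal activity
#'   `betaM * beta0` where sender parameters are attached).
#' @param noiseCV coefficient of variation of multiplicative weight noise;
#'   0 disables noise.
#' @param noiseSeed seed for the weight-noise draws.
#' @param checkUnits refuse a receiver whose input axis is not mCherry units.
#' @return A [`ConsortiumNetwork`][ConsortiumNetwork-class].
#' @export
#' @examples
#' net <- consortiumNetwork(c(450, 3500, 900, 3500))
#' forwardResponse(net, c(1, 0, 1, 1))
consortiumNetwork <- function(weights = NULL, receiver = registryRow("R_mCh"),
                              senders = NULL, bitZeroPolicy = c("zero",
                                "leaky"), noiseCV = 0, noiseSeed = 1L,
                              checkUnits = TRUE) {
  bitZeroPolicy <- match.arg(bitZeroPolicy)
  if (is.null(senders)) {
    if (is.null(weights)) stop("either 'weights' or 'senders' must be given")
    senders <- lapply(seq_along(weights), function(i) {
      senderSpec(paste0("w", i), sign = if (weights[i] < 0) -1 else 1,
        weightValue = abs(weights[i]))
    })
  }
  if (checkUnits && !grepl("mCherry", receiver@inputUnit))
    stop("receiver input axis is '", receiver@inputUnit,
      "' but the weighted sum is in mCherry arb. units; ",
      "use checkUnits = FALSE to override")
  new("ConsortiumNetwork", senders = senders, receiver = receiver,
    bitZeroPolicy = bitZeroPolicy, noiseCV = as.numeric(noiseCV),
    noiseSeed = as.integer(noiseSeed))
}

.patternMatrix <- function(x, nbits) {
  if (is(x, "PatternSet")) x <- x@values
  if (is(x, "Pattern")) x <- matrix(x@values, nrow = 1L)
  if (is.null(dim(x))) x <- matrix(as.numeric(x), nrow = 1L)
  if (ncol(x) != nbits)
    stop("pattern length ", ncol(x), " does not match sender count ", nbits)
  if (any(x < 0) || any(x > 1)) stop("pattern entries must lie in [0, 1]")
  x
}

.leakyOffset <- function(net) {
  # basal mCherry of uninduced senders, added in "leaky" mode for 0 bits
  vapply(net@senders, function(s) {
    if (is(s@params, "HillActivatorParams")) s@params@betaM * s@params@beta0
    else 0
  }, numeric(1))
}

#' Weighted sum of a pattern under a network
#'
#' The collective OHC14 production proxy: `sum_i sign_i * weight_i * x_i`,
#' with graded entries scaling linearly and 0 bits contributing nothing under
#' the default bit-0 policy (`"leaky"` adds uninduced basal activity for
#' senders with attached activator parameters).
#'
#' @param net a [`ConsortiumNetwork`][ConsortiumNetwork-class].
#' @param x a pattern: numeric vector, [`Pattern`][Pattern-class], or
#'   [`PatternSet`][PatternSet-class] (one sum per pattern).
#' @return Numeric weighted sum(s), mCherry-equivalent arb. units (may be
#'   negative when repressor senders dominate).
#' @export
#' @examples
#' net <- consortiumNetwork(c(450, 3500, 900, 3500))
#' weightedSum(net, c(1, 0, 1, 1))  # 4850
weightedSum <- function(net, x) {
  stopifnot(is(net, "ConsortiumNetwork"))
  X <- .patternMatrix(x, length(net@senders))
  w <- signedWeights(net)
  s <- as.numeric(X %*% w)
  if (net@bitZeroPolicy == "leaky")
    s <- s + as.numeric((1 - X) %*% .leakyOffset(net))
  s
}

#' Receiver activation response
#'
#' Evaluates the receiver activation function at a weighted sum on the
#' mCherry-equivalent axis. Negative sums (repressor-dominated mixtures)
#' are clamped to zero with a warning: a signalling-molecule concentration
#' cannot be negative.
#'
#' @param r [`HillActivatorParams`][HillParams-classes] of the receiver.
#' @param s weighted sum(s).
#' @return Simulated EYFP (arb. units).
#' @export
#' @examples
#' receiverResponse(registryRow("R_mCh"), 1103)  # half-max + basal
receiverResponse <- function(r, s) {
  if (any(s < 0)) {
    warning(sum(s < 0), " negative weighted sum(s) clamped to 0")
    s <- pmax(s, 0)
  }
  evalActivator(r, s)
}

.noisyWeights <- function(net) {
  w <- signedWeights(net)
  if (net@noiseCV <= 0) return(w)
  # multiplicative lognormal perturbation with unit mean and the requested CV
  sdlog <- sqrt(log(1 + net@noiseCV^2))
  withSeed(net@noiseSeed,
    w * stats::rlnorm(length(w), meanlog = -sdlog^2 / 2, sdlog = sdlog))
}

#' Forward consortium response
#'
#' Composition of [weightedSum()] and [receiverResponse()]: maps a pattern to
#' simulated receiver EYFP. With weight noise enabled, seeded multiplicative
#' perturbations are applied to the weight magnitudes first.
#'
#' @inheritParams weightedSum
#' @return Simulated EYFP (arb. units), one value per pattern.
#' @export
forwardResponse <- function(net, x) {
  stopifnot(is(net, "ConsortiumNetwork"))
  X <- .patternMatrix(x, length(net@senders))
  w <- .noisyWeights(net)
  s <- as.numeric(X %*% w)
  if (net@bitZeroPolicy == "leaky")
    s <- s + as.numeric((1 - X) %*% .leakyOffset(net))
  receiverResponse(net@receiver, s)
}

#' Response matrix for several weight vectors over a pattern set
#'
#' Simulates every network against every pattern, producing the grid of
#' receiver outputs (and underlying weighted sums) whose rows correspond to
#' weight vectors and columns to patterns in set order.
#'
#' @param nets a single network or list of
#'   [`ConsortiumNetwork`][ConsortiumNetwork-class] objects sharing one
#'   receiver.
#' @param s a [`PatternSet`][PatternSet-class].
#' @return A [`ResponseMatrix`][ResponseMatrix-class].
#' @export
#' @examples
#' nets <- lapply(list(c(450, 3500, 900, 3500), c(900, 900, 900, 900)),
#'                consortiumNetwork)
#' rm4 <- responseMatrix(nets, enumerate4bit())
#' dim(eyfp(rm4))  # 2 x 16
responseMatrix <- function(nets, s) {
  if (is(nets, "ConsortiumNetwork")) nets <- list(nets)
  stopifnot(length(nets) > 0L, is(s, "PatternSet"))
  sums <- do.call(rbind, lapply(nets, function(net) {
    X <- .patternMatrix(s, length(net@senders))
    w <- .noisyWeights(net)
    out <- as.numeric(X %*% w)
    if (net@bitZeroPolicy == "leaky")
      out <- out + as.numeric((1 - X) %*% .leakyOffset(net))
    out
  }))
  resp <- do.call(rbind, lapply(seq_along(nets), function(i) {
    suppressWarnings(receiverResponse(nets[[i]]@receiver, sums[i, ]))
  }))
  ids <- paste0(s@category, ifelse(s@noiseIndex == -1L, "_clean",
    paste0("_flip", s@noiseIndex)))
  if (nPatterns(s) == 0L) ids <- character(0)
  new("ResponseMatrix", eyfp = resp, sums = sums,
    weights = do.call(rbind, lapply(nets, signedWeights)),
    patternIds = ids)
}

#' Count distinct weighted-sum products
#'
#' Many weight-pattern products in symmetric pattern sets are repetitions;
#' this counts the distinct weighted-sum values across a response grid, two
#' values being equal when they differ by at most `tolerance`.
#'
#' @param m a [`ResponseMatrix`][ResponseMatrix-class] or a numeric
#'   matrix/vector of weighted sums.
#' @param tolerance non-negative absolute tolerance; default
#'   `1e-6 * max(abs(sums))`.
#' @return A list with `count`, the distinct `values` (group means, sorted)
#'   and their `multiplicities`.
#' @export
#' @examples
#' countUniqueProducts(matrix(c(0, 5, 5, 9), 2))$count  # 3
countUniqueProducts <- function(m, tolerance = NULL) {
  s <- if (is(m, "ResponseMatrix")) m@sums else m
  s <- as.numeric(s)
  if (length(s) == 0L) stop("non-empty product matrix required")
  if (is.null(tolerance)) tolerance <- 1e-6 * max(abs(s), 0)
  if (tolerance < 0) stop("'tolerance' must be non-negative")
  s <- sort(s)
  grp <- cumsum(c(1, diff(s) > tolerance))
  list(count = as.integer(max(grp)),
    values = as.numeric(tapply(s, grp, mean)),
    multiplicities = as.integer(table(grp)))
}
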