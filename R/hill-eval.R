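#' Construct Hill transfer-function parameter objects
#'
#' `hillActivator()` builds the parameters of the activating Hill form used
#' for sender P_lux activator promoters and the receiver activation function;
#' `hillRepressor()` builds the repressing form used for the P_lux repressor
#' promoter (the negative perceptron weight).
#'
#' @param Kd dissociation constant (> 0), in the units of the input axis.
#' @param n Hill coefficient (> 0).
#' @param betaM maximal promoter activity (> 0, arb. units).
#' @param beta0 basal fraction (>= 0); basal activity is `betaM * beta0`.
#' @param alphaM maximal repressor-promoter activity (> 0, arb. units).
#' @param alpha0 minimal-activity fraction (>= 0).
#' @param label registry name.
#' @param inputUnit unit of the input axis (`"uM"` for inducer doses,
#'   `"mCherry arb. units"` for the receiver activation function).
#' @return A [`HillActivatorParams`][HillParams-classes] or
#'   [`HillRepressorParams`][HillParams-classes] object.
#' @export
#' @examples
#' rpf <- hillActivator(Kd = 0.28, n = 1.97, betaM = 2.25e4, beta0 = 3.95e-2,
#'                      label = "R_PF")
#' evalActivator(rpf, 0.28)  # half-maximal point plus basal
hillActivator <- function(Kd, n, betaM, beta0, label = "activator",
                          inputUnit = "uM") {
  new("HillActivatorParams", Kd = as.numeric(Kd), n = as.numeric(n),
    betaM = as.numeric(betaM), beta0 = as.numeric(beta0),
    label = as.character(label), inputUnit = as.character(inputUnit))
}

#' @rdname hillActivator
#' @export
hillRepressor <- function(Kd, n, alphaM, alpha0, label = "repressor",
                          inputUnit = "uM") {
  new("HillRepressorParams", Kd = as.numeric(Kd), n = as.numeric(n),
    alphaM = as.numeric(alphaM), alpha0 = as.numeric(alpha0),
    label = as.character(label), inputUnit = as.character(inputUnit))
}

#' Signed weight of a repressor promoter
#'
#' The repressor's contribution enters the perceptron as a negative weight
#' `alphaHatM = -alphaM`; the remaining constant factor of the repressing Hill
#' form stays inside [evalRepressor()].
#'
#' @param p a [`HillRepressorParams`][HillParams-classes] object.
#' @return The (negative) signed weight value.
#' @export
alphaHatM <- function(p) {
  stopifnot(is(p, "HillRepressorParams"))
  -p@alphaM
}

#' Hill fraction
#'
#' The saturating fraction `(x/Kd)^n / (1 + (x/Kd)^n)`. At `x = 0` it is
#' evaluated as exactly 0 for every `n`, avoiding `0^n` ambiguity for
#' fractional Hill coefficients.
#'
#' @param x non-negative input levels.
#' @param Kd dissociation constant (> 0).
#' @param n Hill coefficient (> 0).
#' @return Values in `[0, 1)`.
#' @export
hillFraction <- function(x, Kd, n) {
  if (any(x < 0)) stop("input levels must be non-negative")
  r <- (x / Kd)^n
  out <- r / (1 + r)
  out[x == 0] <- 0
  # (x/Kd)^n overflows to Inf for very large x; the fraction saturates at 1
  out[is.infinite(r)] <- 1
  out
}

#' Evaluate Hill transfer functions
#'
#' `evalActivator()` computes `betaM * h + betaM * beta0` with
#' `h = (x/Kd)^n / (1 + (x/Kd)^n)`: strictly increasing in `x`, bounded in
#' `[betaM * beta0, betaM * (1 + beta0))`. `evalRepressor()` computes
#' `alphaM / (1 + (x/Kd)^n) + alpha0 * alphaM`: strictly decreasing, from
#' `alphaM * (1 + alpha0)` at `x = 0` down to the floor `alpha0 * alphaM`.
#'
#' @param p a [`HillActivatorParams`][HillParams-classes] (or repressor)
#'   object.
#' @param x non-negative input levels, in `p`'s input unit.
#' @return Response in fluorescence arbitrary units, one value per `x`.
#' @export
#' @examples
#' srep <- hillRepressor(Kd = 0.252, n = 0.669, alphaM = 735, alpha0 = 0.341,
#'                       label = "S_plux_rep")
#' evalRepressor(srep, c(0, 0.252))  # 985.635, 618.135
evalActivator <- function(p, x) {
  stopifnot(is(p, "HillActivatorParams"))
  p@betaM * (hillFraction(x, p@Kd, p@n) + p@beta0)
}

#' @rdname evalActivator
#' @export
evalRepressor <- function(p, x) {
  stopifnot(is(p, "HillRepressorParams"))
  p@alphaM * (1 - hillFraction(x, p@Kd, p@n) + p@alpha0)
}

#' Derivative of the activating Hill form
#'
#' `d f / d x = betaM * (n / Kd) * (x/Kd)^(n-1) / (1 + (x/Kd)^n)^2`, used for
#' the analytic gradient of the training loss through the receiver activation
#' function. At `x = 0` the derivative is 0 for `n > 1`, `betaM/Kd` for
#' `n = 1`, and unbounded for `n < 1` (returned as `Inf`).
#'
#' @inheritParams evalActivator
#' @return Derivative values (arb. units per input unit).
#' @export
activatorDerivative <- function(p, x) {
  stopifnot(is(p, "HillActivatorParams"))
  if (any(x < 0)) stop("input levels must be non-negative")
  r <- (x / p@Kd)^p@n
  out <- p@betaM * (p@n / p@Kd) * (x / p@Kd)^(p@n - 1) / (1 + r)^2
  at0 <- x == 0
  if (any(at0))
    out[at0] <- if (p@n > 1) 0 else if (p@n == 1) p@betaM / p@Kd else Inf
  out[is.infinite(r)] <- 0
  out
}
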