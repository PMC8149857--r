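# Least-squares fitting of Hill transfer functions to dose-response tables.
# The objective is least squares on log-transformed responses: dose-response
# measurements span decades, and log-space residuals weight the dynamic range
# evenly instead of letting the saturated plateau dominate.

.fitDiagnostics <- function(logObs, logFit, converged, degenerate,
                            message = "") {
  resid <- logObs - logFit
  ss <- sum(resid^2)
  tot <- sum((logObs - mean(logObs))^2)
  r2 <- if (tot > 0) 1 - ss / tot else NA_real_
  list(converged = converged, degenerate = degenerate,
    residualNorm = sqrt(ss), rmsLogResidual = sqrt(mean(resid^2)),
    logR2 = r2, poorFit = is.na(r2) || r2 < 0.5, message = message)
}

.flatData <- function(y) {
  # response range too small to identify Kd or n
  max(y) / max(min(y), .Machine$double.eps) < 1.2
}

#' Fit Hill transfer functions to dose-response data
#'
#' Fits the activating or repressing Hill form to a dose-response table by
#' Levenberg-Marquardt least squares on log-transformed responses (via
#' [minpack.lm::nlsLM()]), with positivity bounds on all parameters and the
#' Hill coefficient constrained to `(0.1, 10]`. Starting values follow the
#' response midpoint heuristic: `Kd` at the input level whose response is
#' nearest the midpoint, `n = 1`, amplitude from the response extremes.
#'
#' Failures are reported, not hidden: non-convergence returns a flagged
#' result with diagnostics, flat data (response range under 20%) is flagged
#' `degenerate` (the Hill coefficient is unidentifiable), and a fit whose
#' log-scale R-squared falls below 0.5 is flagged `poorFit` (e.g. fitting the
#' repressing form to increasing data). Fewer than 4 distinct input levels is
#' an error.
#'
#' @param d a dose-response table (see [doseResponse()]).
#' @param init optional starting parameter object of the matching class.
#' @return A list with elements `params` (the fitted
#'   [`HillActivatorParams`][HillParams-classes] or
#'   [`HillRepressorParams`][HillParams-classes]) and `diagnostics` (list:
#'   `converged`, `degenerate`, `poorFit`, `residualNorm`, `rmsLogResidual`,
#'   `logR2`, `message`).
#' @export
#' @examples
#' d <- simulateDoseResponse(registryRow("S_mut8"))
#' fit <- fitActivator(d)
#' fit$params
fitActivator <- function(d, init = NULL) {
  .fitHill(d, init, repressor = FALSE)
}

#' @rdname fitActivator
#' @export
fitRepressor <- function(d, init = NULL) {
  .fitHill(d, init, repressor = TRUE)
}

.fitHill <- function(d, init, repressor) {
  .checkDoseResponse(d, minLevels = 4L)
  if (any(d$response <= 0)) stop("responses must be positive for fitting")
  x <- d$input_level
  y <- d$response
  label <- if ("circuit_label" %in% names(d)) as.character(d$circuit_label[1])
    else "fit"
  unit <- attr(d, "input_unit") %||% "uM"

  degenerate <- .flatData(y)

  # midpoint heuristic starting values
  mid <- (max(y) + min(y)) / 2
  Kd0 <- x[x > 0][which.min(abs(y[x > 0] - mid))]
  if (length(Kd0) == 0 || Kd0 <= 0) Kd0 <- stats::median(x[x > 0])
  if (repressor) {
    aM0 <- max(max(y) - min(y), max(y) / 10)
    a00 <- min(y) / aM0
    start <- list(Kd = Kd0, n = 1, aM = aM0, a0 = max(a00, 1e-6))
  } else {
    start <- list(Kd = Kd0, n = 1, bM = max(y),
      b0 = max(min(y) / max(y), 1e-6))
  }
  if (!is.null(init)) {
    if (repressor) {
      stopifnot(is(init, "HillRepressorParams"))
      start <- list(Kd = init@Kd, n = init@n, aM = init@alphaM,
        a0 = max(init@alpha0, 1e-8))
    } else {
      stopifnot(is(init, "HillActivatorParams"))
      start <- list(Kd = init@Kd, n = init@n, bM = init@betaM,
        b0 = max(init@beta0, 1e-8))
    }
  }

  eps <- 1e-8
  lower <- c(Kd = max(min(x[x > 0]) * 1e-3, eps), n = 0.1,
    amp = max(y) * 1e-4, frac = 1e-12)
  upper <- c(Kd = max(x) * 1e3, n = 10, amp = max(y) * 1e4, frac = 100)

  logy <- log(y)
  fitEnv <- list(x = x, logy = logy)
  form <- if (repressor)
    logy ~ log(aM * (1 - hillFraction(x, Kd, n) + a0))
  else
    logy ~ log(bM * (hillFraction(x, Kd, n) + b0))
  names(lower) <- names(upper) <- names(start)

  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = fitEnv, start = start, lower = lower,
      upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12)),
    error = function(e) e)

  if (inherits(fit, "error")) {
    params <- if (repressor)
      hillRepressor(start$Kd, start$n, start$aM, start$a0, label = label,
        inputUnit = unit)
    else
      hillActivator(start$Kd, start$n, start$bM, start$b0, label = label,
        inputUnit = unit)
    return(list(params = params,
      diagnostics = .fitDiagnostics(logy, rep(mean(logy), length(logy)),
        converged = FALSE, degenerate = degenerate,
        message = conditionMessage(fit))))
  }

  cf <- stats::coef(fit)
  params <- if (repressor)
    hillRepressor(cf[["Kd"]], cf[["n"]], cf[["aM"]], cf[["a0"]],
      label = label, inputUnit = unit)
  else
    hillActivator(cf[["Kd"]], cf[["n"]], cf[["bM"]], cf[["b0"]],
      label = label, inputUnit = unit)
  conv <- isTRUE(fit$convInfo$isConv) || fit$convInfo$stopCode %in% 1:4
  diag <- .fitDiagnostics(logy, as.numeric(stats::fitted(fit)),
    converged = conv, degenerate = degenerate)
  list(params = params, diagnostics = diag)
}

#' Relative parameter recovery error
#'
#' Largest absolute relative difference between two parameter objects of the
#' same class, over `(Kd, n, betaM, beta0)` or `(Kd, n, alphaM, alpha0)`.
#' Used by the fit round-trip checks.
#'
#' @param fitted,truth Hill parameter objects of the same class.
#' @return The maximum relative error.
#' @export
relativeParamError <- function(fitted, truth) {
  stopifnot(class(fitted) == class(truth))
  if (is(truth, "HillRepressorParams")) {
    f <- c(fitted@Kd, fitted@n, fitted@alphaM, fitted@alpha0)
    t <- c(truth@Kd, truth@n, truth@alphaM, truth@alpha0)
  } else {
    f <- c(fitted@Kd, fitted@n, fitted@betaM, fitted@beta0)
    t <- c(truth@Kd, truth@n, truth@betaM, truth@beta0)
  }
  max(abs(f - t) / abs(t))
}
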