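#' Dose-response tables
#'
#' A dose-response table holds replicated (input level, median fluorescence)
#' measurements for one circuit, the summarized form in which flow-cytometry
#' data enter transfer-function fitting. Tables are plain data frames with
#' columns `input_level`, `response`, `replicate`, `circuit_label`, carrying
#' optional metadata attributes (`input_unit`, `incubation_min`).
#'
#' @param input_level non-negative input levels (uM inducer or mCherry arb.
#'   units).
#' @param response median fluorescence responses (arb. units).
#' @param replicate replicate identifiers (recycled).
#' @param circuit_label circuit name (recycled).
#' @param input_unit unit of the input axis.
#' @param incubation_min incubation time in minutes (metadata only).
#' @return A `data.frame` of class `"DoseResponse"`.
#' @export
#' @examples
#' d <- doseResponse(c(0, 1, 3, 10, 30), c(900, 1500, 4000, 9000, 12000),
#'                   circuit_label = "example")
doseResponse <- function(input_level, response, replicate = 1L,
                         circuit_label = "circuit", input_unit = "uM",
                         incubation_min = 210) {
  if (any(input_level < 0)) stop("input levels must be non-negative")
  if (length(response) != length(input_level))
    stop("'input_level' and 'response' lengths differ")
  d <- data.frame(input_level = as.numeric(input_level),
    response = as.numeric(response),
    replicate = rep_len(replicate, length(input_level)),
    circuit_label = rep_len(as.character(circuit_label),
      length(input_level)))
  attr(d, "input_unit") <- input_unit
  attr(d, "incubation_min") <- incubation_min
  class(d) <- c("DoseResponse", "data.frame")
  d
}

.checkDoseResponse <- function(d, minLevels = 1L) {
  need <- c("input_level", "response")
  if (!all(need %in% names(d)))
    stop("dose-response table must have columns 'input_level' and 'response'")
  if (any(d$input_level < 0)) stop("input levels must be non-negative")
  nlev <- length(unique(d$input_level))
  if (nlev < minLevels)
    stop("at least ", minLevels, " distinct input levels required, got ", nlev)
  invisible(nlev)
}

#' Read and write dose-response tables
#'
#' Delimited-text (CSV) interface; required columns `input_level, response,
#' replicate, circuit_label` with a header row.
#'
#' @param d a dose-response `data.frame` (see [doseResponse()]).
#' @param path file path.
#' @return `readDoseResponse()` returns a `DoseResponse` data frame;
#'   `writeDoseResponse()` returns `path` invisibly.
#' @export
writeDoseResponse <- function(d, path) {
  utils::write.csv(as.data.frame(d)[, c("input_level", "response",
    "replicate", "circuit_label")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDoseResponse
#' @export
readDoseResponse <- function(path) {
  d <- tryCatch(utils::read.csv(path), error = function(e)
    stop("empty or unreadable dose-response file ", path, ": ",
      conditionMessage(e), call. = FALSE))
  if (nrow(d) == 0) stop("empty dose-response file: ", path)
  need <- c("input_level", "response", "replicate", "circuit_label")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("dose-response file ", path, " lacks column(s): ",
      paste(miss, collapse = ", "))
  doseResponse(d$input_level, d$response, d$replicate, d$circuit_label)
}

#' Simulate a dose-response experiment from known parameters
#'
#' Generates a replicated dilution-series table from a Hill parameter object,
#' optionally with multiplicative Gaussian measurement noise
#' (`response * (1 + N(0, cv))`), the error model used for fit round-trip
#' checks.
#'
#' @param p a Hill parameter object (activator or repressor).
#' @param inputLevels input levels; default a 14-point 3-fold dilution series
#'   from `Kd/243` to `6561 Kd` plus a zero-dose point. The wide default
#'   brackets both plateaus even for shallow Hill coefficients (n near 0.35),
#'   without which `Kd` and the amplitude are barely identifiable from noisy
#'   data.
#' @param replicates number of replicates per level. The default 32 is sized
#'   from the Cramer-Rao bound so that, at 5% noise, three standard errors of
#'   the worst-identified parameter (the dissociation constant of the
#'   shallowest sender promoter, n = 0.352) stay within a 15% relative
#'   error band; real assays with a handful of replicates cannot pin such a
#'   Kd this tightly.
#' @param cv coefficient of variation of the multiplicative noise (0 =
#'   noiseless).
#' @param seed RNG seed used when `cv > 0`.
#' @return A `DoseResponse` data frame.
#' @export
#' @examples
#' d <- simulateDoseResponse(registryRow("R_PF"))
simulateDoseResponse <- function(p, inputLevels = NULL, replicates = 32L,
                                 cv = 0, seed = 1L) {
  stopifnot(is(p, "HillParams"))
  if (is.null(inputLevels))
    inputLevels <- c(0, p@Kd * 3^(-5:8))
  f <- if (is(p, "HillRepressorParams")) evalRepressor else evalActivator
  x <- rep(inputLevels, each = replicates)
  y <- f(p, x)
  if (cv > 0)
    y <- withSeed(seed, y * (1 + stats::rnorm(length(y), 0, cv)))
  y <- pmax(y, .Machine$double.eps)
  doseResponse(x, y, replicate = rep(seq_len(replicates),
    times = length(inputLevels)), circuit_label = p@label,
    input_unit = p@inputUnit)
}
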