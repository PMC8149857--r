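# Printed parameter rows for the eight characterized circuits: receiver
# positive-feedback and open-loop topologies, four mutated P_lux activator
# senders, the P_lux repressor sender, and the receiver activation function
# on the sender-mCherry axis.
.registryTable <- list(
  R_PF       = list(model = "activator", Kd = 0.28,  n = 1.97,
                    betaM = 2.25e4, beta0 = 3.95e-2, inputUnit = "uM"),
  R_OL       = list(model = "activator", Kd = 3.41,  n = 0.809,
                    betaM = 2.57e4, beta0 = 7.23e-3, inputUnit = "uM"),
  S_mut40    = list(model = "activator", Kd = 15,    n = 0.352,
                    betaM = 5521,   beta0 = 4.95e-3, inputUnit = "uM"),
  S_mut7     = list(model = "activator", Kd = 50,    n = 0.482,
                    betaM = 1906,   beta0 = 9.1e-2,  inputUnit = "uM"),
  S_mut8     = list(model = "activator", Kd = 50,    n = 0.54,
                    betaM = 729,    beta0 = 1.91e-1, inputUnit = "uM"),
  S_mut15    = list(model = "activator", Kd = 50,    n = 0.426,
                    betaM = 2679,   beta0 = 4.45e-2, inputUnit = "uM"),
  S_plux_rep = list(model = "repressor", Kd = 0.252, n = 0.669,
                    alphaM = 735,   alpha0 = 3.41e-1, inputUnit = "uM"),
  R_mCh      = list(model = "activator", Kd = 1103,  n = 2.33,
                    betaM = 2.16e4, beta0 = 1.95e-2,
                    inputUnit = "mCherry arb. units")
)

.rowToParams <- function(label, row) {
  if (identical(row$model, "repressor"))
    hillRepressor(row$Kd, row$n, row$alphaM, row$alpha0, label = label,
      inputUnit = row$inputUnit)
  else
    hillActivator(row$Kd, row$n, row$betaM, row$beta0, label = label,
      inputUnit = row$inputUnit)
}

#' Registry of fitted transfer-function parameters
#'
#' `defaultRegistry()` returns the named list of Hill parameter objects for
#' the eight characterized circuits: the receiver positive-feedback (`R_PF`)
#' and open-loop (`R_OL`) topologies, the four mutated P_lux activator senders
#' (`S_mut40`, `S_mut7`, `S_mut8`, `S_mut15`), the P_lux repressor sender
#' (`S_plux_rep`), and the receiver activation function on the sender-mCherry
#' axis (`R_mCh`). `registryRow()` retrieves a single entry by label.
#'
#' @param label registry row name.
#' @param registry a registry list; defaults to [defaultRegistry()].
#' @return `defaultRegistry()`: a named list of
#'   [`HillActivatorParams`][HillParams-classes] /
#'   [`HillRepressorParams`][HillParams-classes]; `registryRow()`: one such
#'   object.
#' @export
#' @examples
#' names(defaultRegistry())
#' registryRow("R_mCh")
defaultRegistry <- function() {
  mapply(.rowToParams, names(.registryTable), .registryTable,
    SIMPLIFY = FALSE)
}

#' @rdname defaultRegistry
#' @export
registryRow <- function(label, registry = defaultRegistry()) {
  if (!label %in% names(registry))
    stop("unknown registry row '", label, "'; available: ",
      paste(names(registry), collapse = ", "))
  registry[[label]]
}

#' Read and write parameter registries
#'
#' Registries are stored as JSON objects keyed by row label, each entry with
#' fields `model` (`"activator"` or `"repressor"`), `Kd`, `n`,
#' `betaM`/`alphaM`, `beta0`/`alpha0`, and `input_unit`.
#'
#' @param registry named list of Hill parameter objects.
#' @param path file path.
#' @return `readParamRegistry()` returns a named list of parameter objects;
#'   `writeParamRegistry()` returns `path` invisibly.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".json")
#' writeParamRegistry(defaultRegistry(), tf)
#' reg <- readParamRegistry(tf)
#' reg$R_PF
writeParamRegistry <- function(registry, path) {
  enc <- lapply(registry, function(p) {
    if (is(p, "HillRepressorParams"))
      list(model = "repressor", Kd = p@Kd, n = p@n, alphaM = p@alphaM,
        alpha0 = p@alpha0, input_unit = p@inputUnit)
    else
      list(model = "activator", Kd = p@Kd, n = p@n, betaM = p@betaM,
        beta0 = p@beta0, input_unit = p@inputUnit)
  })
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(path)
}

#' @rdname writeParamRegistry
#' @export
readParamRegistry <- function(path) {
  raw <- jsonlite::read_json(path)
  out <- lapply(names(raw), function(label) {
    row <- raw[[label]]
    if (identical(row$model, "repressor"))
      hillRepressor(row$Kd, row$n, row$alphaM, row$alpha0, label = label,
        inputUnit = row$input_unit %||% "uM")
    else
      hillActivator(row$Kd, row$n, row$betaM, row$beta0, label = label,
        inputUnit = row$input_unit %||% "uM")
  })
  names(out) <- names(raw)
  out
}
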