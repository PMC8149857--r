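# JSON network configuration and CSV response-matrix output.

#' Read and write consortium network configurations
#'
#' Networks are stored as JSON: a list of senders (label, sign, weight value,
#' optional registry reference or inline parameters, induction level), a
#' receiver (registry reference or inline parameters), the bit-0 policy and
#' the weight-noise model.
#'
#' @param net a [`ConsortiumNetwork`][ConsortiumNetwork-class].
#' @param path file path.
#' @param registry registry used to resolve `registry_ref` entries; default
#'   [defaultRegistry()].
#' @return `readNetworkConfig()` returns a `ConsortiumNetwork`;
#'   `writeNetworkConfig()` returns `path` invisibly.
#' @export
writeNetworkConfig <- function(net, path) {
  enc <- list(
    senders = lapply(net@senders, function(s) {
      out <- list(label = s@label, sign = s@sign,
        weight_value = s@weightValue, induction_level = s@inductionLevel)
      if (!is.null(s@params)) out$registry_ref <- s@params@label
      out
    }),
    receiver = list(registry_ref = net@receiver@label),
    bit_zero_policy = net@bitZeroPolicy,
    noise = list(cv = net@noiseCV, seed = net@noiseSeed))
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(path)
}

#' @rdname writeNetworkConfig
#' @export
readNetworkConfig <- function(path, registry = defaultRegistry()) {
  raw <- jsonlite::read_json(path)
  senders <- lapply(raw$senders, function(s) {
    params <- if (!is.null(s$registry_ref))
      registryRow(s$registry_ref, registry) else NULL
    senderSpec(s$label, params = params, sign = s$sign,
      inductionLevel = s$induction_level %||% 33,
      weightValue = s$weight_value)
  })
  receiver <- registryRow(raw$receiver$registry_ref, registry)
  consortiumNetwork(senders = senders, receiver = receiver,
    bitZeroPolicy = raw$bit_zero_policy %||% "zero",
    noiseCV = raw$noise$cv %||% 0, noiseSeed = raw$noise$seed %||% 1L)
}

#' Write a response matrix to CSV
#'
#' Writes two CSV files, one with simulated receiver EYFP and one with the
#' underlying weighted sums: rows are weight vectors, columns pattern ids.
#' Values are written at full double precision.
#'
#' @param m a [`ResponseMatrix`][ResponseMatrix-class].
#' @param eyfpPath,sumsPath output paths (either may be `NULL` to skip).
#' @return Invisibly, the written paths.
#' @export
writeResponseMatrix <- function(m, eyfpPath = NULL, sumsPath = NULL) {
  stopifnot(is(m, "ResponseMatrix"))
  fmt <- function(mat) {
    d <- as.data.frame(format(mat, digits = 17, trim = TRUE,
      scientific = FALSE))
    names(d) <- m@patternIds
    cbind(data.frame(weight_vector = paste0("w", seq_len(nrow(mat)) - 1L)),
      d)
  }
  if (!is.null(eyfpPath))
    utils::write.csv(fmt(m@eyfp), eyfpPath, row.names = FALSE)
  if (!is.null(sumsPath))
    utils::write.csv(fmt(m@sums), sumsPath, row.names = FALSE)
  invisible(c(eyfpPath, sumsPath))
}
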