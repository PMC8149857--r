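# Plain-text pattern-set interchange: CSV (category, noise_index, bit_0..)
# and a JSON form that also carries provenance (kind, seed, scaling vector).

#' Read and write pattern sets
#'
#' CSV files have columns `category`, `noise_index` and `bit_0` ..
#' `bit_{nBits-1}` (row-major bit order, `noise_index = -1` marking clean
#' patterns, 1-based flip positions otherwise). The JSON form additionally
#' stores the provenance block, so graded sets round-trip with their shared
#' scaling vector.
#'
#' @param s a [`PatternSet`][PatternSet-class].
#' @param path file path; `format` is inferred from the extension when
#'   `"auto"`.
#' @param format `"csv"`, `"json"`, or `"auto"`.
#' @return `readPatternSet()` returns a `PatternSet`; `writePatternSet()`
#'   returns `path` invisibly.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writePatternSet(makePatternSet(3), tf)
#' nPatterns(readPatternSet(tf))  # 30
writePatternSet <- function(s, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else
      "csv"
  if (format == "csv") {
    d <- data.frame(category = s@category, noise_index = s@noiseIndex)
    bits <- as.data.frame(s@values)
    names(bits) <- paste0("bit_", seq_len(s@nBits) - 1L)
    utils::write.csv(cbind(d, bits), path, row.names = FALSE)
  } else {
    jsonlite::write_json(list(
      grid_size = s@gridSize, n_bits = s@nBits, category = s@category,
      noise_index = s@noiseIndex, values = s@values,
      provenance = s@provenance), path, auto_unbox = TRUE, digits = NA,
      pretty = TRUE, na = "null")
  }
  invisible(path)
}

#' @rdname writePatternSet
#' @export
readPatternSet <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else
      "csv"
  if (format == "csv") {
    d <- utils::read.csv(path)
    bitCols <- grep("^bit_", names(d), value = TRUE)
    bitCols <- bitCols[order(as.integer(sub("^bit_", "", bitCols)))]
    vals <- as.matrix(d[, bitCols, drop = FALSE])
    dimnames(vals) <- NULL
    nb <- ncol(vals)
    gs <- as.integer(round(sqrt(nb)))
    if (gs * gs != nb) gs <- NA_integer_
    new("PatternSet", gridSize = gs, nBits = as.integer(nb), values = vals,
      category = as.character(d$category),
      noiseIndex = as.integer(d$noise_index),
      provenance = list(kind = if (all(vals %in% c(0, 1))) "binary" else
        "graded"))
  } else {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    vals <- matrix(as.numeric(raw$values), nrow = length(raw$category))
    prov <- as.list(raw$provenance)
    new("PatternSet",
      gridSize = if (is.null(raw$grid_size) || is.na(raw$grid_size))
        NA_integer_ else as.integer(raw$grid_size),
      nBits = as.integer(raw$n_bits), values = vals,
      category = as.character(raw$category),
      noiseIndex = as.integer(raw$noise_index), provenance = prov)
  }
}
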