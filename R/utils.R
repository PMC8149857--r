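`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards so library code never perturbs user draws.
withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage-specific seed
#'
#' Forks one run-level seed into independent per-stage seeds so that adding a
#' pipeline stage does not perturb the draws of earlier stages. The derived
#' seed is a deterministic function of the base seed and the stage name, kept
#' within the 32-bit integer range.
#'
#' @param seed integer base seed.
#' @param stage character stage name.
#' @return An integer seed.
#' @export
#' @examples
#' stageSeed(1, "patterns")
stageSeed <- function(seed, stage) {
  stopifnot(length(seed) == 1L, is.finite(seed), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 2654435 + h * 97 + 11) %% 2147483647)
}

# Provenance block stamped into every written artifact. Deliberately free of
# timestamps so that equal seeds give byte-identical bundles.
provenanceBlock <- function(seed, extra = list()) {
  c(list(package = "qsperceptron",
         version = as.character(utils::packageVersion("qsperceptron")),
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
    extra)
}
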