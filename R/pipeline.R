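# End-to-end workflow stages behind the command-line interface: fitting from
# dose-response files, the patterns -> train -> simulate -> evaluate
# pipeline, and the deterministic fixture generator.

#' Fit a transfer function from a dose-response file
#'
#' Reads a dose-response CSV, fits the requested Hill model, and optionally
#' writes the result as a one-row parameter registry (JSON).
#'
#' @param path dose-response CSV path (columns `input_level, response,
#'   replicate, circuit_label`).
#' @param model `"activator"` or `"repressor"`.
#' @param out optional output registry path.
#' @param label registry row label; defaults to the file's circuit label.
#' @return The fit list from [fitActivator()] / [fitRepressor()], invisibly
#'   when `out` is given.
#' @export
cmdFit <- function(path, model = c("activator", "repressor"), out = NULL,
                   label = NULL) {
  model <- match.arg(model)
  d <- readDoseResponse(path)
  fit <- tryCatch(
    if (model == "repressor") fitRepressor(d) else fitActivator(d),
    error = function(e) stop("fitting ", path, " failed: ",
      conditionMessage(e), call. = FALSE))
  if (!is.null(label)) fit$params@label <- label
  if (!is.null(out)) {
    reg <- stats::setNames(list(fit$params), fit$params@label)
    writeParamRegistry(reg, out)
    return(invisible(fit))
  }
  fit
}

#' Run the full pattern-classification pipeline
#'
#' Generates the pattern set for a grid size (optionally graded), trains one
#' weight vector per category, simulates the response grid, and evaluates
#' margins, misclassification and product degeneracy. All randomness is
#' forked from `seed` by stage name, so adding a stage does not perturb
#' earlier stages' draws; when `outDir` is given, every artifact is written
#' with a provenance block (package version, seed, configuration).
#'
#' @param N odd grid side length.
#' @param seed integer run seed.
#' @param graded apply the shared graded scaling ([makeNonbinary()]).
#' @param cfg a [`TrainingConfig`][TrainingConfig-class]; its seed is
#'   overridden by the forked stage seed.
#' @param receiver receiver activation parameters.
#' @param outDir optional output directory for the report bundle.
#' @return A list of class `"PipelineResult"`: `patterns`, `training`
#'   (a `"MulticlassResult"`), `report` (an `"EvaluationReport"`), `seed`,
#'   and `files` (written paths, if any).
#' @export
#' @examples
#' \donttest{
#' res <- runPipeline(3, seed = 1,
#'                    cfg = trainingConfig(maxIter = 300))
#' res$report
#' }
runPipeline <- function(N, seed = 1L, graded = FALSE,
                        cfg = trainingConfig(),
                        receiver = registryRow("R_mCh"), outDir = NULL) {
  ps <- makePatternSet(N)
  if (graded)
    ps <- makeNonbinary(ps, seed = stageSeed(seed, "grading"))
  cfg@seed <- stageSeed(seed, "training")
  tg <- makeTargets(ps, receiver)
  tr <- trainMulticlass(ps, cfg, receiver, tg)
  report <- evaluationReport(tr$responseMatrix, ps, tg)
  files <- character(0)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    pFile <- file.path(outDir, sprintf("patterns_%dx%d.csv", N, N))
    writePatternSet(ps, pFile)
    mFiles <- file.path(outDir, sprintf(c("responses_%dx%d.csv",
      "weighted_sums_%dx%d.csv"), N, N))
    writeResponseMatrix(tr$responseMatrix, mFiles[1], mFiles[2])
    wFile <- file.path(outDir, sprintf("weights_%dx%d.csv", N, N))
    W <- tr$responseMatrix@weights
    utils::write.csv(data.frame(category = names(tr$results),
      W, check.names = FALSE), wFile, row.names = FALSE)
    tFile <- file.path(outDir, sprintf("trajectory_%dx%d.csv", N, N))
    traj <- lapply(names(tr$results), function(cc)
      data.frame(category = cc,
        iteration = seq_along(tr$results[[cc]]@lossTrajectory) - 1L,
        loss = tr$results[[cc]]@lossTrajectory))
    utils::write.csv(do.call(rbind, traj), tFile, row.names = FALSE)
    rFile <- file.path(outDir, sprintf("report_%dx%d.json", N, N))
    jsonlite::write_json(list(
      provenance = provenanceBlock(seed, list(grid_size = N,
        graded = graded, eta = cfg@eta, palette = cfg@palette,
        mode = cfg@mode)),
      margins = as.list(report$margins),
      misclassified = as.list(report$misclassified),
      threshold = report$threshold,
      unique_products = report$uniqueProducts$count,
      sparseness = report$sparseness), rFile, auto_unbox = TRUE,
      digits = NA, pretty = TRUE)
    files <- c(pFile, mFiles, wFile, tFile, rFile)
  }
  structure(list(patterns = ps, training = tr, report = report,
    seed = as.integer(seed), files = files), class = "PipelineResult")
}

#' @export
print.PipelineResult <- function(x, ...) {
  cat(sprintf("Pipeline result (%dx%d, seed %d)\n", gridSize(x$patterns),
    gridSize(x$patterns), x$seed))
  print(x$report)
  invisible(x)
}

#' Generate the synthetic fixture bundle
#'
#' Writes a deterministic set of plain-text fixtures: a noiseless and a
#' 5%-noise dose-response table for every registry row, the default binary
#' pattern sets (3x3 and the 4-bit enumeration), the default parameter
#' registry, and a small linearly separable two-bit dichotomy (patterns +
#' targets) for trainer smoke checks.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed controlling the noisy tables.
#' @return Invisibly, the named character vector of written paths.
#' @export
makeFixtures <- function(dir, seed = 0L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  for (label in names(defaultRegistry())) {
    p <- registryRow(label)
    clean <- simulateDoseResponse(p)
    noisy <- simulateDoseResponse(p, cv = 0.05,
      seed = stageSeed(seed, paste0("noise_", label)))
    f1 <- file.path(dir, paste0("dose_response_", label, ".csv"))
    f2 <- file.path(dir, paste0("dose_response_", label, "_noisy.csv"))
    writeDoseResponse(clean, f1)
    writeDoseResponse(noisy, f2)
    paths <- c(paths, f1, f2)
  }
  regFile <- file.path(dir, "registry.json")
  writeParamRegistry(defaultRegistry(), regFile)
  p3 <- file.path(dir, "patterns_3x3.csv")
  writePatternSet(makePatternSet(3), p3)
  p4 <- file.path(dir, "patterns_4bit.csv")
  writePatternSet(enumerate4bit(), p4)
  # linearly separable AND-style dichotomy: only [1,1] should activate
  toy <- new("PatternSet", gridSize = NA_integer_, nBits = 2L,
    values = matrix(c(0, 0, 0, 1, 1, 0, 1, 1), 4, 2, byrow = TRUE),
    category = c("low", "low", "low", "high"),
    noiseIndex = rep(-1L, 4L), provenance = list(kind = "binary",
      dichotomy = "AND"))
  toyFile <- file.path(dir, "toy_dichotomy.csv")
  writePatternSet(toy, toyFile)
  paths <- c(paths, regFile, p3, p4, toyFile)
  jsonlite::write_json(provenanceBlock(seed), file.path(dir,
    "provenance.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, file.path(dir, "provenance.json")))
}
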