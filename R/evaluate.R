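# Evaluation reports: margins, misclassification, product degeneracy, and
# the sparseness summary, all recomputable from a stored response grid.

#' Per-category classification margins from a response grid
#'
#' For weight vector `i` (assumed trained for category `i`), the margin is
#' the smallest response over its own category's patterns minus the largest
#' response over all other patterns; positive margins mean every own-category
#' pattern outscores every foreign pattern.
#'
#' @param m a [`ResponseMatrix`][ResponseMatrix-class] whose rows correspond
#'   one-to-one to `categories`.
#' @param patternCategories per-pattern category labels (columns of `m`).
#' @param categories category of each weight-vector row; defaults to the
#'   unique pattern categories in order.
#' @return Named numeric vector of margins.
#' @export
classificationMargins <- function(m, patternCategories,
                                  categories = unique(patternCategories)) {
  stopifnot(is(m, "ResponseMatrix"),
    nrow(m@eyfp) == length(categories),
    ncol(m@eyfp) == length(patternCategories))
  out <- vapply(seq_along(categories), function(i) {
    own <- patternCategories == categories[i]
    min(m@eyfp[i, own]) - max(m@eyfp[i, !own])
  }, numeric(1))
  names(out) <- categories
  out
}

#' Evaluation report for a trained pattern classifier
#'
#' Summarizes a response grid against its targets: per-category margins,
#' misclassification counts at the midpoint threshold between the H and L
#' levels, the distinct weighted-sum count, and the clean-pattern sparseness
#' table. Every entry is a pure function of the stored response matrix and
#' targets, so re-evaluating a saved matrix reproduces the report.
#'
#' @param m a [`ResponseMatrix`][ResponseMatrix-class] (one row per
#'   category).
#' @param s the [`PatternSet`][PatternSet-class] the responses were computed
#'   on.
#' @param targetSpec a `"TargetSpec"` (see [makeTargets()]).
#' @param tolerance tolerance for [countUniqueProducts()].
#' @return A list of class `"EvaluationReport"`: `margins`,
#'   `misclassified` (per category), `threshold`, `uniqueProducts`,
#'   `sparseness`.
#' @export
evaluationReport <- function(m, s, targetSpec, tolerance = NULL) {
  stopifnot(is(m, "ResponseMatrix"), is(s, "PatternSet"))
  cats <- targetSpec$categories
  margins <- classificationMargins(m, s@category, cats)
  thr <- (targetSpec$H + targetSpec$L) / 2
  mis <- vapply(seq_along(cats), function(i) {
    own <- s@category == cats[i]
    sum((m@eyfp[i, ] > thr) != own)
  }, numeric(1))
  names(mis) <- cats
  up <- countUniqueProducts(m, tolerance)
  sp <- if (!is.na(s@gridSize)) sparsenessTable(s@gridSize) else NULL
  structure(list(margins = margins, misclassified = mis, threshold = thr,
    uniqueProducts = up, sparseness = sp), class = "EvaluationReport")
}

#' @export
print.EvaluationReport <- function(x, ...) {
  cat("Evaluation report\n")
  cat("  margins:", paste(sprintf("%s = %.4g", names(x$margins),
    x$margins), collapse = ", "), "\n")
  cat("  misclassified (threshold", format(x$threshold, digits = 6), "):",
    paste(sprintf("%s = %d", names(x$misclassified),
      as.integer(x$misclassified)), collapse = ", "), "\n")
  cat("  distinct weighted-sum products:", x$uniqueProducts$count, "\n")
  if (!is.null(x$sparseness))
    cat(sprintf("  clean-pattern sparseness: %d/%d = %.2f\n",
      x$sparseness$zero_bits, x$sparseness$total_bits,
      x$sparseness$sparseness))
  invisible(x)
}
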