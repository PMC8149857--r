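# Pattern-set generation: category-labelled N x N grids (clean plus
# single-bit-flip noisy variants), the 4-bit enumeration, and graded
# (non-binary) variants sharing one per-size scaling vector.

.rotCW <- function(m) t(m[nrow(m):1, , drop = FALSE])
.rotCCW <- function(m) t(m)[ncol(m):1, , drop = FALSE]

#' Default clean bitmap for a grid size
#'
#' The exact pixel layouts of the published pattern figures are not
#' recoverable from text, so the package ships configurable stand-in glyphs
#' constrained to the published zero-bit counts: 3/9 zeros at N = 3 and
#' `(N-1)^2` zeros (16/25, 36/49, 64/81) for N = 5, 7, 9. The base glyph is
#' mirror-symmetric about the vertical axis and not symmetric under 180-degree
#' rotation; the `"v"` and `"n"` category bitmaps are its 90-degree
#' counter-clockwise and clockwise rotations, so all three categories share
#' the same bit counts. For N >= 5 the base glyph is a T shape (full top row
#' plus centre column, `2N - 1` ones).
#'
#' @param N odd grid side length (3, 5, 7, 9, or any odd value >= 5).
#' @return An `N x N` 0/1 matrix.
#' @export
#' @examples
#' defaultBitmap(3)
defaultBitmap <- function(N) {
  N <- as.integer(N)
  if (is.na(N) || N < 3L || N %% 2L == 0L)
    stop("grid size must be an odd integer >= 3")
  if (N == 3L) {
    matrix(c(0, 1, 0,
             1, 1, 1,
             1, 0, 1), 3L, 3L, byrow = TRUE)
  } else {
    m <- matrix(0, N, N)
    m[1L, ] <- 1
    m[, (N + 1L) %/% 2L] <- 1
    m
  }
}

.categoryBitmap <- function(category, base) {
  switch(category,
    z = base,
    v = .rotCCW(base),
    n = .rotCW(base),
    stop("unknown pattern category '", category,
      "'; expected one of z, v, n"))
}

#' Clean (ideal) pattern for a category
#'
#' Returns the noiseless bitmap for one category, flattened row-major. The
#' `"v"` and `"n"` bitmaps are fixed rotations of the `"z"` bitmap (see
#' [defaultBitmap()]), so all categories have identical bit counts.
#'
#' @param category `"z"`, `"v"`, or `"n"`.
#' @param N odd grid side length.
#' @param base optional custom base (`"z"`) bitmap, an `N x N` 0/1 matrix.
#' @return A [`Pattern`][Pattern-class] with `noiseIndex = -1`.
#' @export
#' @examples
#' sum(patternValues(makeCleanPattern("z", 3)) == 0)  # 3 zero bits
makeCleanPattern <- function(category, N, base = NULL) {
  N <- as.integer(N)
  if (is.null(base)) base <- defaultBitmap(N)
  stopifnot(is.matrix(base), nrow(base) == N, ncol(base) == N,
    all(base %in% c(0, 1)))
  m <- .categoryBitmap(category, base)
  new("Pattern", category = category, gridSize = N,
    values = as.numeric(t(m)), noiseIndex = -1L)
}

#' Single-bit-flip noisy variants of a clean pattern
#'
#' Produces the `N^2` noisy patterns obtained by flipping each bit of the
#' clean pattern in turn (raster order). Every noisy pattern is at Hamming
#' distance exactly 1 from its clean parent.
#'
#' @param clean a binary [`Pattern`][Pattern-class] with `noiseIndex = -1`.
#' @return A list of `length(patternValues(clean))` patterns; element `k`
#'   flips bit `k`.
#' @export
expandNoisy <- function(clean) {
  stopifnot(is(clean, "Pattern"))
  v <- clean@values
  if (!all(v %in% c(0, 1)))
    stop("noisy expansion requires a binary pattern")
  if (clean@noiseIndex != -1L)
    stop("noisy expansion requires the clean (noiseIndex = -1) pattern")
  lapply(seq_along(v), function(k) {
    p <- v
    p[k] <- 1 - p[k]
    new("Pattern", category = clean@category, gridSize = clean@gridSize,
      values = p, noiseIndex = as.integer(k))
  })
}

#' Build a category-major pattern set
#'
#' For each category, the clean pattern is followed by its `N^2` single-bit
#' flips in raster order, giving `(1 + N^2) * length(categories)` patterns in
#' total: 30 at N = 3, 78 at N = 5, 150 at N = 7, 246 at N = 9 for the
#' three-category sets.
#'
#' @param N odd grid side length.
#' @param categories category labels to include (subset of `c("z","v","n")`).
#' @param base optional custom base bitmap passed to [makeCleanPattern()].
#' @return A binary [`PatternSet`][PatternSet-class].
#' @export
#' @examples
#' nPatterns(makePatternSet(3))  # 30
makePatternSet <- function(N, categories = c("z", "v", "n"), base = NULL) {
  N <- as.integer(N)
  pats <- unlist(lapply(categories, function(cc) {
    clean <- makeCleanPattern(cc, N, base = base)
    c(list(clean), expandNoisy(clean))
  }), recursive = FALSE)
  new("PatternSet", gridSize = N, nBits = N * N,
    values = do.call(rbind, lapply(pats, function(p) p@values)),
    category = vapply(pats, function(p) p@category, character(1)),
    noiseIndex = vapply(pats, function(p) p@noiseIndex, integer(1)),
    provenance = list(kind = "binary", categories = categories))
}

#' Graded (non-binary) variant of a binary pattern set
#'
#' Emulates randomized OC6 inputs: draws one scaling vector `u` of length
#' `nBits` with entries uniform in `[low, high]` and multiplies every
#' pattern elementwise by the same `u`. Zero bits stay zero; the seed and the
#' drawn vector are recorded in the provenance.
#'
#' @param s a binary [`PatternSet`][PatternSet-class].
#' @param low,high scaling bounds; `low` must be positive and `high` at most
#'   1.
#' @param seed RNG seed for the single shared draw.
#' @return A graded `PatternSet` of the same shape and ordering.
#' @export
#' @examples
#' g <- makeNonbinary(makePatternSet(3), seed = 7)
#' length(provenance(g)$scaling)  # 9, shared by all 30 patterns
makeNonbinary <- function(s, low = 0.5, high = 1.0, seed = 1L) {
  stopifnot(is(s, "PatternSet"))
  if (low <= 0) stop("'low' must be positive")
  if (high > 1) stop("'high' must not exceed 1 (values must stay in [0, 1])")
  if (low > high) stop("'low' must not exceed 'high'")
  if (!all(s@values %in% c(0, 1)))
    stop("graded scaling requires a binary pattern set")
  u <- withSeed(seed, stats::runif(s@nBits, low, high))
  new("PatternSet", gridSize = s@gridSize, nBits = s@nBits,
    values = sweep(s@values, 2L, u, `*`), category = s@category,
    noiseIndex = s@noiseIndex,
    provenance = list(kind = "graded", seed = as.integer(seed),
      low = low, high = high, scaling = u,
      categories = s@provenance$categories))
}

#' All sixteen 4-bit binary patterns
#'
#' Enumerates the 16 binary 4-vectors in lexicographic order (bit 1 most
#' significant), the input space of the 4-bit classification experiment.
#'
#' @return A flat [`PatternSet`][PatternSet-class] of 16 patterns, category
#'   `"free"`.
#' @export
#' @examples
#' patternValues(enumerate4bit())[1, ]  # 0 0 0 0
enumerate4bit <- function() {
  g <- as.matrix(expand.grid(b4 = 0:1, b3 = 0:1, b2 = 0:1, b1 = 0:1))
  vals <- unname(g[, 4:1, drop = FALSE])
  colnames(vals) <- NULL
  new("PatternSet", gridSize = NA_integer_, nBits = 4L, values = vals,
    category = rep("free", 16L), noiseIndex = rep(-1L, 16L),
    provenance = list(kind = "binary", enumeration = "4bit"))
}

#' Threshold partition of patterns by weighted product
#'
#' Computes the dot product `d = w . x` for every pattern and partitions the
#' set: `d > upper` into `set1`, `d < lower` into `set0`, and the remainder
#' (including products equal to either threshold) into the boundary group.
#' The partition is exhaustive and disjoint and does not depend on pattern
#' order.
#'
#' @param s a [`PatternSet`][PatternSet-class].
#' @param w weight vector of length `nBits(s)`.
#' @param lower,upper decision thresholds, `lower <= upper`.
#' @return A list with integer index vectors `set0`, `set1`, `boundary` and
#'   the numeric vector `products`.
#' @export
#' @examples
#' sel <- selectSeparable(enumerate4bit(), c(450, 3500, 900, 3500),
#'                        4000, 4500)
#' sel$products[13]  # pattern [1,1,0,0] etc.
selectSeparable <- function(s, w, lower, upper) {
  stopifnot(is(s, "PatternSet"))
  if (length(w) != nBits(s))
    stop("weight vector length ", length(w), " does not match pattern size ",
      nBits(s))
  if (lower > upper) stop("'lower' must not exceed 'upper'")
  d <- as.numeric(s@values %*% w)
  list(set0 = which(d < lower), set1 = which(d > upper),
    boundary = which(d >= lower & d <= upper), products = d)
}

#' Sparseness of the default clean patterns
#'
#' Fraction of zero bits in the default clean bitmap for each requested grid
#' size (identical across categories, which are rotations of one glyph).
#'
#' @param sizes odd grid side lengths.
#' @return A data frame with columns `grid_size`, `zero_bits`, `total_bits`,
#'   `sparseness`.
#' @export
#' @examples
#' sparsenessTable()
sparsenessTable <- function(sizes = c(3L, 5L, 7L, 9L)) {
  rows <- lapply(sizes, function(N) {
    b <- defaultBitmap(N)
    data.frame(grid_size = N, zero_bits = sum(b == 0), total_bits = N^2,
      sparseness = sum(b == 0) / N^2)
  })
  do.call(rbind, rows)
}
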