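# Pattern-set generation: counts, sparseness, single-bit-flip noise,
# graded scaling, the 4-bit enumeration and threshold partitioning.

test_that("clean patterns have the configured zero-bit counts", {
  zeros <- c(`3` = 3L, `5` = 16L, `7` = 36L, `9` = 64L)
  for (N in c(3L, 5L, 7L, 9L)) {
    for (cc in c("z", "v", "n")) {
      p <- makeCleanPattern(cc, N)
      expect_identical(sum(patternValues(p) == 0), zeros[[as.character(N)]],
        label = sprintf("%s at N=%d", cc, N))
    }
  }
  expect_error(makeCleanPattern("q", 3), "unknown pattern category")
  expect_error(defaultBitmap(4), "odd integer")
})

test_that("category bitmaps are rotations of one glyph: equal value multisets,
           different arrangements, well separated", {
  for (N in c(3L, 5L)) {
    z <- patternValues(makeCleanPattern("z", N))
    v <- patternValues(makeCleanPattern("v", N))
    n <- patternValues(makeCleanPattern("n", N))
    expect_equal(sort(z), sort(v))
    expect_equal(sort(z), sort(n))
    expect_false(identical(z, v))
    expect_false(identical(v, n))
    # flip-1 noise balls around the cleans must not intersect
    expect_gte(sum(z != v), 3)
    expect_gte(sum(z != n), 3)
    expect_gte(sum(v != n), 3)
  }
})

test_that("noisy expansion flips exactly one bit per pattern", {
  for (N in c(3L, 5L)) {
    clean <- makeCleanPattern("z", N)
    noisy <- expandNoisy(clean)
    expect_length(noisy, N^2)
    vals <- do.call(rbind, lapply(noisy, patternValues))
    # Hamming distance exactly one, flip position k for pattern k
    for (k in seq_len(N^2)) {
      expect_identical(sum(vals[k, ] != patternValues(clean)), 1L)
      expect_equal(vals[k, k], 1 - patternValues(clean)[k])
      expect_identical(noiseIndex(noisy[[k]]), k)
    }
    # all noisy patterns distinct
    expect_identical(nrow(unique(vals)), N * N)
    # flipping the same bit again restores the original
    refl <- expandNoisy(new("Pattern", category = "z", gridSize = N,
      values = vals[1, ], noiseIndex = -1L))
    expect_equal(patternValues(refl[[1]]), patternValues(clean))
  }
  graded <- makeNonbinary(makePatternSet(3), seed = 1)
  expect_error(expandNoisy(getPattern(graded, 1)), "binary")
})

test_that("pattern sets have the published cardinalities and ordering", {
  counts <- c(`3` = 30L, `5` = 78L, `7` = 150L, `9` = 246L)
  for (N in c(3L, 5L, 7L, 9L)) {
    ps <- makePatternSet(N)
    expect_identical(nPatterns(ps), counts[[as.character(N)]])
    # category-major ordering, clean first then flips in raster order
    expect_identical(patternCategory(ps),
      rep(c("z", "v", "n"), each = 1L + N^2))
    expect_identical(noiseIndex(ps), rep(c(-1L, seq_len(N^2)), times = 3L))
  }
  expect_identical(nPatterns(makePatternSet(5, categories = "z")), 26L)
})

test_that("graded sets share one scaling vector drawn once per set", {
  ps <- makePatternSet(5)
  g1 <- makeNonbinary(ps, seed = 42)
  g2 <- makeNonbinary(ps, seed = 42)
  expect_identical(patternValues(g1), patternValues(g2))
  u <- provenance(g1)$scaling
  expect_length(u, 25L)
  expect_true(all(u >= 0.5 & u <= 1))
  # every pattern is its binary parent times the same shared u
  expect_equal(patternValues(g1),
    sweep(patternValues(ps), 2, u, `*`))
  # zero bits stay exactly zero
  expect_identical(patternValues(g1) == 0, patternValues(ps) == 0)
  expect_error(makeNonbinary(ps, low = 0), "positive")
  expect_error(makeNonbinary(ps, high = 1.2), "exceed 1")
  expect_error(makeNonbinary(g1), "binary")
})

test_that("4-bit enumeration is complete and lexicographic", {
  e <- enumerate4bit()
  expect_identical(nPatterns(e), 16L)
  vals <- patternValues(e)
  expect_identical(nrow(unique(vals)), 16L)
  expect_equal(vals[1, ], c(0, 0, 0, 0))
  expect_equal(vals[2, ], c(0, 0, 0, 1))
  expect_equal(vals[16, ], c(1, 1, 1, 1))
  hasRow <- function(m, r) any(apply(m, 1, function(x) all(x == r)))
  expect_true(hasRow(vals, c(1, 0, 1, 1)))
  expect_true(hasRow(vals, c(1, 1, 1, 0)))
})

test_that("threshold partition matches exhaustive dot products", {
  e <- enumerate4bit()
  w <- c(450, 3500, 900, 3500)
  sel <- selectSeparable(e, w, 4000, 4500)
  # oracle: plain loop over all 16 patterns
  oracle <- apply(patternValues(e), 1, function(x) sum(w * x))
  expect_identical(sel$products, as.numeric(oracle))
  expect_identical(sort(c(sel$set0, sel$set1, sel$boundary)), 1:16)
  expect_length(intersect(sel$set0, sel$set1), 0)
  p1011 <- which(apply(patternValues(e), 1,
    function(x) all(x == c(1, 0, 1, 1))))
  expect_equal(sel$products[p1011], 4850)
  expect_true(p1011 %in% sel$set1)
  pzero <- which(apply(patternValues(e), 1, function(x) all(x == 0)))
  expect_true(pzero %in% sel$set0)
  expect_equal(sel$products[pzero], 0)
  # invariant to pattern ordering
  perm <- sample(16)
  sel2 <- selectSeparable(e[perm], w, 4000, 4500)
  expect_setequal(sel$products, sel2$products)
  expect_identical(length(sel$boundary), length(sel2$boundary))
  expect_error(selectSeparable(e, c(1, 2), 0, 1), "does not match")
  expect_error(selectSeparable(e, w, 10, 5), "must not exceed")
})

test_that("pattern sets round trip through CSV and JSON", {
  ps <- makeNonbinary(makePatternSet(3), seed = 9)
  fcsv <- withr::local_tempfile(fileext = ".csv")
  fjson <- withr::local_tempfile(fileext = ".json")
  writePatternSet(ps, fcsv)
  writePatternSet(ps, fjson)
  bcsv <- readPatternSet(fcsv)
  bjson <- readPatternSet(fjson)
  expect_equal(patternValues(bcsv), patternValues(ps))
  expect_identical(patternCategory(bcsv), patternCategory(ps))
  expect_identical(noiseIndex(bcsv), noiseIndex(ps))
  expect_equal(patternValues(bjson), patternValues(ps))
  # JSON carries provenance, including the shared scaling vector
  expect_equal(provenance(bjson)$scaling, provenance(ps)$scaling)
})
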