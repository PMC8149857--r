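# Weight learning: loss, gradients, discrete projection, direct and
# coordinate search, and the trainer against enumeration oracles.

test_that("training loss follows the normalized squared-error form", {
  expect_equal(responseLoss(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(responseLoss(c(1, 0), c(0, 1)), 1)
  set.seed(11)
  for (rep in 1:5) {
    R <- stats::runif(7, 0, 2e4)
    t <- stats::runif(7, 0, 2e4)
    span <- 2.16e4
    expect_equal(responseLoss(R, t, span), 0.5 * sum(((R - t) / span)^2))
  }
  expect_error(responseLoss(1:3, 1:2), "length")
})

test_that("analytic gradient agrees with central finite differences", {
  rec <- registryRow("R_mCh")
  set.seed(21)
  X <- matrix(stats::runif(15), 5, 3)
  targets <- stats::runif(5, 500, 2e4)
  for (rep in 1:4) {
    w <- stats::runif(3, 200, 4000)
    ga <- lossGradient(w, X, targets, rec)
    gf <- lossGradient(w, X, targets, rec, mode = "fd", gradStep = 0.5)
    expect_equal(ga, gf, tolerance = 1e-4)
  }
})

test_that("gradient vanishes at a perfect fit and respects zero inputs", {
  rec <- registryRow("R_mCh")
  X <- matrix(c(1, 0, 0, 0, 1, 0), 2, 3, byrow = TRUE)
  w <- c(1500, 800, 2000)
  targets <- evalActivator(rec, as.numeric(X %*% w))
  expect_equal(lossGradient(w, X, targets, rec), c(0, 0, 0))
  # a single pattern with one active bit only moves that coordinate
  g <- lossGradient(w, matrix(c(1, 0, 0), 1), targets[1] * 2, rec)
  expect_true(g[1] != 0)
  expect_identical(g[2:3], c(0, 0))
})

test_that("discrete projection maps to nearest level, ties to smaller magnitude", {
  expect_equal(projectDiscrete(700, c(450, 900)), 900)   # nearest: 200 < 250
  expect_equal(projectDiscrete(675, c(450, 900)), 450)   # equidistant tie
  expect_equal(projectDiscrete(c(450, 900, -735), c(-735, 450, 900)),
    c(450, 900, -735))
  expect_equal(projectDiscrete(c(-100, 100, 2500), c(-735, 450, 900, 3500)),
    c(450, 450, 3500))
  expect_error(projectDiscrete(1, numeric(0)), "non-empty")
  # idempotence and brute-force nearest-level scan
  set.seed(41)
  pal <- sort(c(-735, 0, 450, 900, 3500))
  w <- stats::runif(50, -1000, 4000)
  p1 <- projectDiscrete(w, pal)
  expect_equal(projectDiscrete(p1, pal), p1)
  for (i in seq_along(w)) {
    dists <- abs(w[i] - pal)
    expect_equal(abs(p1[i] - w[i]), min(dists))
  }
})

test_that("direct search never increases loss and is exhaustive at full radius", {
  toy <- toyDichotomy()
  pal <- c(-735, 450, 900, 3500)
  span <- toy$receiver@betaM
  oracle <- bruteForceOptimum(pal, 2L, toy$X, toy$targets, toy$receiver,
    span)
  # from every palette start, a radius spanning the palette reaches the
  # global optimum
  for (w0 in list(c(450, 450), c(3500, 3500), c(-735, 3500))) {
    ds <- directSearch(w0, pal, radius = 4L, toy$X, toy$targets,
      toy$receiver)
    expect_equal(ds$loss, oracle$loss)
    before <- responseLoss(evalActivator(toy$receiver,
      pmax(as.numeric(toy$X %*% w0), 0)), toy$targets, span)
    expect_lte(ds$loss, before)
  }
  # at the optimum, no neighbour improves and the point is kept
  at <- directSearch(oracle$weights, pal, radius = 4L, toy$X, toy$targets,
    toy$receiver)
  expect_identical(at$weights, oracle$weights)
  # an oversized neighbourhood is refused with guidance
  expect_error(directSearch(rep(450, 12), pal, radius = 4L,
    matrix(1, 1, 12), 1e4, toy$receiver, budget = 1000),
    "exceeding the budget")
})

test_that("coordinate search is monotone and fixed at discrete optima", {
  toy <- toyDichotomy()
  pal <- c(-735, 450, 900, 3500)
  span <- toy$receiver@betaM
  for (w0 in list(c(3500, 3500), c(450, 450), c(-735, 900))) {
    before <- responseLoss(evalActivator(toy$receiver,
      pmax(as.numeric(toy$X %*% w0), 0)), toy$targets, span)
    cs <- coordinateSearch(w0, pal, toy$X, toy$targets, toy$receiver)
    expect_lte(cs$loss, before)
    expect_true(all(cs$weights %in% pal))
  }
  # the global optimum is a fixed point of the greedy sweep
  oracle <- bruteForceOptimum(pal, 2L, toy$X, toy$targets, toy$receiver,
    span)
  at <- coordinateSearch(oracle$weights, pal, toy$X, toy$targets,
    toy$receiver)
  expect_identical(at$weights, oracle$weights)
})

test_that("continuous training separates a linearly separable dichotomy", {
  toy <- toyDichotomy()
  cfg <- quickConfig(mode = "continuous-positive", seed = 3L)
  fit <- trainWeights(toy$X, toy$targets, cfg)
  expect_true(isConverged(fit))
  expect_false(fit@diverged)
  expect_true(all(learnedWeights(fit) >= 0))
  # zero misclassification: the H pattern outscores every L pattern
  expect_gt(fit@responses[4], max(fit@responses[1:3]))
  # loss trajectory is non-increasing under the halving schedule
  expect_true(all(diff(lossTrajectory(fit)) <= 1e-12))
})

test_that("training is deterministic under a fixed seed and stays at optima", {
  toy <- toyDichotomy()
  cfg <- quickConfig(seed = 7L)
  f1 <- trainWeights(toy$X, toy$targets, cfg)
  f2 <- trainWeights(toy$X, toy$targets, cfg)
  expect_identical(learnedWeights(f1), learnedWeights(f2))
  expect_identical(lossTrajectory(f1), lossTrajectory(f2))
  # different seeds may start elsewhere but the API stays deterministic
  f3 <- trainWeights(toy$X, toy$targets, quickConfig(seed = 8L))
  expect_s4_class(f3, "TrainingResult")
  # an already-optimal initialization does not move in continuous mode
  rec <- toy$receiver
  wStar <- c(800, 900)
  targets <- evalActivator(rec, pmax(as.numeric(toy$X %*% wStar), 0))
  fit <- trainWeights(toy$X, targets,
    quickConfig(mode = "continuous-positive"), init = wStar)
  expect_identical(learnedWeights(fit), wStar)
  expect_true(isConverged(fit))
})

test_that("train plus direct search attains the enumeration optimum on
           small discrete problems", {
  rec <- registryRow("R_mCh")
  pal <- c(-735, 450, 900, 3500)
  span <- rec@betaM
  # all 3-bit binary patterns; targets synthesized from a palette weight
  # vector, so the optimum loss is zero and the weights are recoverable
  X <- as.matrix(expand.grid(0:1, 0:1, 0:1))[, 3:1]
  dimnames(X) <- NULL
  for (wTrue in list(c(450, 900, 3500), c(3500, -735, 900))) {
    targets <- evalActivator(rec, pmax(as.numeric(X %*% wTrue), 0))
    oracle <- bruteForceOptimum(pal, 3L, X, targets, rec, span)
    cfg <- quickConfig(seed = 5L, directSearchRadius = 4L)
    fit <- trainWeights(X, targets, cfg)
    expect_true(all(learnedWeights(fit) %in% pal))
    expect_equal(utils::tail(lossTrajectory(fit), 1), oracle$loss,
      tolerance = 1e-10)
    # unit patterns pin every coordinate, so recovery is exact
    expect_equal(learnedWeights(fit), wTrue)
  }
})

test_that("every-step projection keeps iterates on the palette", {
  toy <- toyDichotomy()
  cfg <- quickConfig(seed = 2L, projectionCadence = "everyStep")
  fit <- trainWeights(toy$X, toy$targets, cfg)
  expect_true(all(learnedWeights(fit) %in% cfg@palette))
})

test_that("one-vs-rest targets assign H to exactly one category per pattern", {
  ps <- makePatternSet(3)
  tg <- makeTargets(ps)
  expect_identical(tg$categories, c("z", "v", "n"))
  expect_true(all(colSums(tg$labels == "H") == 1))
  rec <- registryRow("R_mCh")
  expect_equal(tg$H, evalActivator(rec, 3 * rec@Kd))
  expect_equal(tg$L, evalActivator(rec, 0))
  expect_true(all(tg$target %in% c(tg$H, tg$L)))
})

test_that("multiclass training separates the three 3x3 categories", {
  ps <- makePatternSet(3)
  res <- trainMulticlass(ps, quickConfig(seed = 1L))
  expect_named(res$results, c("z", "v", "n"))
  expect_true(all(res$margins > 0))
  # own-category responses exceed all other responses, per category
  for (cc in c("z", "v", "n")) {
    R <- res$results[[cc]]@responses
    own <- patternCategory(ps) == cc
    expect_gt(min(R[own]), max(R[!own]))
  }
  # margins recomputable from the stored response matrix
  expect_equal(classificationMargins(res$responseMatrix,
    patternCategory(ps)), res$margins)
})
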