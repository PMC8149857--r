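# Forward consortium model: weighted sums, receiver activation, response
# matrices and product-degeneracy counting.

test_that("weighted sums follow the signed dot product", {
  net <- consortiumNetwork(c(450, 3500, 900, 3500))
  expect_equal(weightedSum(net, c(1, 0, 1, 1)), 4850)
  expect_equal(weightedSum(net, c(0, 0, 0, 0)), 0)
  net2 <- consortiumNetwork(c(1000, -1000))
  expect_equal(weightedSum(net2, c(1, 1)), 0)
  expect_error(weightedSum(net, c(1, 0)), "does not match")
  # linearity in the pattern and in the weights
  x1 <- c(0.2, 0.8, 0.5, 0)
  x2 <- c(0.1, 0, 0.9, 1)
  expect_equal(weightedSum(net, (x1 + x2) / 2),
    (weightedSum(net, x1) + weightedSum(net, x2)) / 2)
  expect_equal(weightedSum(consortiumNetwork(2 * c(450, 3500, 900, 3500)),
    x1), 2 * weightedSum(net, x1))
})

test_that("receiver response matches the activation closed forms", {
  rmc <- registryRow("R_mCh")
  expect_equal(receiverResponse(rmc, 1103), 2.16e4 * (0.5 + 0.0195))
  expect_equal(receiverResponse(rmc, 0), 2.16e4 * 0.0195)
  expect_gt(receiverResponse(rmc, 4850), receiverResponse(rmc, 3950))
  expect_warning(out <- receiverResponse(rmc, -5), "clamped")
  expect_equal(out, receiverResponse(rmc, 0))
})

test_that("forward response composes sum and activation deterministically", {
  net <- consortiumNetwork(c(450, 3500, 900, 3500))
  r1 <- forwardResponse(net, c(1, 0, 1, 1))
  expect_identical(r1, forwardResponse(net, c(1, 0, 1, 1)))
  expect_equal(r1, receiverResponse(registryRow("R_mCh"), 4850))
  # the high-product pattern outscores a low-product one
  expect_gt(r1, forwardResponse(net, c(0, 0, 1, 0)))
})

test_that("weight noise is seeded, reproducible, and mean-preserving in scale", {
  netA <- consortiumNetwork(c(450, 3500, 900, 3500), noiseCV = 0.1,
    noiseSeed = 5L)
  netB <- consortiumNetwork(c(450, 3500, 900, 3500), noiseCV = 0.1,
    noiseSeed = 5L)
  netC <- consortiumNetwork(c(450, 3500, 900, 3500), noiseCV = 0.1,
    noiseSeed = 6L)
  x <- c(1, 1, 1, 1)
  expect_identical(forwardResponse(netA, x), forwardResponse(netB, x))
  expect_false(identical(forwardResponse(netA, x),
    forwardResponse(netC, x)))
  # noise never flips a weight's sign
  netNeg <- consortiumNetwork(c(-735, 450), noiseCV = 0.2, noiseSeed = 2L)
  expect_lt(weightedSum(netNeg, c(1, 0)), 0)
})

test_that("senders derive weights from transfer functions or overrides", {
  s <- senderSpec("mut8", params = registryRow("S_mut8"))
  expect_equal(s@weightValue, evalActivator(registryRow("S_mut8"), 33))
  sr <- senderSpec("rep", params = registryRow("S_plux_rep"))
  expect_identical(sr@sign, -1)
  expect_equal(sr@sign * sr@weightValue, alphaHatM(registryRow("S_plux_rep")))
  so <- senderSpec("cal", params = registryRow("S_mut8"), weightValue = 450)
  expect_equal(so@weightValue, 450)
  expect_error(senderSpec("nothing"), "either")
  # unit mixing is refused: a receiver on the inducer axis cannot consume
  # mCherry-equivalent weighted sums
  expect_error(consortiumNetwork(c(1, 2), receiver = registryRow("R_PF")),
    "mCherry")
})

test_that("leaky bit-0 policy adds basal sender activity for zero bits", {
  senders <- lapply(c("S_mut8", "S_mut7"), function(l)
    senderSpec(l, params = registryRow(l)))
  netZ <- consortiumNetwork(senders = senders)
  netL <- consortiumNetwork(senders = senders, bitZeroPolicy = "leaky")
  p8 <- registryRow("S_mut8")
  expect_equal(weightedSum(netZ, c(0, 1)) + p8@betaM * p8@beta0,
    weightedSum(netL, c(0, 1)))
  expect_equal(weightedSum(netZ, c(1, 1)), weightedSum(netL, c(1, 1)))
})

test_that("response matrices cover all nets and patterns in order", {
  ps <- makePatternSet(3)
  nets <- lapply(list(rep(450, 9), rep(900, 9), c(rep(450, 4), rep(-735, 5))),
    consortiumNetwork)
  m <- responseMatrix(nets, ps)
  expect_identical(dim(eyfp(m)), c(3L, 30L))
  expect_identical(dim(weightedSums(m)), c(3L, 30L))
  # entries agree with scalar evaluation
  expect_equal(weightedSums(m)[2, 7],
    weightedSum(nets[[2]], patternValues(ps)[7, ]))
  expect_equal(eyfp(m)[1, 1],
    forwardResponse(nets[[1]], patternValues(ps)[1, ]))
  # empty set gives a 1 x 0 matrix
  m0 <- responseMatrix(nets[[1]], makePatternSet(3)[integer(0)])
  expect_identical(dim(eyfp(m0)), c(1L, 0L))
})

test_that("permuting senders and pattern bits together changes nothing", {
  ps <- makePatternSet(3)
  w <- c(450, 900, 3500, -735, 450, 900, 3500, -735, 450)
  perm <- c(3, 1, 2, 9, 5, 6, 4, 8, 7)
  net <- consortiumNetwork(w)
  netP <- consortiumNetwork(w[perm])
  X <- patternValues(ps)
  for (i in c(1, 5, 20)) {
    expect_equal(forwardResponse(netP, X[i, perm]),
      forwardResponse(net, X[i, ]))
  }
})

test_that("unique-product counting matches an independent oracle", {
  expect_identical(countUniqueProducts(matrix(5, 3, 4))$count, 1L)
  expect_identical(countUniqueProducts(matrix(c(0, 5, 5, 9), 2))$count, 3L)
  expect_error(countUniqueProducts(matrix(1), tolerance = -1),
    "non-negative")
  expect_error(countUniqueProducts(numeric(0)), "non-empty")
  set.seed(31)
  for (rep in 1:5) {
    vals <- sample(seq(0, 5000, by = 250), 60, replace = TRUE) +
      sample(c(0, 1e-9), 60, replace = TRUE)
    tol <- 1e-6 * max(abs(vals))
    got <- countUniqueProducts(matrix(vals, 6), tolerance = tol)
    expect_identical(got$count, bruteForceUniqueCount(vals, tol))
    expect_identical(sum(got$multiplicities), 60L)
  }
})

test_that("network configs and response matrices round trip to disk", {
  senders <- list(senderSpec("a", params = registryRow("S_mut40")),
    senderSpec("b", params = registryRow("S_plux_rep")),
    senderSpec("c", weightValue = 900))
  net <- consortiumNetwork(senders = senders, noiseCV = 0.05,
    noiseSeed = 7L)
  tf <- withr::local_tempfile(fileext = ".json")
  writeNetworkConfig(net, tf)
  back <- readNetworkConfig(tf)
  expect_equal(signedWeights(back), signedWeights(net))
  expect_identical(back@bitZeroPolicy, net@bitZeroPolicy)
  expect_equal(back@noiseCV, net@noiseCV)
  expect_error(responseMatrix(consortiumNetwork(c(1, 2)), makePatternSet(3)),
    "does not match")
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  m34 <- responseMatrix(list(consortiumNetwork(rep(450, 9)),
    consortiumNetwork(rep(900, 9))), makePatternSet(3))
  writeResponseMatrix(m34, f1, f2)
  back1 <- utils::read.csv(f1, check.names = FALSE)
  expect_identical(dim(back1), c(2L, 31L))
  expect_equal(as.numeric(back1[1, -1]), as.numeric(eyfp(m34)[1, ]))
})
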