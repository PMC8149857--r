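# Shared helpers for the test suite. All fixtures are built in code.

`%||%` <- function(a, b) if (is.null(a)) b else a

# fast training configuration for small problems
quickConfig <- function(...) {
  trainingConfig(maxIter = 2000L, ...)
}

# brute-force enumeration of every palette combination for d weights;
# returns the loss-minimizing weight vector and its loss (independent of the
# package's search code paths)
bruteForceOptimum <- function(palette, d, X, targets, receiver, span) {
  combos <- as.matrix(expand.grid(rep(list(palette), d)))
  best <- NULL
  bestLoss <- Inf
  for (i in seq_len(nrow(combos))) {
    w <- as.numeric(combos[i, ])
    s <- pmax(as.numeric(X %*% w), 0)
    R <- evalActivator(receiver, s)
    l <- 0.5 * sum(((R - targets) / span)^2)
    if (l < bestLoss) {
      bestLoss <- l
      best <- w
    }
  }
  list(weights = best, loss = bestLoss)
}

# independent distinct-value count: plain double loop over sorted values
bruteForceUniqueCount <- function(values, tol) {
  values <- sort(as.numeric(values))
  count <- 1L
  for (i in seq_along(values)[-1]) {
    if (values[i] - values[i - 1L] > tol) count <- count + 1L
  }
  count
}

# the two-bit AND-style dichotomy: only [1,1] should activate the receiver
toyDichotomy <- function() {
  X <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), 4, 2, byrow = TRUE)
  rec <- registryRow("R_mCh")
  H <- evalActivator(rec, 3 * rec@Kd)
  L <- evalActivator(rec, 0)
  list(X = X, targets = c(L, L, L, H), receiver = rec, H = H, L = L)
}
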