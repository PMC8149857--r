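# Gradient-descent weight learning with discrete-level constraints and
# direct-search refinement. The loss is squared error between simulated
# receiver responses and H/L targets, normalized by the receiver output span;
# descent steps are taken on weights reparameterized by the receiver Kd so
# the learning rate is dimensionless.

#' Build a training configuration
#'
#' @param eta learning rate (> 0, dimensionless); on an overshooting step the
#'   rate is halved until the loss decreases.
#' @param maxIter maximum number of accepted gradient steps.
#' @param lossTol stop once the span-normalized loss falls below this value.
#' @param gradStep finite-difference step in weight units (cross-check
#'   gradient mode only).
#' @param palette allowed discrete signed weight levels, sorted increasing.
#'   The default combines the three calibrated sender mCherry levels with the
#'   repressor's negative weight.
#' @param mode `"discrete"` (descent, then projection to the palette, then
#'   direct search) or `"continuous-positive"` (weights constrained to be
#'   non-negative, no projection).
#' @param projectionCadence `"converged"` (project once after descent,
#'   default) or `"everyStep"` (project every accepted step).
#' @param directSearchRadius neighbourhood half-width, in palette index
#'   steps, for the refinement search.
#' @param directSearchBudget largest neighbourhood enumerated exhaustively;
#'   above it, refinement falls back to greedy coordinate search.
#' @param seed RNG seed for weight initialization.
#' @param initPolicy `"uniform"`: seeded uniform draws over the positive
#'   palette range.
#' @return A [`TrainingConfig`][TrainingConfig-class].
#' @export
#' @examples
#' trainingConfig(seed = 3)
trainingConfig <- function(eta = 0.1, maxIter = 10000L, lossTol = 1e-4,
                           gradStep = 1, palette = c(-735, 450, 900, 3500),
                           mode = c("discrete", "continuous-positive"),
                           projectionCadence = c("converged", "everyStep"),
                           directSearchRadius = 1L, directSearchBudget = 3e5,
                           seed = 1L, initPolicy = "uniform") {
  new("TrainingConfig", eta = as.numeric(eta), maxIter = as.integer(maxIter),
    lossTol = as.numeric(lossTol), gradStep = as.numeric(gradStep),
    palette = sort(as.numeric(palette)), mode = match.arg(mode),
    projectionCadence = match.arg(projectionCadence),
    directSearchRadius = as.integer(directSearchRadius),
    directSearchBudget = as.numeric(directSearchBudget),
    seed = as.integer(seed), initPolicy = as.character(initPolicy))
}

#' Squared-error training loss
#'
#' `0.5 * sum(((R - t) / span)^2)`: zero exactly when the responses equal the
#' targets. During training `span` is the receiver output span `betaM`, which
#' makes the loss (and the learning rate) scale-free.
#'
#' @param R simulated response vector.
#' @param t target vector of the same length.
#' @param span normalization constant (default 1, i.e. raw squared error).
#' @return A non-negative scalar.
#' @export
#' @examples
#' responseLoss(c(1, 0), c(0, 1))  # 1
responseLoss <- function(R, t, span = 1) {
  if (length(R) != length(t))
    stop("response and target vectors differ in length")
  0.5 * sum(((R - t) / span)^2)
}

# forward pass used throughout training: clamp, activate
.forwardBatch <- function(X, w, receiver) {
  s <- as.numeric(X %*% w)
  sc <- pmax(s, 0)
  list(sums = s, responses = evalActivator(receiver, sc))
}

.batchLoss <- function(X, w, receiver, targets, span) {
  responseLoss(.forwardBatch(X, w, receiver)$responses, targets, span)
}

#' Gradient of the training loss
#'
#' Analytic chain-rule gradient of [responseLoss()] with respect to the
#' weights, through the receiver activation function (clamped weighted sums
#' contribute zero), summed over patterns. A central finite-difference mode
#' is available as an independent cross-check.
#'
#' @param w weight vector.
#' @param patterns a [`PatternSet`][PatternSet-class] or numeric pattern
#'   matrix (one row per pattern).
#' @param targets numeric target vector.
#' @param receiver receiver activation
#'   [`HillActivatorParams`][HillParams-classes].
#' @param span loss normalization; default the receiver `betaM`.
#' @param mode `"analytic"` or `"fd"` (central differences).
#' @param gradStep finite-difference step in weight units.
#' @return Gradient vector of length `length(w)`.
#' @export
lossGradient <- function(w, patterns, targets, receiver =
                           registryRow("R_mCh"), span = receiver@betaM,
                         mode = c("analytic", "fd"), gradStep = 1) {
  mode <- match.arg(mode)
  X <- .patternMatrix(patterns, length(w))
  if (nrow(X) != length(targets))
    stop("one target per pattern required")
  if (mode == "fd") {
    g <- vapply(seq_along(w), function(i) {
      wp <- w; wp[i] <- w[i] + gradStep
      wm <- w; wm[i] <- w[i] - gradStep
      (.batchLoss(X, wp, receiver, targets, span) -
         .batchLoss(X, wm, receiver, targets, span)) / (2 * gradStep)
    }, numeric(1))
    return(g)
  }
  fb <- .forwardBatch(X, w, receiver)
  eps <- (fb$responses - targets) / span^2
  dRds <- activatorDerivative(receiver, pmax(fb$sums, 0))
  dRds[fb$sums < 0] <- 0  # clamped region: flat
  g <- as.numeric(crossprod(X, eps * dRds))
  if (any(!is.finite(g)))
    stop("non-finite gradient encountered (check weights and receiver ",
      "parameters)")
  g
}

#' Project weights onto a discrete palette
#'
#' Maps each weight to the nearest allowed level; equidistant ties break
#' toward the level of smaller magnitude.
#'
#' @param w weight vector.
#' @param palette non-empty sorted vector of allowed levels.
#' @return The projected weight vector.
#' @export
#' @examples
#' projectDiscrete(700, c(450, 900))  # 450 (tie toward smaller magnitude)
projectDiscrete <- function(w, palette) {
  if (length(palette) == 0L) stop("'palette' must be non-empty")
  palette <- sort(palette)
  vapply(w, function(wi) {
    d <- abs(wi - palette)
    cand <- palette[d == min(d)]
    cand[which.min(abs(cand))]
  }, numeric(1))
}

.paletteIndex <- function(w, palette) {
  vapply(w, function(wi) {
    i <- which(abs(palette - wi) <= 1e-9 * max(1, abs(wi)))
    if (length(i) != 1L)
      stop("weight ", wi, " is not a palette level; project first")
    i
  }, integer(1))
}

.losses_for_W <- function(W, X, receiver, targets, span, chunk = 50000L) {
  # row-wise loss for a matrix of candidate weight vectors, chunked
  n <- nrow(W)
  out <- numeric(n)
  tX <- t(X)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    S <- W[idx, , drop = FALSE] %*% tX
    R <- evalActivator(receiver, pmax(S, 0))
    D <- sweep(R, 2L, targets, `-`) / span
    out[idx] <- 0.5 * rowSums(D * D)
  }
  out
}

#' Direct search over a discrete neighbourhood
#'
#' Exhaustively evaluates every palette combination within `radius` index
#' steps of `w` in each coordinate and returns the loss-minimizing candidate
#' (or `w` itself if no candidate improves); the loss never increases. With a
#' radius spanning the whole palette this is exhaustive enumeration of the
#' discrete weight space. A neighbourhood larger than `budget` combinations
#' is refused with guidance rather than silently truncated.
#'
#' @param w weight vector whose entries are palette levels.
#' @param palette sorted vector of allowed levels.
#' @param radius neighbourhood half-width in palette index steps (>= 1).
#' @param patterns pattern set or matrix.
#' @param targets numeric target vector.
#' @param receiver receiver activation parameters.
#' @param span loss normalization; default the receiver `betaM`.
#' @param budget maximum number of combinations to enumerate.
#' @return A list with `weights`, `loss`, and `nEvals`.
#' @export
directSearch <- function(w, palette, radius, patterns, targets,
                         receiver = registryRow("R_mCh"),
                         span = receiver@betaM, budget = 3e5) {
  palette <- sort(palette)
  idx <- .paletteIndex(w, palette)
  P <- length(palette)
  ranges <- lapply(idx, function(i) max(1L, i - radius):min(P, i + radius))
  size <- prod(vapply(ranges, length, numeric(1)))
  if (size > budget)
    stop("direct-search neighbourhood has ", format(size, big.mark = ","),
      " combinations, exceeding the budget of ", format(budget,
        big.mark = ","), "; reduce 'radius' or use coordinateSearch()")
  combos <- as.matrix(expand.grid(ranges, KEEP.OUT.ATTRS = FALSE))
  W <- matrix(palette[combos], nrow(combos), ncol(combos))
  X <- .patternMatrix(patterns, length(w))
  losses <- .losses_for_W(W, X, receiver, targets, span)
  lossW <- .batchLoss(X, w, receiver, targets, span)
  best <- which.min(losses)
  if (losses[best] < lossW - 1e-15)
    list(weights = as.numeric(W[best, ]), loss = losses[best],
      nEvals = nrow(W))
  else
    list(weights = w, loss = lossW, nEvals = nrow(W))
}

#' Greedy coordinate search over a palette
#'
#' Sweeps the coordinates repeatedly, replacing each weight by the palette
#' level that most reduces the loss with all other weights held fixed, until
#' a full sweep makes no improvement. Scales to large grids where the full
#' neighbourhood enumeration of [directSearch()] is infeasible; like it, the
#' loss never increases.
#'
#' @inheritParams directSearch
#' @param maxSweeps maximum number of full coordinate sweeps.
#' @return A list with `weights`, `loss`, and `nEvals`.
#' @export
coordinateSearch <- function(w, palette, patterns, targets,
                             receiver = registryRow("R_mCh"),
                             span = receiver@betaM, maxSweeps = 100L) {
  palette <- sort(palette)
  X <- .patternMatrix(patterns, length(w))
  s <- as.numeric(X %*% w)
  loss <- responseLoss(evalActivator(receiver, pmax(s, 0)), targets, span)
  nEvals <- 0L
  for (sweep in seq_len(maxSweeps)) {
    improved <- FALSE
    for (i in seq_along(w)) {
      deltas <- palette - w[i]
      # candidate sums: s + X[,i] * (level - w_i), one column per level
      Scand <- s + outer(X[, i], deltas)
      R <- evalActivator(receiver, pmax(Scand, 0))
      cl <- 0.5 * colSums(((R - targets) / span)^2)
      nEvals <- nEvals + length(palette)
      b <- which.min(cl)
      if (cl[b] < loss - 1e-15) {
        s <- s + X[, i] * deltas[b]
        w[i] <- palette[b]
        loss <- cl[b]
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  list(weights = w, loss = loss, nEvals = nEvals)
}

.initWeights <- function(cfg, d, receiver) {
  pos <- cfg@palette[cfg@palette > 0]
  lo <- if (length(pos)) min(pos) else 0
  hi <- if (length(cfg@palette)) max(cfg@palette) else 3 * receiver@Kd
  withSeed(cfg@seed, stats::runif(d, lo, hi))
}

#' Train a weight vector by gradient descent
#'
#' Iterates gradient-descent updates `w <- w - eta * grad` (on weights
#' reparameterized by the receiver `Kd`, so `eta` is dimensionless) from a
#' seeded random initialization, halving the learning rate whenever a step
#' would increase the loss, until the loss tolerance, a stationary point, or
#' `maxIter` is reached. In `"discrete"` mode the converged weights are then
#' projected onto the palette and refined: exhaustive [directSearch()] when
#' the neighbourhood fits the budget, greedy [coordinateSearch()] otherwise.
#' `"continuous-positive"` mode instead constrains the weights to be
#' non-negative and skips projection. Divergence (non-finite loss) is
#' reported in the result, never silently swallowed.
#'
#' @param patterns a [`PatternSet`][PatternSet-class] or pattern matrix.
#' @param targets numeric vector of H/L target responses, one per pattern
#'   (see [makeTargets()]).
#' @param cfg a [`TrainingConfig`][TrainingConfig-class].
#' @param receiver receiver activation parameters; default registry row
#'   `R_mCh`.
#' @param init optional explicit initial weights (overrides the seeded
#'   initialization).
#' @return A [`TrainingResult`][TrainingResult-class].
#' @export
#' @examples
#' ps <- makePatternSet(3)
#' tg <- makeTargets(ps)
#' cfg <- trainingConfig(seed = 1, maxIter = 500)
#' fit <- trainWeights(ps, tg$target["z", ], cfg)
#' isConverged(fit)
trainWeights <- function(patterns, targets, cfg = trainingConfig(),
                         receiver = registryRow("R_mCh"), init = NULL) {
  X <- if (is(patterns, "PatternSet")) patterns@values else
    .patternMatrix(patterns, ncol(as.matrix(patterns)))
  d <- ncol(X)
  if (nrow(X) != length(targets)) stop("one target per pattern required")
  span <- receiver@betaM
  discrete <- cfg@mode == "discrete"
  clampBox <- function(w) {
    if (discrete && length(cfg@palette))
      pmin(pmax(w, min(cfg@palette)), max(cfg@palette))
    else pmax(w, 0)
  }

  w <- if (is.null(init)) clampBox(.initWeights(cfg, d, receiver)) else
    as.numeric(init)
  if (discrete && cfg@projectionCadence == "everyStep")
    w <- projectDiscrete(w, cfg@palette)

  scale <- receiver@Kd^2
  eta <- cfg@eta
  loss <- .batchLoss(X, w, receiver, targets, span)
  traj <- loss
  converged <- FALSE
  diverged <- FALSE
  stall <- 0L

  if (!is.finite(loss)) {
    diverged <- TRUE
  } else if (loss > cfg@lossTol) {
    for (it in seq_len(cfg@maxIter)) {
      g <- tryCatch(lossGradient(w, X, targets, receiver, span),
        error = function(e) NULL)
      if (is.null(g)) { diverged <- TRUE; break }
      if (sqrt(sum(g^2)) * scale < 1e-12) { converged <- TRUE; break }
      accepted <- FALSE
      for (h in seq_len(60L)) {
        wNew <- clampBox(w - eta * scale * g)
        if (discrete && cfg@projectionCadence == "everyStep")
          wNew <- projectDiscrete(wNew, cfg@palette)
        lossNew <- .batchLoss(X, wNew, receiver, targets, span)
        if (is.finite(lossNew) && lossNew <= loss) {
          accepted <- TRUE
          break
        }
        eta <- eta / 2
      }
      if (!accepted) { converged <- TRUE; break }  # no descent direction left
      # stall: 25 consecutive steps each improving by < 1e-7 of current loss
      if (loss - lossNew < 1e-7 * max(loss, cfg@lossTol))
        stall <- stall + 1L
      else stall <- 0L
      w <- wNew
      loss <- lossNew
      traj <- c(traj, loss)
      eta <- min(eta * 1.2, cfg@eta)
      if (loss <= cfg@lossTol || stall >= 25L) { converged <- TRUE; break }
    }
  } else converged <- TRUE

  nEvals <- 0
  if (discrete && !diverged) {
    w <- projectDiscrete(w, cfg@palette)
    P <- length(cfg@palette)
    nbhd <- prod(pmin(2 * cfg@directSearchRadius + 1, P)^d)
    ref <- if (is.finite(nbhd) && nbhd <= cfg@directSearchBudget)
      directSearch(w, cfg@palette, cfg@directSearchRadius, X, targets,
        receiver, span, budget = cfg@directSearchBudget)
    else
      coordinateSearch(w, cfg@palette, X, targets, receiver, span)
    w <- ref$weights
    loss <- ref$loss
    nEvals <- ref$nEvals
    traj <- c(traj, loss)
  }

  fb <- .forwardBatch(X, w, receiver)
  new("TrainingResult", weights = w, lossTrajectory = traj,
    converged = converged && !diverged, diverged = diverged,
    nSearchEvals = nEvals, responses = fb$responses,
    targets = as.numeric(targets),
    seed = cfg@seed, config = cfg)
}

#' One-vs-rest H/L targets for a pattern set
#'
#' Assigns to each category a target vector over all patterns: H (the
#' receiver response at `3 Kd`, near saturation) for the category's own
#' patterns, L (the basal response at zero input) for every other pattern.
#' Each pattern is H in exactly one category's vector.
#'
#' @param s a [`PatternSet`][PatternSet-class].
#' @param receiver receiver activation parameters.
#' @param H,L numeric target levels; defaults as above.
#' @return A list of class `"TargetSpec"`: `categories`, `H`, `L`, `labels`
#'   (character matrix of `"H"`/`"L"`) and `target` (numeric matrix, one row
#'   per category).
#' @export
#' @examples
#' tg <- makeTargets(makePatternSet(3))
#' tg$target["v", 1:3]
makeTargets <- function(s, receiver = registryRow("R_mCh"), H = NULL,
                        L = NULL) {
  stopifnot(is(s, "PatternSet"))
  if (is.null(H)) H <- evalActivator(receiver, 3 * receiver@Kd)
  if (is.null(L)) L <- evalActivator(receiver, 0)
  cats <- unique(s@category)
  labels <- t(vapply(cats, function(cc)
    ifelse(s@category == cc, "H", "L"), character(nPatterns(s))))
  target <- ifelse(labels == "H", H, L)
  rownames(labels) <- rownames(target) <- cats
  structure(list(categories = cats, H = H, L = L, labels = labels,
    target = target), class = "TargetSpec")
}

#' Train one weight vector per pattern category
#'
#' Runs [trainWeights()] independently for each category against its
#' one-vs-rest targets (each with a category-specific seed forked from the
#' configuration seed) and reports per-category classification margins: the
#' smallest own-category response minus the largest other-category response,
#' positive when the category is perfectly separated.
#'
#' @param s a [`PatternSet`][PatternSet-class].
#' @param cfg a [`TrainingConfig`][TrainingConfig-class].
#' @param receiver receiver activation parameters.
#' @param targetSpec optional `"TargetSpec"` (see [makeTargets()]).
#' @return A list of class `"MulticlassResult"`: `results` (named list of
#'   [`TrainingResult`][TrainingResult-class]), `margins` (named numeric),
#'   `responseMatrix` (a [`ResponseMatrix`][ResponseMatrix-class] of all
#'   trained vectors over the set), and `targetSpec`.
#' @export
#' @examples
#' ps <- makePatternSet(3)
#' res <- trainMulticlass(ps, trainingConfig(seed = 1, maxIter = 300))
#' res$margins
trainMulticlass <- function(s, cfg = trainingConfig(),
                            receiver = registryRow("R_mCh"),
                            targetSpec = makeTargets(s, receiver)) {
  stopifnot(is(s, "PatternSet"))
  cats <- targetSpec$categories
  results <- lapply(cats, function(cc) {
    ccfg <- cfg
    ccfg@seed <- stageSeed(cfg@seed, paste0("train_", cc))
    trainWeights(s, targetSpec$target[cc, ], ccfg, receiver)
  })
  names(results) <- cats
  nets <- lapply(results, function(r)
    consortiumNetwork(r@weights, receiver = receiver))
  rmat <- responseMatrix(nets, s)
  margins <- vapply(cats, function(cc) {
    R <- results[[cc]]@responses
    own <- s@category == cc
    min(R[own]) - max(R[!own])
  }, numeric(1))
  structure(list(results = results, margins = margins,
    responseMatrix = rmat, targetSpec = targetSpec),
    class = "MulticlassResult")
}

#' @export
print.MulticlassResult <- function(x, ...) {
  cat("Multiclass training result\n")
  for (cc in names(x$results)) {
    r <- x$results[[cc]]
    cat(sprintf("  %s: loss %.5g, margin %.4g, %s\n", cc,
      utils::tail(r@lossTrajectory, 1), x$margins[[cc]],
      if (r@converged) "converged" else "not converged"))
  }
  invisible(x)
}
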