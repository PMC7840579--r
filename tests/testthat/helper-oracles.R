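# Independent brute-force implementations used as oracles. These are kept
# deliberately naive (explicit element-by-element loops) and never call the
# package's own linear-algebra paths.

# one propagation layer, element by element
loopLayer <- function(W, B, A, xPrev, residual) {
  n <- length(xPrev)
  xNext <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(n)) acc <- acc + W[i, j] * A[i, j] * xPrev[j]
    xNext[i] <- acc + B[i]
    if (residual) xNext[i] <- xNext[i] + xPrev[i]
  }
  xNext
}

# full forward pass by iterating the loop oracle from the all-ones state
loopForward <- function(net, A) {
  x <- rep(1, net@nRegions)
  for (k in seq_len(net@nLayers))
    x <- loopLayer(net@layers[[k]]$W, net@layers[[k]]$B, A, x, net@residual)
  list(prediction = x[net@roiIndex], state = x)
}

# random symmetric unit-diagonal matrix with entries in [-1, 1]
randomConnectome <- function(n) {
  M <- matrix(runif(n * n, -0.9, 0.9), n, n)
  A <- (M + t(M)) / 2
  diag(A) <- 1
  A
}

# small cohort built directly from random connectomes + supplied targets
makeCohort <- function(mats, y, roi = 1L) {
  new("ConnectomeCohort", connectomes = mats, targets = y,
      roiIndex = as.integer(roi))
}

# fast-but-real training configuration for tests that need a trained model
# without the full 500-epoch schedule
quickConfig <- function(epochs = 60L, batchSize = 32L, seed = 1L,
                        augment = TRUE) {
  decay <- unique(as.integer(round(epochs * c(0.6, 0.8))))
  decay <- decay[decay > 0L & decay < epochs]
  trainingConfig(batchSize = batchSize, epochs = epochs,
                 decayEpochs = decay, augment = augment, seed = seed)
}

# small synthetic cohort at reduced scale for fast tests
quickCohort <- function(nSubjects = 60L, nRegions = 12L, seed = 1L, ...) {
  simulateCohort(generatorConfig(nSubjects = nSubjects, nRegions = nRegions,
                                 nTimepoints = 200L, seed = seed, ...))
}
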