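test_that("initialization follows the scaled Xavier normal convention", {
  # closed form: sd(W) = gain * sqrt(2/(n+n)) = 0.1/sqrt(76) for n = 76
  net <- initNetwork(76, nLayers = 1, roiIndex = 1, gain = 0.1, seed = 42)
  W <- extractPropagation(net, 1)
  expect_equal(0.1 * sqrt(2 / 152), 0.1 / sqrt(76))
  # 5776 draws: sample sd within 5% of the target sd
  expect_lt(abs(sd(W) - 0.1 / sqrt(76)) / (0.1 / sqrt(76)), 0.05)
  expect_lt(abs(sd(net@layers[[1]]$B) - 0.1 * sqrt(2 / 77)) /
              (0.1 * sqrt(2 / 77)), 0.25)

  # zero gain degenerates to exactly zero parameters
  z <- initNetwork(10, 2, 3, gain = 0, seed = 1)
  expect_true(all(z@layers[[1]]$W == 0) && all(z@layers[[2]]$B == 0))

  # determinism: same seed bit-identical, different seed differs
  a <- initNetwork(8, 2, 1, seed = 7)
  b <- initNetwork(8, 2, 1, seed = 7)
  c <- initNetwork(8, 2, 1, seed = 8)
  expect_identical(a@layers, b@layers)
  expect_false(identical(a@layers, c@layers))

  expect_error(initNetwork(8, 2, 9), "roiIndex")
  expect_error(initNetwork(8, 2, 0), "roiIndex")
  expect_error(initNetwork(8, 2, 1, gain = -0.1), "gain")
})

test_that("a single layer matches hand values and the loop oracle", {
  # zero parameters with residual: identity map
  x <- c(0.3, -1, 2)
  out <- layerForward(matrix(0, 3, 3), rep(0, 3), randomConnectome(3), x,
                      residual = TRUE)
  expect_identical(out, x)

  # W of ones makes (W .* A) = A: plain row sums
  A <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  out <- layerForward(matrix(1, 2, 2), c(0, 0), A, c(1, 1),
                      residual = FALSE)
  expect_equal(out, c(1.5, 1.5))

  # random instances against the element-by-element loop
  set.seed(11)
  for (rep in 1:5) {
    n <- 6
    W <- matrix(rnorm(n * n), n, n)
    B <- rnorm(n)
    A <- randomConnectome(n)
    xp <- rnorm(n)
    for (res in c(TRUE, FALSE))
      expect_equal(layerForward(W, B, A, xp, res),
                   loopLayer(W, B, A, xp, res), tolerance = 1e-12)
  }

  expect_error(layerForward(matrix(0, 3, 3), rep(0, 3),
                            matrix(0, 2, 2), x), "dimensions")
})

test_that("forward pass equals the loop oracle on random instances", {
  set.seed(21)
  for (rep in 1:100) {
    n <- sample(2:10, 1)
    K <- sample(1:3, 1)
    res <- rep %% 2 == 0
    net <- initNetwork(n, K, sample(n, 1), gain = runif(1, 0.05, 1),
                       residual = res)
    A <- randomConnectome(n)
    got <- forwardPass(net, A)
    want <- loopForward(net, A)
    expect_equal(got$prediction, want$prediction, tolerance = 1e-10)
    expect_equal(got$state, want$state, tolerance = 1e-10)
  }
})

test_that("cohort forward pass agrees with the per-matrix method", {
  coh <- quickCohort(nSubjects = 15, nRegions = 8, seed = 3)
  net <- initNetwork(8, 3, 2, seed = 5)
  batch <- forwardPass(net, coh)
  single <- vapply(connectomes(coh),
                   function(A) forwardPass(net, A)$prediction, numeric(1))
  expect_equal(batch, single, tolerance = 1e-12)
})

test_that("residual layers telescope: zero parameters preserve the ones state", {
  for (K in c(1, 4)) {
    net <- initNetwork(7, K, 3, gain = 0, residual = TRUE)
    out <- forwardPass(net, randomConnectome(7))
    expect_identical(out$state, rep(1, 7))
    expect_identical(out$prediction, 1)
  }
})

test_that("a 1-layer network is affine in the ROI row with slope W[roi, j]", {
  set.seed(31)
  n <- 6
  roi <- 4
  net <- initNetwork(n, 1, roi, gain = 0.5, residual = FALSE, seed = 13)
  A <- randomConnectome(n)
  base <- forwardPass(net, A)$prediction
  # K=1, residual off: prediction = sum_j W[roi,j] A[roi,j] + B[roi]
  W <- extractPropagation(net, 1)
  expect_equal(base, sum(W[roi, ] * A[roi, ]) + net@layers[[1]]$B[roi],
               tolerance = 1e-12)
  # exact finite-difference slope (affine => any h gives the slope)
  for (j in c(1, n)) {
    Ah <- A
    h <- 0.25
    Ah[roi, j] <- Ah[roi, j] + h
    slope <- (forwardPass(net, Ah)$prediction - base) / h
    expect_equal(slope, W[roi, j], tolerance = 1e-10)
  }
})

test_that("depth equals hops: all-ones W without residual gives A^K powers", {
  set.seed(41)
  n <- 5L
  A <- randomConnectome(n)
  for (K in 1:3) {
    layers <- replicate(K, list(W = matrix(1, n, n), B = rep(0, n)),
                        simplify = FALSE)
    net <- new("PropagationNetwork", nRegions = n, nLayers = as.integer(K),
               roiIndex = 1L, residual = FALSE, layers = layers,
               seed = NA_integer_)
    want <- rep(1, n)
    for (k in seq_len(K)) want <- as.vector(A %*% want)  # A^K %*% ones
    expect_equal(forwardPass(net, A)$state, want, tolerance = 1e-10)
  }
})

test_that("extracted coefficient matrices are copies with bounds checking", {
  net <- initNetwork(6, 2, 1, seed = 17)
  W1 <- extractPropagation(net, 1)
  expect_identical(W1, net@layers[[1]]$W)
  W1[1, 1] <- 999
  expect_false(identical(extractPropagation(net, 1)[1, 1], 999))
  expect_error(extractPropagation(net, 3), "out of range")
  expect_error(extractPropagation(net, 0), "out of range")
})

test_that("topEdges ranks by |coefficient| with documented tie-breaking", {
  # full set on a 2x2
  W <- matrix(c(0.1, -0.4, 0.2, 0.3), 2, 2)
  all4 <- topEdges(W, fraction = 1)
  expect_equal(nrow(all4), 4)
  expect_equal(abs(all4$coefficient), sort(abs(as.vector(W)),
                                           decreasing = TRUE))

  # single dominant entry
  W <- matrix(0.1, 3, 3)
  W[2, 3] <- 10
  top1 <- topEdges(W, fraction = 1 / 9)
  expect_equal(nrow(top1), 1)
  expect_equal(top1$source, 3)   # column = sender
  expect_equal(top1$target, 2)   # row = integrator
  expect_equal(top1$coefficient, 10)

  # random 10x10 against a full-sort oracle
  set.seed(51)
  W <- matrix(rnorm(100), 10, 10)
  got <- topEdges(W, fraction = 0.05)
  expect_equal(nrow(got), 5)
  want <- sort(abs(as.vector(W)), decreasing = TRUE)[1:5]
  expect_equal(abs(got$coefficient), want)

  # ties broken by (row, column) lexicographic order
  W <- matrix(1, 2, 2)
  t2 <- topEdges(W, fraction = 0.5)
  expect_equal(t2$target, c(1, 1))
  expect_equal(t2$source, c(1, 2))

  # labels map indices to names
  W <- diag(3)
  lab <- c("V1", "FFC", "MT")
  expect_true(all(topEdges(W, 1, labels = lab)$source %in% lab))

  expect_error(topEdges(matrix(c(1, NA, 1, 1), 2, 2), 0.5), "missing")
  expect_error(topEdges(W, fraction = 0), "fraction")
  expect_error(topEdges(W, fraction = 1.2), "fraction")
})

test_that("checkpoints round-trip bit-exactly", {
  net <- initNetwork(9, 3, 4, seed = 23, residual = TRUE)
  path <- withr::local_tempfile(fileext = ".json")
  writeCheckpoint(net, path)
  back <- readCheckpoint(path)
  expect_identical(back@layers, net@layers)
  expect_identical(back@roiIndex, net@roiIndex)
  expect_identical(back@residual, net@residual)
  expect_identical(back@seed, net@seed)
  expect_error(readCheckpoint(withr::local_tempfile()), "not found")
})
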