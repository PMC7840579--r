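# reference draw from the truncated-at-zero Gaussian + Gamma mixture used
# in the recovery experiments
rGaussGamma <- function(n, pi0 = 0.6, mu = 1.0, sigma = 0.3,
                        shape = 6, scale = 0.5) {
  fromGauss <- runif(n) < pi0
  x <- numeric(n)
  x[fromGauss] <- rnorm(sum(fromGauss), mu, sigma)
  x[!fromGauss] <- rgamma(sum(!fromGauss), shape = shape, scale = scale)
  x[x > 0]
}

test_that("mean absolute activation prevents sign cancellation", {
  expect_equal(meanAbsActivation(matrix(c(-1, 1), 2, 1)), 1.0)
  expect_equal(meanAbsActivation(matrix(c(1, -2), 1, 2)), c(1, 2))
  expect_equal(meanAbsActivation(matrix(c(1, 3, -2, -4), 2, 2)), c(2, 3))
  expect_error(meanAbsActivation(matrix(numeric(0), 0, 0)), "non-empty")
})

test_that("EM increases the log-likelihood monotonically and converges", {
  set.seed(101)
  for (rep in 1:5) {
    x <- rGaussGamma(400)
    fit <- fitGaussianGamma(x)
    expect_true(fit@converged)
    expect_true(all(diff(fit@loglikTrace) >= -1e-8))
  }
})

test_that("an EM fixed point moves less than the tolerance", {
  set.seed(103)
  x <- rGaussGamma(800)
  fit <- fitGaussianGamma(x, tol = 1e-10, maxIter = 2000L)
  # refitting from the converged parameters gains almost nothing in 1 step
  refit <- hopnet:::.ggEm(x, list(pi0 = fit@weightGauss, mu = fit@mu,
                                  sigma = fit@sigma, shape = fit@shape,
                                  scale = fit@scale),
                          tol = 1e-6, maxIter = 2L)
  expect_lt(abs(refit@loglikTrace[length(refit@loglikTrace)] -
                  refit@loglikTrace[1]), 1e-5)
})

test_that("the mixture density integrates to one for fitted parameters", {
  set.seed(105)
  fit <- fitGaussianGamma(rGaussGamma(500))
  total <- integrate(function(x) mixtureDensity(fit, x), -Inf, Inf,
                     rel.tol = 1e-9)$value
  expect_lt(abs(total - 1), 1e-6)
})

test_that("EM recovers designed mixture parameters, improving with n", {
  # median recovery error over seeds, at three sample sizes
  errAt <- function(n, nSeeds = 7) {
    errs <- vapply(seq_len(nSeeds), function(s) {
      set.seed(200 + s)
      fit <- fitGaussianGamma(rGaussGamma(n))
      c(abs(fit@weightGauss - 0.6), abs(fit@mu - 1.0))
    }, numeric(2))
    apply(errs, 1, median)
  }
  e200 <- errAt(200)
  e2000 <- errAt(2000)
  expect_lt(e2000[1], 0.1)    # mixing weight within +-0.1
  expect_lt(e2000[2], 0.1)    # Gaussian mean within +-0.1
  # graceful degradation: more data, no worse recovery (with slack)
  expect_lt(e2000[1], e200[1] + 0.05)
  expect_lt(e2000[2], e200[2] + 0.05)
})

test_that("input validation guards the Gamma support", {
  expect_error(fitGaussianGamma(c(rep(1, 20), -0.1)), "positive")
  expect_error(fitGaussianGamma(rep(1, 5)), "at least 10")
})

test_that("the activation threshold matches a fine-grid crossing oracle", {
  set.seed(111)
  for (rep in 1:20) {
    fit <- new("GaussianGammaFit",
               weightGauss = runif(1, 0.35, 0.75),
               mu = runif(1, 0.5, 1.2), sigma = runif(1, 0.15, 0.4),
               shape = runif(1, 4, 9), scale = runif(1, 0.35, 0.7),
               loglikTrace = numeric(0), converged = TRUE)
    rng <- c(1e-6, 12)
    got <- activationThreshold(fit, searchRange = rng, nGrid = 4096L)
    # fine-grid oracle: last sign change of the weighted density difference
    g <- seq(rng[1], rng[2], length.out = 200000)
    d <- (1 - fit@weightGauss) * dgamma(g, fit@shape, scale = fit@scale) -
      fit@weightGauss * dnorm(g, fit@mu, fit@sigma)
    xStar <- g[max(which(d < 0)) + 1]
    step <- diff(rng) / 4095
    expect_lt(abs(got - xStar), step)
  }
})

test_that("threshold handles degenerate weights and missing crossings", {
  # all-Gamma mixture: dominance everywhere, threshold at the range floor
  fit <- new("GaussianGammaFit", weightGauss = 0, mu = 0, sigma = 1,
             shape = 3, scale = 1, loglikTrace = numeric(0),
             converged = TRUE)
  expect_equal(activationThreshold(fit, c(0.01, 5)), 0.01)
  # Gaussian that dominates through the whole range: no crossing
  noSep <- new("GaussianGammaFit", weightGauss = 0.999, mu = 2,
               sigma = 5, shape = 1.1, scale = 0.1,
               loglikTrace = numeric(0), converged = TRUE)
  expect_error(activationThreshold(noSep, c(1e-6, 3)), "no crossing")
  # weighted vs unweighted comparison is a real switch at pi != 0.5
  fit2 <- new("GaussianGammaFit", weightGauss = 0.7, mu = 1, sigma = 0.3,
              shape = 6, scale = 0.5, loglikTrace = numeric(0),
              converged = TRUE)
  tw <- activationThreshold(fit2, c(1e-6, 8))
  tu <- activationThreshold(fit2, c(1e-6, 8), weighted = FALSE)
  expect_gt(tw, tu)  # down-weighting the Gamma pushes the crossing right
})

test_that("network selection slices cohorts and protects the ROI", {
  coh <- quickCohort(nSubjects = 12, nRegions = 20, seed = 7)
  vals <- seq(0.05, 1, length.out = 20)
  coh@roiIndex <- 15L   # above the threshold used below

  # threshold below the minimum keeps everything unchanged
  all20 <- selectNetwork(vals, 0, coh)
  expect_equal(all20$selection$nSelected, 20)
  expect_identical(all20$cohort@connectomes, coh@connectomes)

  # brute-force filter oracle on a mid threshold
  thr <- vals[12]
  sel <- selectNetwork(vals, thr, coh)
  keep <- which(vals > thr)
  expect_identical(sel$selection$selectedIndices, keep)
  expect_equal(dim(connectomes(sel$cohort)[[1]]),
               c(length(keep), length(keep)))
  expect_identical(connectomes(sel$cohort)[[3]],
                   connectomes(coh)[[3]][keep, keep])
  expect_equal(roiIndex(sel$cohort), match(15L, keep))

  # ROI below threshold is an error; empty selection is an error
  coh@roiIndex <- 1L
  expect_error(selectNetwork(vals, thr, coh), "ROI")
  expect_error(selectNetwork(vals, 2, coh), "every region")
})

test_that("activation tables with known membership are recovered end-to-end", {
  cfg <- generatorConfig(nSubjects = 300, nRegions = 60, seed = 13)
  tab <- generateActivationTable(cfg, nActiveRegions = 18)
  expect_equal(dim(tab$activations), c(300, 60))
  vals <- meanAbsActivation(tab$activations)
  fit <- fitGaussianGamma(vals, seed = 13)
  thr <- activationThreshold(fit)
  called <- which(vals > thr)
  truth <- tab$activeIndices
  # fraction of regions classified correctly (active vs inactive)
  correct <- sum((seq_len(60) %in% called) == (seq_len(60) %in% truth)) / 60
  expect_gte(correct, 0.9)

  # no active regions: the mixture cannot separate, error path
  flat <- generateActivationTable(cfg, nActiveRegions = 0)
  expect_error({
    f <- fitGaussianGamma(meanAbsActivation(flat$activations), seed = 1)
    activationThreshold(f, c(1e-6, 3))
  }, "crossing|collapsed|failed")

  # seeded reproducibility
  tab2 <- generateActivationTable(cfg, nActiveRegions = 18)
  expect_identical(tab$activations, tab2$activations)
})
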