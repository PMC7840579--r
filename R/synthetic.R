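# Synthetic cohorts with the statistical structure the method assumes:
# per-subject correlation matrices built through the real connectivity
# pipeline from simulated time series, and ROI targets produced by a known
# k-hop propagation process (the production forward pass itself, so the
# generator and the model can never drift apart).

#' Generator configuration for synthetic cohorts
#'
#' Defaults describe the standard experimental conditions used throughout
#' the package's tests and examples: 400 subjects, 30 regions, 600
#' timepoints per subject, a true hop depth of 2, moderate
#' between-subject connectivity variability, and target noise whose
#' standard deviation is half the spread of the noiseless targets (noise
#' variance one quarter of signal variance).
#'
#' @param nSubjects number of subjects.
#' @param nRegions number of regions (>= 4).
#' @param nTimepoints simulated timepoints per subject.
#' @param trueDepth hop depth of the generative propagation network.
#' @param trueParams optional list of `trueDepth` lists with ground-truth
#'   `W` (n-by-n) and `B` (length n); if `NULL`, drawn once per cohort
#'   with `W` entries Normal(0, `trueParamSd`^2) and `B` entries
#'   Normal(0, (0.1 * trueParamSd)^2).
#' @param trueParamSd sd of drawn ground-truth coefficients.
#' @param targetNoiseSd absolute sd of the Gaussian noise added to the
#'   noiseless targets; if `NULL`, `targetNoiseScale * sd(oracle)` is used.
#' @param targetNoiseScale relative noise level (used when `targetNoiseSd`
#'   is `NULL`).
#' @param subjectVariability spread of each subject's covariance loading
#'   around the group template (0 = all subjects share one template).
#' @param templateRank rank of the low-rank part of the group covariance
#'   template; defaults to `max(2, round(nRegions / 5))`.
#' @param roiIndex 1-based target region.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return a list of class `generatorConfig`.
#' @export
generatorConfig <- function(nSubjects = 400L, nRegions = 30L,
                            nTimepoints = 600L, trueDepth = 2L,
                            trueParams = NULL, trueParamSd = 1.0,
                            targetNoiseSd = NULL, targetNoiseScale = 0.5,
                            subjectVariability = 0.3, templateRank = NULL,
                            roiIndex = 1L, seed = 1L) {
  nRegions <- as.integer(nRegions)
  if (nRegions < 4L) stop("nRegions must be at least 4")
  if (!is.null(trueParams) && length(trueParams) != trueDepth)
    stop("trueParams must have length trueDepth")
  if (!is.null(targetNoiseSd) && targetNoiseSd < 0)
    stop("targetNoiseSd must be non-negative")
  if (subjectVariability < 0) stop("subjectVariability must be >= 0")
  if (is.null(templateRank)) templateRank <- max(2L, round(nRegions / 5))
  structure(list(nSubjects = as.integer(nSubjects), nRegions = nRegions,
                 nTimepoints = as.integer(nTimepoints),
                 trueDepth = as.integer(trueDepth),
                 trueParams = trueParams, trueParamSd = trueParamSd,
                 targetNoiseSd = targetNoiseSd,
                 targetNoiseScale = targetNoiseScale,
                 subjectVariability = subjectVariability,
                 templateRank = as.integer(templateRank),
                 roiIndex = as.integer(roiIndex),
                 seed = as.integer(seed)),
            class = "generatorConfig")
}

#' Simulate per-subject connectivity matrices
#'
#' Draws a group covariance template (random low-rank loadings plus a
#' positive diagonal), perturbs the loadings per subject with scale
#' `subjectVariability`, simulates Gaussian region-by-time series from
#' each subject's covariance, and runs them through
#' [connectivityMatrix()] -- so every generated matrix has exactly the
#' properties the real pipeline produces (symmetric, unit diagonal,
#' entries in \[-1, 1\]). The low-rank-plus-diagonal construction is
#' positive definite by construction; a Cholesky failure is retried with
#' diagonal jitter up to 5 times before erroring.
#'
#' @param config a [generatorConfig()].
#' @return list of `nSubjects` connectivity matrices.
#' @export
generateConnectomes <- function(config) {
  n <- config$nRegions
  r <- config$templateRank
  set.seed(config$seed)
  L <- matrix(rnorm(n * r), n, r) / sqrt(r)
  D <- runif(n, 0.3, 0.8)
  lapply(seq_len(config$nSubjects), function(s) {
    Ls <- L + config$subjectVariability * matrix(rnorm(n * r), n, r) / sqrt(r)
    Sigma <- tcrossprod(Ls) + diag(D)
    C <- NULL
    for (try in 1:5) {
      C <- tryCatch(chol(Sigma), error = function(e) NULL)
      if (!is.null(C)) break
      Sigma <- Sigma + diag(1e-6 * try, n)
    }
    if (is.null(C)) stop("covariance template not positive definite ",
                         "after 5 jitter attempts")
    ts <- t(C) %*% matrix(rnorm(n * config$nTimepoints),
                          n, config$nTimepoints)
    connectivityMatrix(ts)
  })
}

# draw (or validate) the ground-truth propagation network
.trueNetwork <- function(config) {
  n <- config$nRegions
  K <- config$trueDepth
  layers <- config$trueParams
  if (is.null(layers)) {
    set.seed(config$seed + 1L)
    layers <- lapply(seq_len(K), function(k)
      list(W = matrix(rnorm(n^2, sd = config$trueParamSd), n, n),
           B = rnorm(n, sd = 0.1 * config$trueParamSd)))
  }
  for (k in seq_len(K)) {
    if (!identical(dim(layers[[k]]$W), c(n, n)) ||
        length(layers[[k]]$B) != n)
      stop("trueParams shapes do not match nRegions")
  }
  new("PropagationNetwork", nRegions = n, nLayers = K,
      roiIndex = config$roiIndex, residual = TRUE, layers = layers,
      seed = config$seed)
}

#' Generate activation targets from a known propagation process
#'
#' Noiseless oracle targets are the production forward pass of the
#' ground-truth network applied to each subject's connectivity matrix;
#' observed targets add independent Gaussian noise. The generative hop
#' depth is therefore exactly `config$trueDepth`.
#'
#' @param connectomes list of connectivity matrices.
#' @param config a [generatorConfig()].
#' @return list with `targets`, `oracleTargets`, `trueNetwork`, and
#'   `noiseSd` (the absolute sd actually used).
#' @export
generateTargets <- function(connectomes, config) {
  net <- .trueNetwork(config)
  oracle <- vapply(connectomes,
                   function(A) forwardPass(net, A)$prediction, numeric(1))
  noiseSd <- if (!is.null(config$targetNoiseSd)) config$targetNoiseSd
             else config$targetNoiseScale * sd(oracle)
  set.seed(config$seed + 2L)
  list(targets = oracle + rnorm(length(oracle), sd = noiseSd),
       oracleTargets = oracle, trueNetwork = net, noiseSd = noiseSd)
}

#' Simulate a full synthetic cohort
#'
#' [generateConnectomes()] followed by [generateTargets()], packaged as a
#' [ConnectomeCohort-class]. The generator config, the ground-truth
#' network and the realized noise sd are stored in the cohort's
#' `metadata`.
#'
#' @param config a [generatorConfig()].
#' @return a [ConnectomeCohort-class] with `targets` and `oracleTargets`.
#' @examples
#' coh <- simulateCohort(generatorConfig(nSubjects = 20, nRegions = 10,
#'                                       nTimepoints = 120, seed = 7))
#' coh
#' @export
simulateCohort <- function(config = generatorConfig()) {
  mats <- generateConnectomes(config)
  tg <- generateTargets(mats, config)
  new("ConnectomeCohort",
      connectomes = mats,
      targets = tg$targets,
      oracleTargets = tg$oracleTargets,
      roiIndex = config$roiIndex,
      metadata = list(config = config, trueNetwork = tg$trueNetwork,
                      noiseSd = tg$noiseSd))
}

#' Generate a subjects-by-regions activation table with known membership
#'
#' Feeds the mixture-threshold module: inactive regions' activations are
#' near-zero Gaussian noise (sd `noiseSd`), active regions' activations
#' are Gamma-distributed positive magnitudes (shape `activeShape`, scale
#' `activeScale`), so the regionwise mean absolute activation follows a
#' genuine two-component mixture with known membership. The active regions
#' are the first `nActiveRegions` (including the ROI when present).
#'
#' @param config a [generatorConfig()] (uses `nSubjects`, `nRegions`,
#'   `seed`).
#' @param nActiveRegions number of truly active regions
#'   (< `nRegions`).
#' @param noiseSd sd of the inactive regions' activations.
#' @param activeShape,activeScale Gamma parameters of the active regions'
#'   activations.
#' @return list with `activations` (subjects-by-regions matrix) and
#'   `activeIndices`.
#' @export
generateActivationTable <- function(config, nActiveRegions,
                                    noiseSd = 0.3, activeShape = 6,
                                    activeScale = 0.5) {
  n <- config$nRegions
  S <- config$nSubjects
  nActiveRegions <- as.integer(nActiveRegions)
  if (nActiveRegions >= n)
    stop("nActiveRegions must be smaller than nRegions")
  set.seed(config$seed + 3L)
  act <- matrix(rnorm(S * n, sd = noiseSd), S, n)
  if (nActiveRegions > 0L) {
    idx <- seq_len(nActiveRegions)
    act[, idx] <- matrix(rgamma(S * nActiveRegions, shape = activeShape,
                                scale = activeScale), S, nActiveRegions)
  }
  list(activations = act,
       activeIndices = seq_len(nActiveRegions))
}
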