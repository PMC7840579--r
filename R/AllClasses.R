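#' PropagationNetwork: an edge-weighted residual graph propagation network
#'
#' A K-layer linear propagation model over an n-region brain network. Layer
#' k maps the per-region state vector \eqn{X^{k-1}} to
#' \eqn{X^k = (W^k \odot A) X^{k-1} + B^k} (plus \eqn{X^{k-1}} when
#' `residual` is `TRUE`), where `A` is a subject's functional connectivity
#' matrix and \eqn{\odot} is the element-wise product. The state is
#' initialized to the all-ones dummy vector, so the only subject-specific
#' input is the connectivity matrix; the prediction is the `roiIndex` entry
#' of the final state. There is no nonlinear activation function anywhere:
#' depth, not a nonlinearity, is what lets layer K expose K-hop walk
#' structure of `A`.
#'
#' `W` is not constrained to be symmetric: row i of `W` weights how region i
#' integrates information from its neighbours, while column j weights how
#' region j propagates information out.
#'
#' @slot nRegions number of regions n.
#' @slot nLayers number of layers K (the hop depth).
#' @slot roiIndex 1-based index of the target region whose final-state entry
#'   is read out as the prediction.
#' @slot residual logical; if `TRUE` each layer adds a skip connection
#'   `+ X^{k-1}`.
#' @slot layers list of K lists, each with an n-by-n matrix `W` and a
#'   length-n numeric `B`.
#' @slot seed integer seed used at initialization (`NA` if none recorded).
#'
#' @seealso [initNetwork()], [forwardPass()], [trainNetwork()],
#'   [extractPropagation()]
#' @export
setClass("PropagationNetwork",
  representation(
    nRegions = "integer",
    nLayers  = "integer",
    roiIndex = "integer",
    residual = "logical",
    layers   = "list",
    seed     = "integer"
  )
)

setValidity("PropagationNetwork", function(object) {
  n <- object@nRegions
  K <- object@nLayers
  if (length(n) != 1L || n < 2L) return("nRegions must be a single integer >= 2")
  if (length(K) != 1L || K < 1L) return("nLayers must be a single integer >= 1")
  if (length(object@layers) != K)
    return(sprintf("layers has length %d but nLayers is %d",
                   length(object@layers), K))
  if (object@roiIndex < 1L || object@roiIndex > n)
    return(sprintf("roiIndex %d out of range [1, %d]", object@roiIndex, n))
  for (k in seq_len(K)) {
    lay <- object@layers[[k]]
    if (!is.list(lay) || !all(c("W", "B") %in% names(lay)))
      return(sprintf("layer %d must be a list with elements W and B", k))
    if (!is.matrix(lay$W) || !identical(dim(lay$W), c(n, n)))
      return(sprintf("layer %d: W must be a %d x %d matrix", k, n, n))
    if (length(lay$B) != n)
      return(sprintf("layer %d: B must have length %d", k, n))
    if (!all(is.finite(lay$W)) || !all(is.finite(lay$B)))
      return(sprintf("layer %d: parameters must be finite", k))
  }
  TRUE
})

#' ConnectomeCohort: subjects' connectivity matrices and activation targets
#'
#' An ordered collection of subjects, each contributing one symmetric
#' functional connectivity matrix (unit diagonal, entries in \[-1, 1\]) and,
#' optionally, a scalar activation target for the region of interest. All
#' subjects share the region count and the ROI index. Subset subjects with
#' `cohort[i]`.
#'
#' @slot connectomes list of n-by-n connectivity matrices, one per subject.
#' @slot targets numeric vector of ROI activations (length = number of
#'   subjects, or length 0 when targets are absent).
#' @slot oracleTargets noiseless ground-truth predictions for synthetic
#'   cohorts (length 0 for real data).
#' @slot roiIndex 1-based index of the target region.
#' @slot regionLabels character vector of region names (may be empty).
#' @slot metadata list of provenance information (generator config, true
#'   network for synthetic cohorts, ...).
#'
#' @seealso [simulateCohort()], [splitCohort()], [readCohort()]
#' @export
setClass("ConnectomeCohort",
  representation(
    connectomes   = "list",
    targets       = "numeric",
    oracleTargets = "numeric",
    roiIndex      = "integer",
    regionLabels  = "character",
    metadata      = "list"
  ),
  prototype(
    oracleTargets = numeric(0),
    regionLabels  = character(0),
    metadata      = list()
  )
)

setValidity("ConnectomeCohort", function(object) {
  S <- length(object@connectomes)
  if (S == 0L) return("cohort must contain at least one subject")
  n <- nrow(object@connectomes[[1L]])
  tolSym <- 1e-8
  for (s in seq_len(S)) {
    A <- object@connectomes[[s]]
    if (!is.matrix(A) || nrow(A) != ncol(A))
      return(sprintf("subject %d: connectome must be a square matrix", s))
    if (nrow(A) != n)
      return(sprintf("subject %d: region count %d differs from %d", s, nrow(A), n))
    if (!all(is.finite(A)))
      return(sprintf("subject %d: connectome has non-finite entries", s))
    if (max(abs(A - t(A))) > tolSym)
      return(sprintf("subject %d: connectome is not symmetric", s))
    if (max(abs(diag(A) - 1)) > tolSym)
      return(sprintf("subject %d: connectome diagonal is not 1", s))
    if (max(abs(A)) > 1 + tolSym)
      return(sprintf("subject %d: connectome entries outside [-1, 1]", s))
  }
  if (length(object@targets) && length(object@targets) != S)
    return("targets length must equal the number of subjects")
  if (length(object@oracleTargets) && length(object@oracleTargets) != S)
    return("oracleTargets length must equal the number of subjects")
  if (object@roiIndex < 1L || object@roiIndex > n)
    return(sprintf("roiIndex %d out of range [1, %d]", object@roiIndex, n))
  if (length(object@regionLabels) && length(object@regionLabels) != n)
    return("regionLabels length must equal the number of regions")
  TRUE
})

#' GaussianGammaFit: a fitted two-component Gaussian + Gamma mixture
#'
#' Models the density of regionwise mean absolute activations as
#' \eqn{\pi N(\mu, \sigma^2) + (1-\pi)\,\mathrm{Gamma}(shape, scale)}:
#' the Gaussian component is the null (noise) distribution, the Gamma
#' component the genuinely activated regions. Fitted by EM; the
#' log-likelihood trace is non-decreasing.
#'
#' @slot weightGauss mixing weight \eqn{\pi} of the Gaussian component,
#'   in \[0, 1).
#' @slot mu,sigma Gaussian mean and standard deviation.
#' @slot shape,scale Gamma shape and scale.
#' @slot loglikTrace per-iteration log-likelihood.
#' @slot converged logical; `TRUE` if EM reached the tolerance before the
#'   iteration cap.
#'
#' @seealso [fitGaussianGamma()], [activationThreshold()]
#' @export
setClass("GaussianGammaFit",
  representation(
    weightGauss = "numeric",
    mu          = "numeric",
    sigma       = "numeric",
    shape       = "numeric",
    scale       = "numeric",
    loglikTrace = "numeric",
    converged   = "logical"
  )
)

setValidity("GaussianGammaFit", function(object) {
  if (object@weightGauss < 0 || object@weightGauss >= 1)
    return("weightGauss must lie in [0, 1)")
  if (object@weightGauss > 0 && object@sigma <= 0)
    return("sigma must be positive")
  if (object@shape <= 0 || object@scale <= 0)
    return("shape and scale must be positive")
  TRUE
})

#' PermutationResult: retrained permutation null for a prediction model
#'
#' Null distributions of test NSE and test correlation obtained by shuffling
#' the pairing between connectivity matrices and targets across all subjects
#' and re-training the same architecture per shuffle, together with the
#' observed model's mean metrics and the null percentile bounds they are
#' compared against (1st percentile for NSE, where lower is better; 99th for
#' r, where higher is better).
#'
#' @slot nullNse,nullR null metric values, one per permutation.
#' @slot observedMeanNse,observedMeanR observed model's mean metrics over
#'   unpermuted evaluation splits.
#' @slot percentile99Bounds named numeric: `nse_p01` and `r_p99`, the
#'   nearest-rank percentile bounds of the null distributions.
#'
#' @seealso [permutationTest()]
#' @export
setClass("PermutationResult",
  representation(
    nullNse            = "numeric",
    nullR              = "numeric",
    observedMeanNse    = "numeric",
    observedMeanR      = "numeric",
    percentile99Bounds = "numeric"
  )
)
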