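#' @rdname nRegions
#' @export
setMethod("nRegions", "PropagationNetwork", function(x) x@nRegions)

#' @rdname nRegions
#' @export
setMethod("nRegions", "ConnectomeCohort",
          function(x) nrow(x@connectomes[[1L]]))

#' @rdname nLayers
#' @export
setMethod("nLayers", "PropagationNetwork", function(x) x@nLayers)

#' @rdname roiIndex
#' @export
setMethod("roiIndex", "PropagationNetwork", function(x) x@roiIndex)

#' @rdname roiIndex
#' @export
setMethod("roiIndex", "ConnectomeCohort", function(x) x@roiIndex)

#' @rdname nSubjects
#' @export
setMethod("nSubjects", "ConnectomeCohort",
          function(x) length(x@connectomes))

#' @rdname connectomes
#' @export
setMethod("connectomes", "ConnectomeCohort", function(x) x@connectomes)

#' @rdname targets
#' @export
setMethod("targets", "ConnectomeCohort", function(x) x@targets)

#' @rdname targets-set
#' @export
setReplaceMethod("targets", "ConnectomeCohort", function(x, value) {
  x@targets <- as.numeric(value)
  validObject(x)
  x
})

#' Subset a cohort by subject
#'
#' @param x a [ConnectomeCohort-class].
#' @param i integer or logical subject indices.
#' @param j,...,drop ignored.
#' @return a [ConnectomeCohort-class] with the selected subjects, in the
#'   given order.
#' @export
setMethod("[", "ConnectomeCohort", function(x, i, j, ..., drop = FALSE) {
  i <- seq_len(nSubjects(x))[i]
  if (anyNA(i)) stop("subject index out of range")
  new("ConnectomeCohort",
      connectomes   = x@connectomes[i],
      targets       = if (length(x@targets)) x@targets[i] else numeric(0),
      oracleTargets = if (length(x@oracleTargets)) x@oracleTargets[i]
                      else numeric(0),
      roiIndex      = x@roiIndex,
      regionLabels  = x@regionLabels,
      metadata      = x@metadata)
})

setMethod("show", "PropagationNetwork", function(object) {
  cat(sprintf("PropagationNetwork: %d regions, %d layer%s (%d-hop), %s\n",
              object@nRegions, object@nLayers,
              if (object@nLayers > 1L) "s" else "", object@nLayers,
              if (object@residual) "residual" else "plain"))
  cat(sprintf("  target region (ROI): %d\n", object@roiIndex))
  cat(sprintf("  parameters: %d per layer (W %dx%d + B %d)\n",
              object@nRegions^2 + object@nRegions,
              object@nRegions, object@nRegions, object@nRegions))
})

setMethod("show", "ConnectomeCohort", function(object) {
  cat(sprintf("ConnectomeCohort: %d subjects x %d regions (ROI %d)\n",
              nSubjects(object), nRegions(object), object@roiIndex))
  cat(sprintf("  targets: %s; oracle targets: %s\n",
              if (length(object@targets)) "present" else "absent",
              if (length(object@oracleTargets)) "present" else "absent"))
})

setMethod("show", "GaussianGammaFit", function(object) {
  cat("Gaussian-Gamma mixture fit\n")
  cat(sprintf("  pi (Gaussian weight) = %.4f\n", object@weightGauss))
  cat(sprintf("  Gaussian: mu = %.4f, sigma = %.4f\n",
              object@mu, object@sigma))
  cat(sprintf("  Gamma: shape = %.4f, scale = %.4f\n",
              object@shape, object@scale))
  cat(sprintf("  EM: %d iterations, %sconverged\n",
              length(object@loglikTrace),
              if (object@converged) "" else "NOT "))
})

setMethod("show", "PermutationResult", function(object) {
  cat(sprintf("Retrained permutation null (%d permutations)\n",
              length(object@nullNse)))
  cat(sprintf("  observed mean NSE %.4f vs null 1st percentile %.4f\n",
              object@observedMeanNse,
              object@percentile99Bounds[["nse_p01"]]))
  cat(sprintf("  observed mean r   %.4f vs null 99th percentile %.4f\n",
              object@observedMeanR, object@percentile99Bounds[["r_p99"]]))
})
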