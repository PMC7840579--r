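#' Number of regions
#' @param x a [PropagationNetwork-class] or [ConnectomeCohort-class].
#' @return integer scalar.
#' @export
setGeneric("nRegions", function(x) standardGeneric("nRegions"))

#' Number of layers (hop depth)
#' @param x a [PropagationNetwork-class].
#' @return integer scalar.
#' @export
setGeneric("nLayers", function(x) standardGeneric("nLayers"))

#' Index of the target region (ROI)
#' @param x a [PropagationNetwork-class] or [ConnectomeCohort-class].
#' @return integer scalar (1-based).
#' @export
setGeneric("roiIndex", function(x) standardGeneric("roiIndex"))

#' Number of subjects in a cohort
#' @param x a [ConnectomeCohort-class].
#' @return integer scalar.
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))

#' Per-subject connectivity matrices
#' @param x a [ConnectomeCohort-class].
#' @return list of n-by-n matrices.
#' @export
setGeneric("connectomes", function(x) standardGeneric("connectomes"))

#' Activation targets of a cohort
#' @param x a [ConnectomeCohort-class].
#' @return numeric vector (length 0 if targets are absent).
#' @export
setGeneric("targets", function(x) standardGeneric("targets"))

#' Replace the activation targets of a cohort
#' @param x a [ConnectomeCohort-class].
#' @param value numeric vector, one target per subject.
#' @return the modified cohort.
#' @export
setGeneric("targets<-", function(x, value) standardGeneric("targets<-"))

#' Run the propagation network forward
#'
#' Applies the K layers of a [PropagationNetwork-class] to the all-ones
#' dummy state, propagating through a subject's connectivity matrix, and
#' reads the prediction out of the ROI entry of the final state.
#'
#' @param net a [PropagationNetwork-class].
#' @param data an n-by-n connectivity matrix, or a
#'   [ConnectomeCohort-class] (one prediction per subject).
#' @return For a matrix: a list with `prediction` (scalar) and `state`
#'   (the length-n final state vector). For a cohort: a numeric vector of
#'   predictions, one per subject.
#' @examples
#' net <- initNetwork(5, nLayers = 2, roiIndex = 1, seed = 1)
#' A <- diag(5)
#' forwardPass(net, A)$prediction
#' @export
setGeneric("forwardPass", function(net, data) standardGeneric("forwardPass"))
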