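# Core edge-weighted propagation model: initialization, forward pass,
# coefficient extraction.

#' Initialize a propagation network
#'
#' Draws every propagation coefficient and bias from the Glorot (Xavier)
#' normal distribution scaled by `gain`: entries of each n-by-n `W` are
#' i.i.d. Normal with sd `gain * sqrt(2/(n + n))` (fan-in = fan-out = n),
#' and entries of each length-n bias `B` with sd `gain * sqrt(2/(n + 1))`
#' (fan-in 1, fan-out n). The default gain of 0.1 keeps the initial
#' propagation weak, so the dummy all-ones input passes through the
#' residual connections nearly unchanged at the start of training.
#'
#' @param nRegions number of regions n (>= 2).
#' @param nLayers number of layers K (the hop depth of the model).
#' @param roiIndex 1-based index of the target region.
#' @param gain Xavier gain; `0` gives exactly zero parameters.
#' @param residual logical; add a skip connection `+ X^{k-1}` in every layer.
#' @param seed integer; if non-`NULL`, `set.seed(seed)` is called first so
#'   the same seed reproduces the parameters bit-exactly.
#' @return a [PropagationNetwork-class].
#' @examples
#' net <- initNetwork(76, nLayers = 2, roiIndex = 10, seed = 1)
#' sd(extractPropagation(net, 1))  # about 0.1/sqrt(76)
#' @export
initNetwork <- function(nRegions, nLayers, roiIndex, gain = 0.1,
                        residual = TRUE, seed = NULL) {
  nRegions <- as.integer(nRegions)
  nLayers <- as.integer(nLayers)
  roiIndex <- as.integer(roiIndex)
  if (nRegions < 2L) stop("nRegions must be at least 2")
  if (nLayers < 1L) stop("nLayers must be at least 1")
  if (roiIndex < 1L || roiIndex > nRegions)
    stop(sprintf("roiIndex %d out of range [1, %d]", roiIndex, nRegions))
  if (!is.numeric(gain) || length(gain) != 1L || gain < 0)
    stop("gain must be a single non-negative number")
  if (!is.null(seed)) set.seed(seed)
  sdW <- gain * sqrt(2 / (nRegions + nRegions))
  sdB <- gain * sqrt(2 / (nRegions + 1))
  layers <- lapply(seq_len(nLayers), function(k) {
    list(W = matrix(rnorm(nRegions^2, sd = sdW), nRegions, nRegions),
         B = rnorm(nRegions, sd = sdB))
  })
  new("PropagationNetwork",
      nRegions = nRegions, nLayers = nLayers, roiIndex = roiIndex,
      residual = residual, layers = layers,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Apply one propagation layer
#'
#' Computes `(W * A) %*% x + B` (element-wise product `W * A`, then
#' matrix-vector product), adding the previous state when `residual` is
#' `TRUE`. Each region's new state is its W-weighted integration of its
#' neighbours' states over the connectivity matrix.
#'
#' @param W n-by-n propagation coefficients.
#' @param B length-n bias.
#' @param A n-by-n connectivity matrix.
#' @param xPrev length-n previous state.
#' @param residual logical; add `xPrev` to the output.
#' @return length-n next state.
#' @export
layerForward <- function(W, B, A, xPrev, residual = TRUE) {
  n <- length(xPrev)
  if (!is.matrix(W) || !identical(dim(W), c(n, n)))
    stop("W must be an n x n matrix conforming to xPrev")
  if (!is.matrix(A) || !identical(dim(A), dim(W)))
    stop("A must have the same dimensions as W")
  if (length(B) != n) stop("B must have length n")
  if (!all(is.finite(xPrev))) stop("xPrev must be finite")
  x <- as.vector((W * A) %*% xPrev) + B
  if (residual) x <- x + xPrev
  x
}

#' @rdname forwardPass
#' @export
setMethod("forwardPass", signature("PropagationNetwork", "matrix"),
  function(net, data) {
    n <- net@nRegions
    if (!identical(dim(data), c(n, n)))
      stop(sprintf("connectivity matrix must be %d x %d", n, n))
    if (!all(is.finite(data))) stop("connectivity matrix must be finite")
    x <- rep(1, n)
    for (k in seq_len(net@nLayers))
      x <- layerForward(net@layers[[k]]$W, net@layers[[k]]$B, data, x,
                        residual = net@residual)
    list(prediction = x[net@roiIndex], state = x)
  })

#' @rdname forwardPass
#' @export
setMethod("forwardPass", signature("PropagationNetwork", "ConnectomeCohort"),
  function(net, data) {
    if (nRegions(data) != net@nRegions)
      stop("cohort and network region counts differ")
    as.numeric(cppForwardCohort(.connArray(data@connectomes),
                                .weightCube(net), .biasMatrix(net),
                                net@residual, net@roiIndex - 1L))
  })

# stack a list of n x n matrices into an n x n x S array (S may be 1)
.connArray <- function(mats) {
  n <- nrow(mats[[1L]])
  array(unlist(mats, use.names = FALSE), c(n, n, length(mats)))
}

# layer parameters as the array layout the C++ routines expect
.weightCube <- function(net) {
  n <- net@nRegions
  arr <- array(0, c(n, n, net@nLayers))
  for (k in seq_len(net@nLayers)) arr[, , k] <- net@layers[[k]]$W
  arr
}

.biasMatrix <- function(net) {
  n <- net@nRegions
  B <- matrix(0, n, net@nLayers)
  for (k in seq_len(net@nLayers)) B[, k] <- net@layers[[k]]$B
  B
}

#' Extract a layer's propagation coefficient matrix
#'
#' Returns a copy of the trained coefficient matrix `W` of one layer. Row i
#' describes how region i integrates information from its neighbours;
#' column j describes how region j propagates information out to its
#' neighbours. The first layer is the one usually inspected: in a K-layer
#' network it carries the K-hop (most indirect) stage of the propagation.
#'
#' @param net a [PropagationNetwork-class].
#' @param layerIndex 1-based layer index.
#' @return an n-by-n matrix (a copy; modifying it does not touch the
#'   network).
#' @export
extractPropagation <- function(net, layerIndex = 1L) {
  layerIndex <- as.integer(layerIndex)
  if (layerIndex < 1L || layerIndex > net@nLayers)
    stop(sprintf("layerIndex %d out of range [1, %d]",
                 layerIndex, net@nLayers))
  net@layers[[layerIndex]]$W
}

#' Strongest propagation coefficients of a coefficient matrix
#'
#' Ranks all n^2 entries of `W` by absolute value and returns the top
#' `ceiling(fraction * n^2)` as an edge table. Following the row/column
#' semantics of the propagation model, the source region of an edge is the
#' column index (information sender) and the target region the row index
#' (information integrator). Ties in absolute value are broken by (row,
#' column) lexicographic order.
#'
#' @param W an n-by-n coefficient matrix.
#' @param fraction fraction of entries to keep, in (0, 1] (e.g. `0.01` for
#'   the top 1 percent).
#' @param labels optional character vector of n region names used to label
#'   sources and targets.
#' @return a `data.frame` with columns `source`, `target`, `coefficient`,
#'   ordered by decreasing `abs(coefficient)`.
#' @export
topEdges <- function(W, fraction = 0.01, labels = NULL) {
  if (!is.matrix(W) || nrow(W) != ncol(W) || nrow(W) == 0L)
    stop("W must be a non-empty square matrix")
  if (anyNA(W)) stop("W contains missing values")
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]")
  n <- nrow(W)
  m <- ceiling(fraction * n^2)
  row <- rep(seq_len(n), times = n)
  col <- rep(seq_len(n), each = n)
  ord <- order(-abs(as.vector(W)), row, col)[seq_len(m)]
  out <- data.frame(
    source = col[ord], target = row[ord],
    coefficient = as.vector(W)[ord])
  if (!is.null(labels)) {
    if (length(labels) != n) stop("labels must have length n")
    out$source <- labels[out$source]
    out$target <- labels[out$target]
  }
  out
}
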