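# Functional connectivity construction: standardize each run along time,
# concatenate, Pearson-correlate all region pairs, force the diagonal to 1.
# No thresholding and no global signal regression.

#' Demean and variance-normalize a run along time
#'
#' Each region's time series is transformed to mean 0 and unit (sample)
#' variance. This is the per-run normalization applied before runs are
#' concatenated.
#'
#' @param ts regions-by-timepoints numeric matrix (>= 2 timepoints).
#' @return matrix of the same shape with standardized rows.
#' @export
standardizeRun <- function(ts) {
  if (!is.matrix(ts) || ncol(ts) < 2L)
    stop("ts must be a regions x timepoints matrix with >= 2 timepoints")
  m <- rowMeans(ts)
  s <- apply(ts, 1L, sd)
  bad <- which(s < 1e-12)
  if (length(bad))
    stop(sprintf("region %d has a constant time series; cannot standardize",
                 bad[1L]))
  (ts - m) / s
}

#' Functional connectivity matrix from region-by-time runs
#'
#' Standardizes each run along time ([standardizeRun()]), concatenates the
#' runs, computes the Pearson correlation between every pair of region
#' series on the concatenated sample, and sets the diagonal to exactly 1.
#' The matrix is kept dense: no threshold is applied (weak direct edges
#' are left for the model to down-weight), and no global signal
#' regression is performed.
#'
#' @param runs a regions-by-timepoints matrix or a list of such matrices
#'   (all with the same region count).
#' @return an n-by-n symmetric correlation matrix with unit diagonal.
#' @export
connectivityMatrix <- function(runs) {
  if (is.matrix(runs)) runs <- list(runs)
  if (!length(runs)) stop("need at least one run")
  n <- nrow(runs[[1L]])
  if (any(vapply(runs, nrow, 0L) != n))
    stop("all runs must have the same region count")
  concat <- do.call(cbind, lapply(runs, standardizeRun))
  A <- cor(t(concat))
  A[A > 1] <- 1
  A[A < -1] <- -1
  A <- (A + t(A)) / 2
  diag(A) <- 1
  A
}
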