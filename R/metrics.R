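# Prediction metrics. NSE = SSE/SST is 0 at perfect individual prediction
# and about 1 for a model that only predicts the mean; Pearson r is 1 at
# perfect prediction. They coincide as NSE = 1 - r^2 only at the
# least-squares limit, so both are reported.

#' Normalized squared error
#'
#' `sum((y - yhat)^2) / sum((y - mean(y))^2)`. Unlike the raw SSE, the NSE
#' is comparable across test splits whose target variance differs.
#'
#' @param y observed targets (length >= 2, not constant).
#' @param yhat predictions (same length).
#' @return NSE, a non-negative scalar; 0 iff prediction is perfect.
#' @examples
#' nse(c(1, 2, 3), c(1, 2, 4))  # SSE 1 / SST 2 = 0.5
#' @export
nse <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("y and yhat must have equal length")
  if (length(y) < 2L) stop("need at least 2 observations")
  sst <- sum((y - mean(y))^2)
  if (sst < 1e-12)
    stop("y is (numerically) constant: NSE denominator undefined")
  sum((y - yhat)^2) / sst
}

#' Pearson correlation between observed and predicted values
#'
#' Standard product-moment correlation across subjects; errors on constant
#' input rather than returning `NA`, since a constant prediction vector
#' signals a degenerate model.
#'
#' @param y observed targets (length >= 3).
#' @param yhat predictions.
#' @return correlation in \[-1, 1\].
#' @export
pearsonR <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("y and yhat must have equal length")
  if (length(y) < 3L) stop("need at least 3 observations")
  if (sd(y) < 1e-12) stop("y is constant: correlation undefined")
  if (sd(yhat) < 1e-12)
    stop("yhat is constant: correlation undefined (degenerate model output)")
  cor(y, yhat)
}

#' Fisher z transform
#'
#' `atanh(r)`, the variance-stabilizing transform applied to correlations
#' before t-tests.
#'
#' @param r correlation(s) with `abs(r) < 1`.
#' @return transformed value(s).
#' @export
fisherZ <- function(r) {
  if (any(abs(r) >= 1)) stop("fisherZ requires |r| < 1")
  atanh(r)
}

#' Paired-sample t-test for split-matched metrics
#'
#' Two-sided paired t-test between two metric vectors paired by evaluation
#' split; df = n - 1. Correlations should be Fisher-z transformed by the
#' caller before testing ([fisherZ()]); NSE values are compared raw.
#' Identical vectors (zero-variance differences) are an error, since the t
#' statistic is then undefined.
#'
#' @param a,b equal-length metric vectors, paired by split.
#' @return list with elements `t`, `p`, `df`.
#' @export
pairedT <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  if (length(a) < 2L) stop("need at least 2 pairs")
  if (sd(a - b) < 1e-12)
    stop("paired differences have zero variance: t statistic undefined")
  ht <- t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter))
}
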