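# Gaussian-Gamma mixture thresholding of regionwise mean absolute
# activations, used to select the task-activation network before any model
# training (selection is independent of the propagation network, whose
# input is a dummy ones vector).

#' Mean absolute activation per region
#'
#' Per-region mean of the absolute activation across subjects. Taking the
#' absolute value first prevents individual differences with opposite
#' signs from cancelling.
#'
#' @param activations subjects-by-regions numeric matrix.
#' @return non-negative numeric vector, one value per region.
#' @export
meanAbsActivation <- function(activations) {
  if (!is.matrix(activations) || nrow(activations) < 1L ||
      ncol(activations) < 1L)
    stop("activations must be a non-empty subjects x regions matrix")
  colMeans(abs(activations))
}

# mixture log-likelihood pieces; x > 0 throughout
.ggLogDens <- function(x, pi0, mu, sigma, shape, scale) {
  la <- log(pi0) + dnorm(x, mu, sigma, log = TRUE)
  lb <- log1p(-pi0) + dgamma(x, shape = shape, scale = scale, log = TRUE)
  m <- pmax(la, lb)
  list(ll = m + log(exp(la - m) + exp(lb - m)), la = la)
}

# weighted Gamma MLE: Newton on log(shape) - digamma(shape) = s
.gammaWeightedMle <- function(x, w) {
  sw <- sum(w)
  wm <- sum(w * x) / sw
  wml <- sum(w * log(x)) / sw
  s <- log(wm) - wml          # >= 0 by Jensen
  if (s < 1e-9) return(list(shape = 1e6, scale = wm / 1e6))
  a <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  for (it in 1:50) {
    f <- log(a) - digamma(a) - s
    fp <- 1 / a - trigamma(a)
    step <- f / fp
    aNew <- a - step
    if (aNew <= 0) aNew <- a / 2
    if (abs(aNew - a) < 1e-12 * a) { a <- aNew; break }
    a <- aNew
  }
  list(shape = a, scale = wm / a)
}

# moment-based initialization: split at a quantile, Gaussian below,
# Gamma above
.ggInit <- function(x, q = 0.5) {
  cut <- quantile(x, q, names = FALSE)
  lo <- x[x <= cut]
  hi <- x[x > cut]
  if (length(lo) < 2L || length(hi) < 2L)
    stop("cannot initialize mixture: degenerate split of the data")
  m <- mean(hi); v <- var(hi)
  list(pi0 = length(lo) / length(x),
       mu = mean(lo), sigma = max(sd(lo), 1e-3),
       shape = max(m^2 / v, 0.1), scale = max(v / m, 1e-6))
}

#' Fit a Gaussian + Gamma mixture by EM
#'
#' Models positive activation magnitudes as a weighted sum of a Gaussian
#' (the null/noise component) and a Gamma (the activated component),
#' fitted by expectation-maximization. The E-step computes component
#' responsibilities; the M-step updates the mixing weight and Gaussian
#' parameters in closed form and solves the weighted Gamma likelihood for
#' the shape by Newton iterations on the digamma equation (scale is then
#' closed-form). Initialization is a deterministic moment-based split at
#' the median; a collapsing Gaussian component (sigma below 1e-6) triggers
#' up to 3 restarts from randomized quantile splits before erroring.
#'
#' The Gaussian component is fitted without truncation correction even
#' though the data are positive; this is a documented approximation.
#'
#' @param values positive numeric vector, length >= 10.
#' @param tol EM stops when the log-likelihood gain drops below `tol`.
#' @param maxIter iteration cap.
#' @param seed optional seed (only consumed if a restart is needed).
#' @return a [GaussianGammaFit-class].
#' @export
fitGaussianGamma <- function(values, tol = 1e-6, maxIter = 500L,
                             seed = NULL) {
  x <- as.numeric(values)
  if (length(x) < 10L) stop("need at least 10 values to fit the mixture")
  if (any(!is.finite(x)) || any(x <= 0))
    stop("all values must be positive and finite (Gamma support)")
  if (!is.null(seed)) set.seed(seed)
  for (attempt in 0:3) {
    par <- if (attempt == 0) .ggInit(x)
           else .ggInit(x, q = runif(1, 0.3, 0.7))
    fit <- tryCatch(.ggEm(x, par, tol, maxIter),
                    error = function(e) e)
    if (!inherits(fit, "error")) return(fit)
    collapse <- grepl("collapsed", conditionMessage(fit), fixed = TRUE)
    if (!collapse || attempt == 3)
      stop("mixture fit failed: ", conditionMessage(fit))
  }
}

.ggEm <- function(x, par, tol, maxIter) {
  pi0 <- min(max(par$pi0, 1e-4), 1 - 1e-4)
  mu <- par$mu; sigma <- par$sigma
  shape <- par$shape; scale <- par$scale
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    d <- .ggLogDens(x, pi0, mu, sigma, shape, scale)
    ll <- sum(d$ll)
    if (!is.finite(ll)) stop("log-likelihood became non-finite")
    trace <- c(trace, ll)
    if (it > 1L && ll - trace[it - 1L] < tol) { converged <- TRUE; break }
    r <- exp(d$la - d$ll)                     # Gaussian responsibility
    sr <- sum(r)
    if (sr < 1e-8 || sum(1 - r) < 1e-8)
      stop("a mixture component collapsed (vanishing responsibility)")
    pi0 <- min(max(sr / length(x), 1e-6), 1 - 1e-6)
    mu <- sum(r * x) / sr
    sigma <- sqrt(sum(r * (x - mu)^2) / sr)
    if (sigma < 1e-6) stop("Gaussian component collapsed (sigma -> 0)")
    g <- .gammaWeightedMle(x, 1 - r)
    shape <- g$shape; scale <- g$scale
  }
  new("GaussianGammaFit", weightGauss = pi0, mu = mu, sigma = sigma,
      shape = shape, scale = scale, loglikTrace = trace,
      converged = converged)
}

#' Mixture density of a Gaussian-Gamma fit
#'
#' `pi * dnorm + (1 - pi) * dgamma` evaluated at `x` (the Gamma component
#' contributes 0 for `x <= 0`).
#'
#' @param fit a [GaussianGammaFit-class].
#' @param x numeric vector.
#' @return density values.
#' @export
mixtureDensity <- function(fit, x) {
  fit@weightGauss * dnorm(x, fit@mu, fit@sigma) +
    (1 - fit@weightGauss) *
      ifelse(x > 0, dgamma(x, shape = fit@shape, scale = fit@scale), 0)
}

#' Activation threshold from a fitted mixture
#'
#' The threshold is the point above which the (by default weighted) Gamma
#' density dominates the Gaussian density: the smallest grid point x such
#' that `(1-pi) * dgamma >= pi * dnorm` at x and at every larger grid
#' point, refined by root finding between the bracketing grid points. The
#' grid spans `searchRange` with `nGrid` points (default 4096), so the
#' scan resolution is `diff(searchRange)/(nGrid-1)`.
#'
#' With `weighted = FALSE` the unweighted component densities are compared
#' instead (a configuration switch; the weighted comparison is the
#' default, since the fitted object is a weighted sum).
#'
#' @param fit a [GaussianGammaFit-class].
#' @param searchRange length-2 numeric; defaults to `[1e-6, mu + 10 sigma
#'   or the 0.9999 Gamma quantile, whichever is larger]`.
#' @param nGrid number of grid points.
#' @param weighted compare weighted (`TRUE`) or raw component densities.
#' @return the threshold (smallest x of Gamma dominance).
#' @export
activationThreshold <- function(fit, searchRange = NULL, nGrid = 4096L,
                                weighted = TRUE) {
  if (is.null(searchRange))
    searchRange <- c(1e-6,
                     max(fit@mu + 10 * fit@sigma,
                         qgamma(0.9999, shape = fit@shape,
                                scale = fit@scale)))
  if (length(searchRange) != 2L || searchRange[1] >= searchRange[2])
    stop("searchRange must be an increasing pair")
  grid <- seq(searchRange[1], searchRange[2], length.out = nGrid)
  wG <- if (weighted) 1 - fit@weightGauss else 1
  wN <- if (weighted) fit@weightGauss else 1
  d <- wG * dgamma(grid, shape = fit@shape, scale = fit@scale) -
       wN * dnorm(grid, fit@mu, fit@sigma)
  dominated <- rev(cumprod(rev(d >= 0))) == 1  # TRUE from i to the end
  if (!dominated[nGrid])
    stop("no crossing: the Gamma density never dominates at the top of ",
         "the search range (components not separated?)")
  i <- which(dominated)[1L]
  if (i == 1L) return(searchRange[1])
  f <- function(x) wG * dgamma(x, shape = fit@shape, scale = fit@scale) -
                   wN * dnorm(x, fit@mu, fit@sigma)
  root <- tryCatch(
    uniroot(f, lower = grid[i - 1L], upper = grid[i], tol = 1e-10)$root,
    error = function(e) grid[i])
  # a crossing beyond virtually all of the Gamma component's mass is a
  # tail artifact of two overlapping components, not a genuine boundary
  # between noise and activation
  if (wN > 1e-6 &&
      root > qgamma(0.999, shape = fit@shape, scale = fit@scale))
    stop("the density crossing lies beyond the activated (Gamma) ",
         "component's mass: components not separated")
  root
}

#' Select the task-activation network above a threshold
#'
#' Keeps the regions whose mean absolute activation exceeds `threshold`
#' (order preserved) and slices every subject's connectivity matrix to the
#' selected rows and columns. The target region must survive the
#' selection; a task network that excludes its own ROI is an error.
#'
#' @param values per-region mean absolute activations ([meanAbsActivation()]).
#' @param threshold activation threshold ([activationThreshold()]).
#' @param cohort a [ConnectomeCohort-class] whose matrices are sliced; its
#'   `roiIndex` is remapped into the reduced network.
#' @return list with `selection` (a list: `threshold`, `selectedIndices`,
#'   `nSelected`) and `cohort` (the reduced [ConnectomeCohort-class]).
#' @export
selectNetwork <- function(values, threshold, cohort) {
  if (!is.finite(threshold)) stop("threshold must be finite")
  if (length(values) != nRegions(cohort))
    stop("values length must equal the cohort's region count")
  keep <- which(values > threshold)
  if (length(keep) == 0L)
    stop("threshold excludes every region (empty network)")
  roi <- roiIndex(cohort)
  if (!(roi %in% keep))
    stop("the target region (ROI) falls below the activation threshold; ",
         "it must belong to its own task network")
  mats <- lapply(connectomes(cohort),
                 function(A) A[keep, keep, drop = FALSE])
  reduced <- new("ConnectomeCohort",
                 connectomes = mats,
                 targets = targets(cohort),
                 oracleTargets = cohort@oracleTargets,
                 roiIndex = match(roi, keep),
                 regionLabels = if (length(cohort@regionLabels))
                                  cohort@regionLabels[keep]
                                else character(0),
                 metadata = cohort@metadata)
  list(selection = list(threshold = threshold, selectedIndices = keep,
                        nSelected = length(keep)),
       cohort = reduced)
}
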