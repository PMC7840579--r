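# SGD training with the published schedule and on-line connectivity-noise
# augmentation.

#' Training configuration
#'
#' Defaults reproduce the published schedule: minibatch SGD with Nesterov
#' momentum 0.9, batch size 128, 500 epochs, initial learning rate 0.01
#' decayed by a factor of 0.1 at epochs 300 and 400, and on-line Gaussian
#' noise added to every connectivity feature at each training step with the
#' feature's across-subject standard deviation.
#'
#' @param batchSize minibatch size.
#' @param epochs number of passes over the training cohort.
#' @param lr0 initial learning rate.
#' @param momentum Nesterov momentum coefficient.
#' @param decayFactor multiplicative learning-rate decay.
#' @param decayEpochs 0-based epochs at which the decay is applied; must be
#'   strictly increasing and below `epochs`.
#' @param augment logical; perturb each connectivity feature at every step
#'   with Gaussian noise scaled to its across-subject standard deviation.
#' @param seed integer seed for shuffling and augmentation noise.
#' @return a list of class `trainingConfig`.
#' @export
trainingConfig <- function(batchSize = 128L, epochs = 500L, lr0 = 0.01,
                           momentum = 0.9, decayFactor = 0.1,
                           decayEpochs = c(300L, 400L), augment = TRUE,
                           seed = 1L) {
  decayEpochs <- as.integer(decayEpochs)
  epochs <- as.integer(epochs)
  if (epochs < 0L) stop("epochs must be non-negative")
  if (length(decayEpochs) &&
      (is.unsorted(decayEpochs, strictly = TRUE) ||
       any(decayEpochs >= epochs) || any(decayEpochs < 0L)))
    stop("decayEpochs must be strictly increasing and within [0, epochs)")
  structure(list(batchSize = as.integer(batchSize), epochs = epochs,
                 lr0 = lr0, momentum = momentum, decayFactor = decayFactor,
                 decayEpochs = decayEpochs, augment = isTRUE(augment),
                 seed = as.integer(seed)),
            class = "trainingConfig")
}

#' Learning rate at a given epoch
#'
#' `lr0 * decayFactor^m` where `m` is the number of decay epochs at or
#' before `epoch` (0-based). With the defaults: 0.01 up to epoch 299,
#' 0.001 from 300, 0.0001 from 400.
#'
#' @param config a [trainingConfig()].
#' @param epoch 0-based epoch index in `[0, epochs)`.
#' @return the learning rate.
#' @export
lrAt <- function(config, epoch) {
  if (epoch < 0 || epoch >= config$epochs)
    stop(sprintf("epoch %d out of range [0, %d)", epoch, config$epochs))
  config$lr0 * config$decayFactor^sum(config$decayEpochs <= epoch)
}

#' Across-subject standard deviation of each connectivity feature
#'
#' The edge-noise model for on-line augmentation: entry (i, j) is the
#' sample standard deviation (denominator S - 1) of the subjects'
#' connectivity values at edge (i, j). Features that are constant across
#' subjects -- in particular the unit diagonal -- get sd 0 and are never
#' perturbed.
#'
#' @param cohort a [ConnectomeCohort-class] (or plain list of matrices)
#'   with at least 2 subjects.
#' @return an n-by-n matrix of standard deviations, class `edgeNoiseModel`.
#' @export
edgewiseSd <- function(cohort) {
  mats <- if (is(cohort, "ConnectomeCohort")) connectomes(cohort) else cohort
  S <- length(mats)
  if (S < 2L) stop("edgewiseSd needs at least 2 subjects")
  n <- nrow(mats[[1L]])
  M <- vapply(mats, as.vector, numeric(n * n))   # (n^2) x S
  rm <- rowMeans(M)
  v <- (rowSums(M^2) - S * rm^2) / (S - 1)
  sdMat <- matrix(sqrt(pmax(v, 0)), n, n)
  structure(sdMat, class = c("edgeNoiseModel", "matrix"))
}

#' Perturb connectivity matrices with the edge-noise model
#'
#' Adds an independent Normal(0, sd^2) (entrywise) draw to every entry of every
#' subject's matrix; entries with sd 0 (the diagonal, and any feature
#' constant across training subjects) are left untouched. Fresh draws are
#' made at every call (on-line augmentation); the same `seed` reproduces
#' the same perturbation.
#'
#' @param mats list of n-by-n matrices (a minibatch of connectomes).
#' @param noise an n-by-n sd matrix from [edgewiseSd()].
#' @param seed optional integer seed.
#' @return list of perturbed matrices (no longer valid correlation
#'   matrices; they are training-time features, not estimates).
#' @export
augmentConnectomes <- function(mats, noise, seed = NULL) {
  if (any(noise < 0)) stop("noise sd must be non-negative")
  n <- nrow(noise)
  if (!is.null(seed)) set.seed(seed)
  lapply(mats, function(A) {
    if (!identical(dim(A), dim(noise))) stop("shape mismatch")
    A + matrix(rnorm(n * n), n, n) * unclass(noise)
  })
}

#' Train a propagation network on a cohort
#'
#' Minibatch SGD with Nesterov momentum on the NSE loss: within each batch
#' the squared prediction error at the ROI is normalized by the batch's
#' total sum of squares around the batch mean target. Subjects are
#' reshuffled every epoch; when `config$augment` is `TRUE`, every
#' connectivity feature of every batch subject is perturbed at each step by
#' Gaussian noise with that feature's across-subject standard deviation in
#' the training cohort. The last incomplete batch is kept. All randomness
#' is governed by `config$seed`, so a fixed seed gives a bit-identical loss
#' trace and parameters.
#'
#' @param net an initialized [PropagationNetwork-class].
#' @param cohort training [ConnectomeCohort-class] with targets.
#' @param config a [trainingConfig()].
#' @return list with `network` (the trained [PropagationNetwork-class]) and
#'   `loss` (per-epoch mean batch loss).
#' @export
trainNetwork <- function(net, cohort, config = trainingConfig()) {
  if (!is(net, "PropagationNetwork")) stop("net must be a PropagationNetwork")
  if (!is(cohort, "ConnectomeCohort")) stop("cohort must be a ConnectomeCohort")
  if (nRegions(cohort) != net@nRegions)
    stop("cohort and network region counts differ")
  S <- nSubjects(cohort)
  if (S < 2L) stop("training needs at least 2 subjects")
  if (length(targets(cohort)) != S) stop("cohort has no targets to fit")
  if (S %% config$batchSize == 1L)
    stop("cohort size modulo batchSize is 1; a singleton batch has an ",
         "undefined NSE loss -- choose a different batchSize")
  if (config$epochs == 0L)
    return(list(network = net, loss = numeric(0)))
  sdMat <- if (config$augment) unclass(edgewiseSd(cohort))
           else matrix(0, net@nRegions, net@nRegions)
  arr <- .connArray(connectomes(cohort))
  set.seed(config$seed)
  fit <- cppTrain(arr, targets(cohort), .weightCube(net), .biasMatrix(net),
                  net@residual, net@roiIndex - 1L,
                  config$batchSize, config$epochs, config$lr0,
                  config$momentum, config$decayFactor, config$decayEpochs,
                  config$augment, sdMat)
  for (k in seq_len(net@nLayers)) {
    net@layers[[k]]$W <- fit$W[, , k, drop = TRUE]
    net@layers[[k]]$B <- fit$B[, k]
  }
  if (net@nLayers == 1L && !is.matrix(net@layers[[1L]]$W))
    net@layers[[1L]]$W <- matrix(net@layers[[1L]]$W, net@nRegions)
  validObject(net)
  list(network = net, loss = as.numeric(fit$loss))
}

# loss and analytic gradients on one batch; used by the gradient tests
.lossGrad <- function(net, mats, y) {
  arr <- .connArray(mats)
  cppLossGrad(arr, y, .weightCube(net), .biasMatrix(net),
              net@residual, net@roiIndex - 1L)
}
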