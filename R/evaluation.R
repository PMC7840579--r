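# Repeated-split evaluation protocol, depth comparison, and the retrained
# permutation null.

#' Model specification for evaluation experiments
#'
#' Bundles the architecture and training settings that the evaluation
#' protocol re-instantiates on every split: hop depth (number of layers),
#' residual flag, Xavier gain, and the [trainingConfig()].
#'
#' @param nLayers hop depth K of the network.
#' @param residual logical; residual connections in every layer.
#' @param gain Xavier initialization gain.
#' @param config a [trainingConfig()].
#' @param tag label used in evaluation records; defaults to e.g. `"2-layer"`.
#' @return a list of class `modelSpec`.
#' @export
modelSpec <- function(nLayers, residual = TRUE, gain = 0.1,
                      config = trainingConfig(), tag = NULL) {
  if (is.null(tag)) tag <- sprintf("%d-layer", nLayers)
  structure(list(nLayers = as.integer(nLayers), residual = isTRUE(residual),
                 gain = gain, config = config, tag = tag),
            class = "modelSpec")
}

#' Random train/test division of a cohort
#'
#' Draws a uniformly random test set of `round(testFraction * N)` subjects
#' (the 9:1 protocol by default) and returns disjoint, exhaustive train and
#' test cohorts. Reproducible given `seed`.
#'
#' @param cohort a [ConnectomeCohort-class] with at least 10 subjects.
#' @param testFraction fraction of subjects held out.
#' @param seed integer seed.
#' @return list with `train`, `test` (cohorts) and `trainIndices`,
#'   `testIndices`.
#' @export
splitCohort <- function(cohort, testFraction = 0.1, seed = 1L) {
  S <- nSubjects(cohort)
  if (S < 10L) stop("cohort must have at least 10 subjects to split")
  nTest <- round(testFraction * S)
  if (nTest < 1L || nTest >= S) stop("testFraction leaves an empty set")
  set.seed(seed)
  testIdx <- sort(sample.int(S, nTest))
  trainIdx <- setdiff(seq_len(S), testIdx)
  list(train = cohort[trainIdx], test = cohort[testIdx],
       trainIndices = trainIdx, testIndices = testIdx)
}

# one split -> train -> test cycle; the building block of the protocol
.evaluateOnce <- function(cohort, spec, seed, testFraction = 0.1) {
  sp <- splitCohort(cohort, testFraction = testFraction, seed = seed)
  net <- initNetwork(nRegions(cohort), spec$nLayers, roiIndex(cohort),
                     gain = spec$gain, residual = spec$residual, seed = seed)
  cfg <- spec$config
  cfg$seed <- seed
  fit <- trainNetwork(net, sp$train, cfg)
  yhat <- forwardPass(fit$network, sp$test)
  y <- targets(sp$test)
  list(nse = nse(y, yhat), r = pearsonR(y, yhat), network = fit$network)
}

#' Repeated random-split evaluation of a model
#'
#' Runs the full prediction process `nRepeats` times with different random
#' 9:1 divisions of the cohort: split, initialize, train, predict on the
#' held-out subjects, and record test NSE and Pearson r. Per-repeat seeds
#' are derived deterministically as `baseSeed + split_id`, so two models
#' evaluated with the same `baseSeed` see identical divisions and their
#' records are paired by `split_id` for paired t-tests.
#'
#' @param cohort a [ConnectomeCohort-class] with targets.
#' @param spec a [modelSpec()].
#' @param nRepeats number of random divisions.
#' @param baseSeed integer; seed origin for all repeats.
#' @param testFraction held-out fraction per division.
#' @return a `data.frame` with columns `split_id`, `model_tag`, `nse`, `r`.
#' @export
repeatedEvaluation <- function(cohort, spec, nRepeats = 100L, baseSeed = 1L,
                               testFraction = 0.1) {
  if (nRepeats < 1L) stop("nRepeats must be at least 1")
  rows <- lapply(seq_len(nRepeats), function(i) {
    res <- tryCatch(
      .evaluateOnce(cohort, spec, seed = baseSeed + i,
                    testFraction = testFraction),
      error = function(e) stop(sprintf("split %d: %s", i, conditionMessage(e)),
                               call. = FALSE))
    data.frame(split_id = i, model_tag = spec$tag, nse = res$nse, r = res$r)
  })
  do.call(rbind, rows)
}

#' Compare propagation networks of different depths
#'
#' Evaluates one model per requested depth with [repeatedEvaluation()]
#' under a shared `baseSeed` (so all depths see the same random divisions),
#' then tests each consecutive pair of depths with paired t-tests: raw NSE,
#' and Fisher-z transformed correlations.
#'
#' @param cohort a [ConnectomeCohort-class] with targets.
#' @param depths integer vector of layer counts to compare.
#' @param nRepeats random divisions per depth.
#' @param baseSeed shared seed origin.
#' @param residual,gain,config passed to each depth's [modelSpec()].
#' @param testFraction held-out fraction.
#' @return list with `records` (all evaluation rows), `summary` (per-depth
#'   mean NSE and mean r), and `comparisons` (per consecutive depth pair:
#'   t, p, df for NSE and for Fisher-z r).
#' @export
compareDepths <- function(cohort, depths = c(1L, 2L, 3L), nRepeats = 10L,
                          baseSeed = 1L, residual = TRUE, gain = 0.1,
                          config = trainingConfig(), testFraction = 0.1) {
  depths <- as.integer(depths)
  recs <- lapply(depths, function(K)
    repeatedEvaluation(cohort,
                       modelSpec(K, residual = residual, gain = gain,
                                 config = config),
                       nRepeats = nRepeats, baseSeed = baseSeed,
                       testFraction = testFraction))
  names(recs) <- sprintf("%d-layer", depths)
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  summary <- data.frame(
    model_tag = names(recs),
    depth = depths,
    mean_nse = vapply(recs, function(r) mean(r$nse), numeric(1)),
    mean_r = vapply(recs, function(r) mean(r$r), numeric(1)),
    row.names = NULL)
  comparisons <- NULL
  if (length(depths) > 1L) {
    cmp <- lapply(seq_len(length(depths) - 1L), function(i) {
      a <- recs[[i]]; b <- recs[[i + 1L]]
      tn <- pairedT(b$nse, a$nse)
      tr <- pairedT(fisherZ(b$r), fisherZ(a$r))
      data.frame(pair = sprintf("%d-layer vs %d-layer",
                                depths[i + 1L], depths[i]),
                 t_nse = tn$t, p_nse = tn$p,
                 t_z = tr$t, p_z = tr$p, df = tn$df)
    })
    comparisons <- do.call(rbind, cmp)
  }
  list(records = records, summary = summary, comparisons = comparisons)
}

# nearest-rank empirical percentile (q in (0, 1])
.nearestRankPercentile <- function(x, q) {
  sort(x)[max(1L, ceiling(q * length(x)))]
}

#' Retrained permutation null for the prediction model
#'
#' Shuffles the pairing between connectivity matrices and activation
#' targets across all subjects, then re-trains the same architecture on the
#' shuffled cohort and evaluates it on one held-out split -- once per
#' permutation -- building null distributions of test NSE and test r. The
#' observed (unpermuted) model's mean metrics over `nObservedRepeats`
#' divisions are compared against the null's nearest-rank percentiles:
#' since lower NSE is better, the observed mean NSE is compared to the
#' null's 1st percentile, and the observed mean r to the null's 99th.
#'
#' @param cohort a [ConnectomeCohort-class] with targets.
#' @param spec a [modelSpec()].
#' @param nPermutations number of target shuffles (each retrained).
#' @param seed integer seed governing shuffles, splits and training.
#' @param nObservedRepeats random divisions used for the observed model's
#'   mean metrics.
#' @param testFraction held-out fraction.
#' @return a [PermutationResult-class].
#' @export
permutationTest <- function(cohort, spec, nPermutations = 1000L, seed = 1L,
                            nObservedRepeats = 10L, testFraction = 0.1) {
  if (nPermutations < 1L) stop("nPermutations must be at least 1")
  obs <- repeatedEvaluation(cohort, spec, nRepeats = nObservedRepeats,
                            baseSeed = seed, testFraction = testFraction)
  nullNse <- numeric(nPermutations)
  nullR <- numeric(nPermutations)
  for (p in seq_len(nPermutations)) {
    permSeed <- seed + 100000L + p
    set.seed(permSeed)
    shuffled <- cohort
    targets(shuffled) <- sample(targets(cohort))
    res <- tryCatch(
      .evaluateOnce(shuffled, spec, seed = permSeed,
                    testFraction = testFraction),
      error = function(e)
        stop(sprintf("permutation %d: %s", p, conditionMessage(e)),
             call. = FALSE))
    nullNse[p] <- res$nse
    nullR[p] <- res$r
  }
  new("PermutationResult",
      nullNse = nullNse, nullR = nullR,
      observedMeanNse = mean(obs$nse), observedMeanR = mean(obs$r),
      percentile99Bounds = c(
        nse_p01 = .nearestRankPercentile(nullNse, 0.01),
        r_p99 = .nearestRankPercentile(nullR, 0.99)))
}

#' Write an evaluation-record table as delimited text
#'
#' Adds a Fisher-z column and writes tab-separated text with columns
#' `split_id`, `model_tag`, `nse`, `r`, `z`.
#'
#' @param records a `data.frame` from [repeatedEvaluation()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeEvaluationRecords <- function(records, path) {
  records$z <- fisherZ(records$r)
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
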