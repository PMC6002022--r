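#' Seeded k-fold split
#'
#' A seeded uniform random permutation of `1..n` is cut into k folds of
#' near-equal size: `n %/% k` each, with the remainder distributed to the
#' first `n %% k` folds (so 999 samples in 5 folds give sizes
#' 200, 200, 200, 200, 199). No stratification is applied by default.
#'
#' @param n total sample count.
#' @param k fold count, `2 <= k <= n`.
#' @param seed integer seed.
#' @param stratifyBy optional vector of length n; when given, samples are
#'   permuted within strata before assignment so each fold receives a
#'   near-proportional share of every stratum.
#' @return a [FoldPlan].
#' @export
makeFolds <- function(n, k, seed = 1L, stratifyBy = NULL) {
  n <- as.integer(n); k <- as.integer(k)
  if (k > n) stop("more folds than samples")
  if (k < 2L) stop("need at least two folds")
  set.seed(seed)
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  foldOf <- rep(seq_len(k), sizes)
  assignment <- integer(n)
  if (is.null(stratifyBy)) {
    assignment[sample.int(n)] <- foldOf
  } else {
    stopifnot(length(stratifyBy) == n)
    ord <- unlist(lapply(split(seq_len(n), stratifyBy),
                         function(ix) ix[sample.int(length(ix))]),
                  use.names = FALSE)
    # deal round-robin down the shuffled strata so shares stay proportional
    assignment[ord] <- rep_len(seq_len(k), n)
  }
  new("FoldPlan", n = n, k = k, assignment = assignment, seed = as.integer(seed))
}

#' Fold membership accessor
#' @param plan a [FoldPlan].
#' @param fold fold index in `1..k`.
#' @return integer indices of the samples held out in `fold`.
#' @export
foldIndices <- function(plan, fold) {
  stopifnot(is(plan, "FoldPlan"))
  which(plan@assignment == fold)
}

#' Pooled true-positive / true-negative rates
#'
#' Counts are pooled over every (chemical, cluster) cell:
#' `tpRate = 100 * #(pred=1 & truth=1) / #(truth=1)` and
#' `tnRate = 100 * #(pred=0 & truth=0) / #(truth=0)`, so the two columns of
#' the confusion table each sum to 100%. A rate whose truth class is empty
#' is reported as NA, never as 0.
#'
#' @param pred,truth binary matrices (or vectors) of identical shape.
#' @return a [ConfusionRates].
#' @export
confusionRates <- function(pred, truth) {
  pred <- as.matrix(pred); truth <- as.matrix(truth)
  if (!identical(dim(pred), dim(truth))) stop("shape mismatch")
  if (!all(pred %in% c(0, 1)) || !all(truth %in% c(0, 1)))
    stop("inputs must be binary")
  tp <- sum(pred == 1 & truth == 1); fn <- sum(pred == 0 & truth == 1)
  tn <- sum(pred == 0 & truth == 0); fp <- sum(pred == 1 & truth == 0)
  npos <- tp + fn; nneg <- tn + fp
  counts <- matrix(as.integer(c(tp, fn, fp, tn)), 2L, 2L,
                   dimnames = list(pred = c("1", "0"), truth = c("1", "0")))
  rate <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  new("ConfusionRates",
      tpRate = rate(tp, npos), fnRate = rate(fn, npos),
      tnRate = rate(tn, nneg), fpRate = rate(fp, nneg),
      counts = counts)
}

default_pipeline_configs <- function(d, K, seed = 1L, scale = "desk") {
  if (scale == "reference") {
    aeLayers <- c(d, 85L, 30L, 85L, d)
    mapperLayers <- c(30L, 50L, 20L, K)
    ep <- c(ae = 1e6, map = 5e5, ft = 1000)
    decay <- 0.99
  } else {
    bott <- max(2L, min(10L, d %/% 4L))
    hid <- max(bott + 2L, d %/% 2L)
    aeLayers <- c(d, hid, bott, hid, d)
    mapperLayers <- c(bott, 20L, 12L, K)
    # at ~10^3 epochs a 0.99 decay exhausts the cumulative learning-rate
    # budget before the autoencoder escapes the constant-output solution;
    # 0.999 spreads the same geometric schedule over the shorter run
    ep <- c(ae = 1200, map = 2000, ft = 150)
    decay <- 0.999
  }
  list(
    aeLayers = aeLayers,
    mapperLayers = mapperLayers,
    autoencoder = trainingConfig(eta0 = 0.5, alpha0 = 0.3, decay = decay,
                                 lam = 3e-7, epochs = ep["ae"], seed = seed),
    mapper = trainingConfig(eta0 = 0.3, alpha0 = 0.1, decay = decay,
                            lam = 2e-7, epochs = ep["map"], seed = seed + 1L),
    finetune = trainingConfig(eta0 = 0.3, alpha0 = 0.1, decay = decay,
                              lam = 2e-7, epochs = ep["ft"], seed = seed + 2L))
}

#' Default hyperparameter blocks for the predictive pipeline
#'
#' `scale = "reference"` reproduces the published architecture and epoch
#' counts for 212-bin spectra (autoencoder `[212, 85, 30, 85, 212]` with
#' 1e6 epochs, mapper `[30, 50, 20, K]` with 5e5 epochs, 1000 fine-tuning
#' epochs, schedules `eta_M = 0.5 * 0.99^tau`, `eta_p = 0.3 * 0.99^tau`,
#' `alpha_M = 0.3 * 0.99^tau`, `alpha_p = 0.1 * 0.99^tau`, `lambda_M =
#' 3e-7`, `lambda_p = 2e-7`, L2). These counts are far beyond interactive
#' use; `scale = "desk"` keeps the same schedules and shrinks architecture
#' and epochs to workstation size (the vignette discusses the choice).
#'
#' @param d input (spectrum) width.
#' @param K number of output clusters.
#' @param seed integer seed; the three blocks derive their seeds from it.
#' @param scale `"desk"` or `"reference"`.
#' @return list with `aeLayers`, `mapperLayers`, and [trainingConfig()]
#'   blocks `autoencoder`, `mapper`, `finetune`.
#' @export
pipelineConfigs <- function(d, K, seed = 1L, scale = c("desk", "reference")) {
  scale <- match.arg(scale)
  default_pipeline_configs(as.integer(d), as.integer(K), as.integer(seed), scale)
}

train_fold_predictor <- function(Xtrain, Ytrain, cfgs) {
  ae <- trainAutoencoder(Xtrain, layerSizes = cfgs$aeLayers,
                         cfg = cfgs$autoencoder)
  feats <- encodeSpectra(ae$encoder, Xtrain)
  mapper0 <- initNetwork(cfgs$mapperLayers, seed = cfgs$mapper$seed,
                         sigma = cfgs$mapper$initSigma)
  mapfit <- trainNetwork(mapper0, feats, Ytrain, cfgs$mapper)
  assembled <- assemblePredictor(ae$encoder, mapfit$net)
  ftfit <- trainNetwork(assembled, Xtrain, Ytrain, cfgs$finetune)
  fitThreshold(ftfit$net, Xtrain, Ytrain)
}

#' Five-fold cross-validation of the full predictive pipeline
#'
#' Per fold, using the training portion only: train the spectrum
#' autoencoder, encode features, train the mapping network, assemble and
#' fine-tune the six-layer predictor, and fit the step threshold; then
#' predict the held-out chemicals. The autoencoder is retrained inside each
#' fold so held-out spectra never influence the feature extractor.
#'
#' @param cat a [SensoryCatalog].
#' @param sm a [SpectrumMatrix] over the same chemicals (same order).
#' @param asg a [ClusterAssignment] for the catalog's descriptors.
#' @param cfgs hyperparameter blocks from [pipelineConfigs()].
#' @param folds a [FoldPlan] with `n == ` number of chemicals.
#' @return list with `perFold` (list of [ConfusionRates]), `pooled`
#'   (a [ConfusionRates] over all held-out cells), `thresholds` (fitted
#'   theta per fold) and `predictions` (binary matrix, chemicals x K,
#'   assembled from the held-out folds).
#' @export
crossvalidate <- function(cat, sm, asg, cfgs, folds) {
  stopifnot(is(cat, "SensoryCatalog"), is(sm, "SpectrumMatrix"),
            is(folds, "FoldPlan"))
  if (!identical(chemicalIds(cat), chemicalIds(sm)))
    stop("catalog and spectra disagree on chemical ids")
  labels <- buildClusterLabels(cat, asg)
  X <- asMatrix(sm)
  Y <- asMatrix(labels)
  if (folds@n != nrow(X)) stop("fold plan does not match sample count")
  pred <- matrix(NA_real_, nrow(Y), ncol(Y), dimnames = dimnames(Y))
  perFold <- vector("list", folds@k)
  thresholds <- numeric(folds@k)
  for (f in seq_len(folds@k)) {
    test <- foldIndices(folds, f)
    train <- setdiff(seq_len(nrow(X)), test)
    if (length(train) == 0L) stop("empty training fold")
    predictor <- train_fold_predictor(X[train, , drop = FALSE],
                                      Y[train, , drop = FALSE], cfgs)
    thresholds[f] <- predictor@theta
    pred[test, ] <- predictOdor(predictor, X[test, , drop = FALSE])
    perFold[[f]] <- confusionRates(pred[test, , drop = FALSE],
                                   Y[test, , drop = FALSE])
  }
  list(perFold = perFold, pooled = confusionRates(pred, Y),
       thresholds = thresholds, predictions = pred)
}

#' Accuracy-versus-K sweep
#'
#' For each K in `kValues`: cut the dendrogram of `dm`, rebuild cluster
#' labels, cross-validate, and record pooled rates plus the per-cluster
#' positive-count distribution (the imbalance diagnostic for the degenerate
#' one-huge-cluster regime).
#'
#' @param cat a [SensoryCatalog].
#' @param sm a matching [SpectrumMatrix].
#' @param dm a [DescriptorDistance] over the catalog's descriptors.
#' @param kValues integer vector of cluster counts.
#' @param folds a [FoldPlan].
#' @param seed base seed for the per-K hyperparameter blocks.
#' @param scale passed to [pipelineConfigs()].
#' @param cfgsFor optional `function(K)` returning the hyperparameter blocks
#'   for one K, overriding [pipelineConfigs()] (e.g. for quick sweeps).
#' @return data.frame with columns `K`, `method`, `tp_rate`, `tn_rate`,
#'   `threshold_mean`; attribute `"sizeDistributions"` holds the per-K
#'   cluster-size counts.
#' @export
sweepK <- function(cat, sm, dm, kValues, folds, seed = 1L, scale = "desk",
                   cfgsFor = NULL) {
  dend <- upgma(dm)
  rows <- list()
  dists <- list()
  for (K in kValues) {
    asg <- cutToK(dend, K)
    cfgs <- if (is.null(cfgsFor))
      pipelineConfigs(ncol(asMatrix(sm)), K, seed = seed, scale = scale)
    else cfgsFor(K)
    cv <- crossvalidate(cat, sm, asg, cfgs, folds)
    labels <- buildClusterLabels(cat, asg)
    dists[[as.character(K)]] <- clusterSizeDistribution(labels)
    rows[[length(rows) + 1L]] <- data.frame(
      K = K, method = dm@method, tp_rate = cv$pooled@tpRate,
      tn_rate = cv$pooled@tnRate, threshold_mean = mean(cv$thresholds))
  }
  out <- do.call(rbind, rows)
  attr(out, "sizeDistributions") <- dists
  out
}
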