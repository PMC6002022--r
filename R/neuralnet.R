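#' Training configuration for momentum SGD
#'
#' Learning rate and momentum decay geometrically once per epoch:
#' `eta = eta0 * decay^tau`, `alpha = alpha0 * decay^tau` with `tau` the
#' epoch index. Updates are per-sample (pure stochastic gradient descent),
#' with the visiting order reshuffled every epoch from the run seed. The
#' regularizer is L2 weight decay `lam * sum(w^2)` over weights only; biases
#' are not penalized.
#'
#' @param eta0 initial learning rate (> 0).
#' @param alpha0 initial momentum coefficient (>= 0).
#' @param decay per-epoch geometric factor in (0, 1] (default 0.99).
#' @param lam regularization constant lambda (>= 0).
#' @param epochs number of epochs (>= 1).
#' @param seed integer seed driving initialization order and shuffling.
#' @param initSigma weight-initialization standard deviation (default 0.1).
#' @return a list of class `odorlexTrainingConfig`.
#' @export
trainingConfig <- function(eta0, alpha0 = 0, decay = 0.99, lam = 0,
                           epochs = 100L, seed = 1L, initSigma = 0.1) {
  stopifnot(eta0 > 0, alpha0 >= 0, decay > 0, decay <= 1, lam >= 0,
            epochs >= 1)
  structure(list(eta0 = eta0, alpha0 = alpha0, decay = decay, lam = lam,
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 initSigma = initSigma),
            class = "odorlexTrainingConfig")
}

#' Initialize a sigmoid feed-forward network
#'
#' Weights are drawn i.i.d. Gaussian with zero mean and standard deviation
#' `sigma` (default 0.1) from the seeded generator; biases start at zero
#' (standard practice; avoids initial sigmoid saturation).
#'
#' @param layerSizes integer vector of layer widths, input first, length >= 2.
#' @param seed integer seed; the same seed reproduces the network exactly.
#' @param sigma weight standard deviation.
#' @return an [OdorNet].
#' @export
initNetwork <- function(layerSizes, seed = 1L, sigma = 0.1) {
  layerSizes <- as.integer(layerSizes)
  set.seed(seed)
  L <- length(layerSizes)
  weights <- vector("list", L - 1L)
  biases <- vector("list", L - 1L)
  for (l in seq_len(L - 1L)) {
    weights[[l]] <- matrix(rnorm(layerSizes[l + 1L] * layerSizes[l], 0, sigma),
                           nrow = layerSizes[l + 1L])
    biases[[l]] <- rep(0, layerSizes[l + 1L])
  }
  new("OdorNet", layerSizes = layerSizes, weights = weights, biases = biases)
}

#' Forward pass through an OdorNet
#'
#' `a^0 = x`, `a^l = sigmoid(W^l a^(l-1) + b^l)`; sigmoid on every hidden
#' and output layer.
#'
#' @param net an [OdorNet].
#' @param x input vector of length `layerSizes(net)[1]`, finite.
#' @return list of per-layer activation vectors, input first.
#' @export
nnForward <- function(net, x) {
  stopifnot(is(net, "OdorNet"))
  if (length(x) != net@layerSizes[1L])
    stop(sprintf("input length %d does not match input layer size %d",
                 length(x), net@layerSizes[1L]))
  if (!all(is.finite(x))) stop("input must be finite")
  lapply(cpp_forward(net@weights, net@biases, as.numeric(x)), as.numeric)
}

#' Network outputs for a batch
#'
#' @param net an [OdorNet].
#' @param X matrix of inputs, one row per sample.
#' @return matrix of sigmoid outputs (rows = samples).
#' @export
nnPredict <- function(net, X) {
  stopifnot(is(net, "OdorNet"))
  X <- as.matrix(X)
  if (ncol(X) != net@layerSizes[1L]) stop("input width does not match network")
  out <- cpp_predict(net@weights, net@biases, X)
  rownames(out) <- rownames(X)
  out
}

#' Regularized mean-squared-error loss
#'
#' Data term: mean over samples and output neurons of the squared error.
#' Penalty: `lam * sum(w^2)` over all weights (biases excluded).
#'
#' @param net an [OdorNet].
#' @param X,Y input and target matrices (one row per sample).
#' @param lam regularization constant.
#' @return scalar loss.
#' @export
nnLoss <- function(net, X, Y, lam = 0) {
  stopifnot(is(net, "OdorNet"))
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) == 0L) stop("empty batch")
  cpp_loss(net@weights, net@biases, X, Y, lam)
}

#' Backpropagation gradient for one sample
#'
#' @param net an [OdorNet].
#' @param x,y input and target vectors.
#' @param lam regularization constant (adds `2 * lam * w` to each weight
#'   gradient).
#' @return list with `gradW`, `gradb` (lists shaped like the network) and
#'   `loss` (the per-sample regularized loss).
#' @export
nnGradient <- function(net, x, y, lam = 0) {
  stopifnot(is(net, "OdorNet"))
  cpp_gradient(net@weights, net@biases, as.numeric(x), as.numeric(y), lam)
}

#' One momentum-SGD update
#'
#' `delta_w = -eta * grad + alpha * delta_w_prev`, applied to all weights and
#' biases; `velocity` carries the previous update. Non-finite gradients are
#' an error (training-divergence signal).
#'
#' @param net an [OdorNet].
#' @param velocity previous update (list with `W`, `b`), or NULL for zero.
#' @param x,y one training sample.
#' @param eta,alpha,lam learning rate, momentum coefficient, regularization
#'   constant.
#' @return list with updated `net` and `velocity`.
#' @export
sgdStep <- function(net, velocity, x, y, eta, alpha, lam = 0) {
  g <- nnGradient(net, x, y, lam)
  if (!all(vapply(g$gradW, function(m) all(is.finite(m)), TRUE)))
    stop("non-finite gradient: training divergence")
  L <- length(net@weights)
  if (is.null(velocity))
    velocity <- list(W = lapply(net@weights, function(m) m * 0),
                     b = lapply(net@biases, function(v) v * 0))
  for (l in seq_len(L)) {
    velocity$W[[l]] <- alpha * velocity$W[[l]] - eta * g$gradW[[l]]
    velocity$b[[l]] <- alpha * velocity$b[[l]] - eta * g$gradb[[l]]
    net@weights[[l]] <- net@weights[[l]] + velocity$W[[l]]
    net@biases[[l]] <- net@biases[[l]] + velocity$b[[l]]
  }
  list(net = net, velocity = velocity)
}

#' Train a network by per-sample momentum SGD
#'
#' For epoch `tau = 0 .. epochs-1`: reshuffle the samples (seeded), take one
#' [sgdStep()]-equivalent update per sample with
#' `eta = eta0 * decay^tau`, `alpha = alpha0 * decay^tau`. Divergence
#' (non-finite loss) is an error.
#'
#' @param net an [OdorNet] (typically from [initNetwork()]).
#' @param X,Y training inputs and targets, one row per sample.
#' @param cfg a [trainingConfig()].
#' @return list with `net` (trained [OdorNet]) and `trace` (per-epoch mean
#'   training loss).
#' @export
trainNetwork <- function(net, X, Y, cfg) {
  stopifnot(is(net, "OdorNet"), inherits(cfg, "odorlexTrainingConfig"))
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) == 0L) stop("empty training set")
  if (nrow(X) != nrow(Y)) stop("inputs and targets disagree on sample count")
  set.seed(cfg$seed)
  res <- cpp_train(net@weights, net@biases, X, Y, cfg$eta0, cfg$alpha0,
                   cfg$decay, cfg$lam, cfg$epochs)
  net@weights <- res$weights
  net@biases <- res$biases
  list(net = net, trace = as.numeric(res$trace))
}

#' Train the spectrum autoencoder
#'
#' A sandglass (bottlenecked) network trained to reproduce its input; the
#' bottleneck activation is the compressed feature vector. The reference
#' architecture for 212-bin spectra is `[212, 85, 30, 85, 212]` (three
#' hidden layers, 30-dimensional features); for other input widths pass
#' `layerSizes` explicitly.
#'
#' @param sm a [SpectrumMatrix] or a numeric matrix in `[0, 1]`.
#' @param layerSizes symmetric odd-length layer vector whose middle layer is
#'   the bottleneck; default `c(d, 85, 30, 85, d)` for input width d.
#' @param cfg a [trainingConfig()].
#' @return list with `encoder` (input to bottleneck [OdorNet]), `autoencoder`
#'   (full net) and `trace`.
#' @details A bottleneck at least as wide as the input gives no compression
#'   and triggers a warning.
#' @export
trainAutoencoder <- function(sm, layerSizes = NULL, cfg) {
  X <- if (is(sm, "SpectrumMatrix")) asMatrix(sm) else as.matrix(sm)
  d <- ncol(X)
  if (is.null(layerSizes)) layerSizes <- c(d, 85L, 30L, 85L, d)
  layerSizes <- as.integer(layerSizes)
  L <- length(layerSizes)
  if (L %% 2L == 0L) stop("autoencoder needs an odd number of layers")
  if (!identical(layerSizes, rev(layerSizes)))
    stop("autoencoder layer sizes must be symmetric")
  if (layerSizes[1L] != d) stop("input layer must match spectrum width")
  mid <- (L + 1L) %/% 2L
  if (layerSizes[mid] >= d)
    warning("bottleneck is not smaller than the input: no compression",
            call. = FALSE)
  net <- initNetwork(layerSizes, seed = cfg$seed, sigma = cfg$initSigma)
  fit <- trainNetwork(net, X, X, cfg)
  enc <- new("OdorNet", layerSizes = layerSizes[1:mid],
             weights = fit$net@weights[seq_len(mid - 1L)],
             biases = fit$net@biases[seq_len(mid - 1L)])
  list(encoder = enc, autoencoder = fit$net, trace = fit$trace)
}

#' Bottleneck feature vectors for spectra
#'
#' @param encoder the encoder half from [trainAutoencoder()].
#' @param sm a [SpectrumMatrix] or matrix.
#' @return feature matrix (samples x bottleneck width).
#' @export
encodeSpectra <- function(encoder, sm) {
  X <- if (is(sm, "SpectrumMatrix")) asMatrix(sm) else as.matrix(sm)
  nnPredict(encoder, X)
}

#' Connect encoder and mapping network into one predictor
#'
#' Concatenates the layer lists so that
#' `nnPredict(assembled, x) == nnPredict(mapper, nnPredict(encoder, x))`
#' exactly. With the reference encoder `[212, 85, 30]` and mapper
#' `[30, 50, 20, K]` the assembly is the six-layer predictor
#' `[212, 85, 30, 50, 20, K]`.
#'
#' @param encoder,mapper [OdorNet]s; the encoder's output width must equal
#'   the mapper's input width.
#' @return assembled [OdorNet].
#' @export
assemblePredictor <- function(encoder, mapper) {
  stopifnot(is(encoder, "OdorNet"), is(mapper, "OdorNet"))
  ne <- length(encoder@layerSizes)
  if (encoder@layerSizes[ne] != mapper@layerSizes[1L])
    stop("encoder output size does not match mapper input size")
  new("OdorNet",
      layerSizes = c(encoder@layerSizes, mapper@layerSizes[-1L]),
      weights = c(encoder@weights, mapper@weights),
      biases = c(encoder@biases, mapper@biases))
}

balanced_accuracy <- function(pred, truth) {
  pos <- truth == 1
  tp <- if (any(pos)) mean(pred[pos] == 1) else NA_real_
  tn <- if (any(!pos)) mean(pred[!pos] == 0) else NA_real_
  mean(c(tp, tn), na.rm = TRUE)
}

#' Fit the step-function threshold on training data
#'
#' One global threshold theta, shared by all outputs, is chosen from `grid`
#' to maximize balanced accuracy (mean of the true-positive and
#' true-negative rates) on the training set; under ~98% sparsity plain
#' concordance would collapse to the all-zeros predictor. Ties pick the
#' smallest threshold.
#'
#' @param net assembled [OdorNet].
#' @param X training inputs.
#' @param Y training labels (binary matrix).
#' @param grid candidate thresholds inside (0, 1); default 0.01..0.99 step
#'   0.01.
#' @return a [ThresholdedOdorNet].
#' @export
fitThreshold <- function(net, X, Y, grid = seq(0.01, 0.99, by = 0.01)) {
  stopifnot(length(grid) > 0L, all(grid > 0), all(grid < 1))
  Y <- as.matrix(Y)
  scores <- nnPredict(net, X)
  objective <- vapply(grid, function(th)
    balanced_accuracy((scores >= th) * 1, Y), numeric(1))
  best <- grid[which.max(objective)]   # which.max takes the first (smallest) tie
  new("ThresholdedOdorNet", net = net, theta = best)
}

#' Binary odor-cluster predictions
#'
#' @param predictor a [ThresholdedOdorNet].
#' @param X input matrix (one spectrum row per chemical).
#' @return binary matrix: sigmoid outputs thresholded by the fitted theta.
#' @export
predictOdor <- function(predictor, X) {
  stopifnot(is(predictor, "ThresholdedOdorNet"))
  (nnPredict(predictor@net, X) >= predictor@theta) * 1
}

#' Serialize a network to JSON
#'
#' Container: layer sizes, per-layer weight matrices (row-major), biases,
#' and optional metadata (training config, seed).
#'
#' @param net an [OdorNet].
#' @param path output path.
#' @param meta optional list stored verbatim under `meta`.
#' @return `path`, invisibly.
#' @export
writeNetwork <- function(net, path, meta = NULL) {
  stopifnot(is(net, "OdorNet"))
  obj <- list(
    layer_sizes = net@layerSizes,
    weights = lapply(net@weights, function(m)
      list(nrow = nrow(m), ncol = ncol(m), data = as.numeric(t(m)))),
    biases = net@biases,
    meta = meta)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a network serialized by [writeNetwork()]
#'
#' @param path JSON path.
#' @return an [OdorNet].
#' @export
readNetwork <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  weights <- lapply(seq_len(nrow(obj$weights)), function(i)
    matrix(obj$weights$data[[i]], nrow = obj$weights$nrow[i], byrow = TRUE))
  new("OdorNet", layerSizes = as.integer(obj$layer_sizes),
      weights = weights, biases = lapply(obj$biases, as.numeric))
}
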