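test_that("initialization is seeded, Gaussian and bias-free", {
  n1 <- initNetwork(c(5, 4, 3), seed = 42)
  n2 <- initNetwork(c(5, 4, 3), seed = 42)
  expect_identical(n1@weights, n2@weights)     # same seed, bit-identical
  expect_true(all(vapply(n1@biases, function(b) all(b == 0), TRUE)))

  big <- initNetwork(c(100, 100), seed = 7)    # 10^4 weights
  expect_gt(sd(big@weights[[1]]), 0.09)
  expect_lt(sd(big@weights[[1]]), 0.11)

  z <- initNetwork(c(3, 2), seed = 1, sigma = 0)
  expect_true(all(z@weights[[1]] == 0))
})

test_that("forward pass is sigmoid layer composition", {
  z <- initNetwork(c(3, 4, 2), seed = 1, sigma = 0)
  acts <- nnForward(z, c(0.3, -0.1, 2))
  expect_equal(acts[[2]], rep(0.5, 4))   # sigmoid(0) everywhere
  expect_equal(acts[[3]], rep(0.5, 2))

  one <- new("OdorNet", layerSizes = c(1L, 1L),
             weights = list(matrix(1)), biases = list(0))
  expect_equal(nnForward(one, 0)[[2]], 0.5)

  set.seed(12)
  net <- initNetwork(c(6, 5, 4, 3), seed = 12)
  x <- runif(6)
  got <- nnForward(net, x)
  exp <- r_forward(net@weights, net@biases, x)
  for (l in 1:4) expect_equal(got[[l]], exp[[l]], tolerance = 1e-12)

  expect_error(nnForward(net, runif(5)), "does not match")
})

test_that("the loss is mean squared error plus L2 weight penalty", {
  one <- new("OdorNet", layerSizes = c(1L, 1L),
             weights = list(matrix(0)), biases = list(0))
  # output is sigmoid(0) = 0.5; target 1 gives squared error 0.25
  expect_equal(nnLoss(one, matrix(0), matrix(1), lam = 0), 0.25)
  # zero weights contribute no penalty whatever lambda is
  expect_equal(nnLoss(one, matrix(0), matrix(1), lam = 10),
               nnLoss(one, matrix(0), matrix(1), lam = 0))
  # a perfectly reproduced constant target has zero data term
  expect_equal(nnLoss(one, matrix(0), matrix(0.5), lam = 0), 0)
})

test_that("backprop matches central finite differences", {
  set.seed(77)
  net <- initNetwork(c(4, 3, 2), seed = 77)
  x <- runif(4); y <- c(1, 0)
  for (lam in c(0, 3e-7)) {
    g <- nnGradient(net, x, y, lam)
    eps <- 1e-6
    for (l in 1:2) {
      idx <- sample(seq_along(net@weights[[l]]), 5)
      for (i in idx) {
        np <- net; np@weights[[l]][i] <- np@weights[[l]][i] + eps
        nm <- net; nm@weights[[l]][i] <- nm@weights[[l]][i] - eps
        fd <- (nnLoss(np, matrix(x, 1), matrix(y, 1), lam) -
                 nnLoss(nm, matrix(x, 1), matrix(y, 1), lam)) / (2 * eps)
        expect_lt(abs(fd - g$gradW[[l]][i]), 1e-7)
      }
      bp <- net; bp@biases[[l]][1] <- bp@biases[[l]][1] + eps
      bm <- net; bm@biases[[l]][1] <- bm@biases[[l]][1] - eps
      fd <- (nnLoss(bp, matrix(x, 1), matrix(y, 1), lam) -
               nnLoss(bm, matrix(x, 1), matrix(y, 1), lam)) / (2 * eps)
      expect_lt(abs(fd - g$gradb[[l]][1]), 1e-7)
    }
  }
})

test_that("momentum SGD follows the update recursion", {
  set.seed(3)
  net <- initNetwork(c(3, 2), seed = 3)
  x <- runif(3); y <- c(1, 0)
  g <- nnGradient(net, x, y, 0)

  # alpha = 0: textbook gradient descent, bitwise
  s1 <- sgdStep(net, NULL, x, y, eta = 0.1, alpha = 0, lam = 0)
  expect_identical(s1$net@weights[[1]],
                   net@weights[[1]] - 0.1 * g$gradW[[1]])

  # eta = 0 with zero velocity: nothing moves
  s0 <- sgdStep(net, NULL, x, y, eta = 0, alpha = 0.5, lam = 0)
  expect_identical(s0$net@weights, net@weights)

  # eta = 0 with prior velocity: velocity scales by alpha, pure momentum step
  v0 <- list(W = list(matrix(1, 2, 3)), b = list(c(1, 1)))
  s2 <- sgdStep(net, v0, x, y, eta = 0, alpha = 0.5, lam = 0)
  expect_equal(s2$velocity$W[[1]], 0.5 * v0$W[[1]])
  expect_equal(s2$net@weights[[1]], net@weights[[1]] + 0.5 * v0$W[[1]])

  # two plain steps: second update includes alpha * first update
  sA <- sgdStep(net, NULL, x, y, eta = 0.1, alpha = 0.9, lam = 0)
  gB <- nnGradient(sA$net, x, y, 0)
  sB <- sgdStep(sA$net, sA$velocity, x, y, eta = 0.1, alpha = 0.9, lam = 0)
  expect_equal(sB$net@weights[[1]],
               sA$net@weights[[1]] - 0.1 * gB$gradW[[1]] +
                 0.9 * (sA$net@weights[[1]] - net@weights[[1]]))
})

test_that("training is seeded-deterministic and reduces loss on a toy set", {
  X <- rbind(c(0, 0, 1), c(1, 1, 0))
  Y <- rbind(0, 1)
  net <- initNetwork(c(3, 3, 1), seed = 5)
  cfg <- trainingConfig(eta0 = 0.5, alpha0 = 0.2, epochs = 500, seed = 5)
  f1 <- trainNetwork(net, X, Y, cfg)
  f2 <- trainNetwork(net, X, Y, cfg)
  expect_identical(f1$trace, f2$trace)
  expect_lt(f1$trace[500], f1$trace[1])
  expect_lt(nnLoss(f1$net, X, Y), nnLoss(net, X, Y))

  # an effectively-zero learning rate leaves the network untouched
  still <- trainNetwork(net, X, Y,
                        trainingConfig(eta0 = 1e-300, alpha0 = 0, epochs = 1,
                                       seed = 5))
  expect_identical(still$net@weights, net@weights)
})

test_that("weight norms shrink as the regularization constant grows", {
  X <- rbind(c(0, 1), c(1, 0), c(1, 1))
  Y <- rbind(1, 0, 1)
  norms <- vapply(c(0, 1e-3, 1e-1), function(lam) {
    cfg <- trainingConfig(eta0 = 0.5, alpha0 = 0, decay = 1, lam = lam,
                          epochs = 800, seed = 9)
    fit <- trainNetwork(initNetwork(c(2, 3, 1), seed = 9), X, Y, cfg)
    sum(vapply(fit$net@weights, function(w) sum(w^2), 0))
  }, 0)
  expect_true(all(diff(norms) <= 0))
})

test_that("the autoencoder compresses structured data below the constant baseline", {
  set.seed(31)
  basis <- matrix(runif(16, 0, 1), 2, 8)
  X <- pmin(matrix(runif(80, 0, 1), 40, 2) %*% basis, 1)
  cfg <- trainingConfig(eta0 = 2, alpha0 = 0.5, decay = 1, lam = 0,
                        epochs = 2000, seed = 31)
  ae <- trainAutoencoder(X, layerSizes = c(8, 4, 2, 4, 8), cfg = cfg)
  recon <- nnPredict(ae$autoencoder, X)
  constMSE <- mean(scale(X, scale = FALSE)^2)
  expect_lt(mean((recon - X)^2), constMSE)
  expect_identical(ae$encoder@layerSizes, c(8L, 4L, 2L))
  expect_identical(ncol(encodeSpectra(ae$encoder, X)), 2L)
})

test_that("a single repeated input is reconstructed nearly exactly", {
  x <- c(0.1, 0.8, 0.4, 0.6)
  X <- matrix(rep(x, 30), 30, byrow = TRUE)
  cfg <- trainingConfig(eta0 = 1, alpha0 = 0.3, decay = 1, lam = 0,
                        epochs = 400, seed = 2)
  ae <- trainAutoencoder(X, layerSizes = c(4, 3, 2, 3, 4), cfg = cfg)
  expect_lt(max(abs(nnPredict(ae$autoencoder, X)[1, ] - x)), 0.05)
})

test_that("autoencoder shape constraints are enforced", {
  cfg <- trainingConfig(eta0 = 0.1, epochs = 1, seed = 1)
  X <- matrix(runif(12), 3, 4)
  expect_error(trainAutoencoder(X, layerSizes = c(4, 3, 3, 4), cfg = cfg),
               "odd")
  expect_error(trainAutoencoder(X, layerSizes = c(4, 3, 2, 5, 4), cfg = cfg),
               "symmetric")
  expect_warning(trainAutoencoder(X, layerSizes = c(4, 5, 4, 5, 4), cfg = cfg),
                 "no compression")
})

test_that("assembly concatenates layers and preserves composition exactly", {
  enc <- initNetwork(c(212, 85, 30), seed = 1)
  map <- initNetwork(c(30, 50, 20, 7), seed = 2)
  asm <- assemblePredictor(enc, map)
  expect_identical(asm@layerSizes, c(212L, 85L, 30L, 50L, 20L, 7L))
  expect_length(asm@layerSizes, 6L)

  x <- runif(212)
  direct <- nnPredict(asm, matrix(x, 1))
  composed <- nnPredict(map, nnPredict(enc, matrix(x, 1)))
  expect_identical(direct, composed)   # 0 ulp: same operations in sequence

  expect_error(assemblePredictor(enc, initNetwork(c(29, 5), seed = 1)),
               "does not match")
})

test_that("fine-tuning the assembled predictor moves every layer", {
  set.seed(6)
  enc <- initNetwork(c(6, 4, 2), seed = 6)
  map <- initNetwork(c(2, 3, 2), seed = 7)
  asm <- assemblePredictor(enc, map)
  X <- matrix(runif(60), 10, 6)
  Y <- matrix(rbinom(20, 1, 0.5), 10, 2)
  fit <- trainNetwork(asm, X, Y,
                      trainingConfig(eta0 = 0.3, alpha0 = 0.1, epochs = 50,
                                     seed = 8))
  for (l in seq_along(asm@weights))
    expect_false(identical(fit$net@weights[[l]], asm@weights[[l]]))
})

test_that("threshold fitting maximizes balanced accuracy on the grid", {
  # perfectly separated scores: positives 0.9, negatives 0.1
  sep <- new("OdorNet", layerSizes = c(1L, 1L),
             weights = list(matrix(10)), biases = list(-5))
  X <- matrix(c(0.9, 0.9, 0.1, 0.1), 4)
  Y <- matrix(c(1, 1, 0, 0), 4)
  th <- fitThreshold(sep, X, Y)
  pred <- predictOdor(th, X)
  cr <- confusionRates(pred, Y)
  expect_equal(cr@tpRate, 100)
  expect_equal(cr@tnRate, 100)

  # a one-point grid is returned as-is
  expect_equal(fitThreshold(sep, X, Y, grid = 0.37)@theta, 0.37)

  # random scores: fitted theta matches an exhaustive search
  set.seed(44)
  net2 <- initNetwork(c(3, 4, 2), seed = 44)
  X2 <- matrix(runif(60), 20, 3)
  Y2 <- matrix(rbinom(40, 1, 0.4), 20, 2)
  got <- fitThreshold(net2, X2, Y2)@theta
  scores <- nnPredict(net2, X2)
  grid <- seq(0.01, 0.99, by = 0.01)
  obj <- vapply(grid, function(t0) {
    p <- (scores >= t0) * 1
    tp <- mean(p[Y2 == 1] == 1); tn <- mean(p[Y2 == 0] == 0)
    mean(c(tp, tn))
  }, 0)
  expect_equal(got, grid[which.max(obj)])
})

test_that("networks round-trip through the JSON container", {
  net <- initNetwork(c(4, 3, 2), seed = 13)
  path <- withr::local_tempfile(fileext = ".json")
  writeNetwork(net, path, meta = list(seed = 13))
  back <- readNetwork(path)
  expect_identical(back@layerSizes, net@layerSizes)
  expect_equal(back@weights, net@weights)
  expect_equal(back@biases, net@biases)
})
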