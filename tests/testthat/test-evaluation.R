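test_that("fold sizes follow division with remainder", {
  expect_identical(unname(tabulate(makeFolds(999, 5, 1)@assignment, 5)),
                   c(200L, 200L, 200L, 200L, 199L))
  expect_identical(unname(tabulate(makeFolds(10, 5, 1)@assignment, 5)),
                   rep(2L, 5))
  expect_identical(unname(tabulate(makeFolds(7, 3, 1)@assignment, 3)),
                   c(3L, 2L, 2L))
  expect_error(makeFolds(3, 5, 1), "more folds than samples")
})

test_that("fold plans always partition with near-equal sizes", {
  set.seed(19)
  for (i in 1:20) {
    n <- sample(10:500, 1)
    k <- sample(2:min(n, 10), 1)
    plan <- makeFolds(n, k, seed = i)
    sizes <- tabulate(plan@assignment, k)
    expect_identical(sum(sizes), n)
    expect_lte(max(sizes) - min(sizes), 1L)
    expect_identical(sort(unlist(lapply(seq_len(k), foldIndices, plan = plan))),
                     seq_len(n))
  }
})

test_that("stratified folds spread strata near-proportionally", {
  strata <- rep(c("x", "y"), c(40, 20))
  plan <- makeFolds(60, 5, seed = 3, stratifyBy = strata)
  for (f in 1:5) {
    idx <- foldIndices(plan, f)
    expect_identical(sum(strata[idx] == "x"), 8L)
    expect_identical(sum(strata[idx] == "y"), 4L)
  }
})

test_that("confusion rates pool cells and column-normalize to 100", {
  y <- matrix(c(1, 1, 0, 0), 2)
  expect_equal(confusionRates(y, y)@tpRate, 100)
  expect_equal(confusionRates(y, y)@tnRate, 100)
  flip <- confusionRates(1 - y, y)
  expect_equal(flip@tpRate, 0)
  expect_equal(flip@tnRate, 0)

  hand <- confusionRates(matrix(c(1, 0, 0, 0), 1), matrix(c(1, 1, 0, 0), 1))
  expect_equal(hand@tpRate, 50)
  expect_equal(hand@tnRate, 100)
  expect_equal(hand@tpRate + hand@fnRate, 100)
  expect_equal(hand@tnRate + hand@fpRate, 100)

  set.seed(23)
  for (i in 1:10) {
    p <- matrix(rbinom(40, 1, 0.5), 8)
    t0 <- matrix(rbinom(40, 1, 0.5), 8)
    cr <- confusionRates(p, t0)
    if (!is.na(cr@tpRate)) expect_equal(cr@tpRate + cr@fnRate, 100)
    if (!is.na(cr@tnRate)) expect_equal(cr@tnRate + cr@fpRate, 100)
  }
})

test_that("an empty truth class yields NA rather than zero", {
  ones <- matrix(1, 2, 2)
  cr <- confusionRates(ones, ones)
  expect_true(is.na(cr@tnRate))
  expect_equal(cr@tpRate, 100)
})

test_that("a memorizable synthetic set cross-validates above chance", {
  w <- generateWorld(syntheticConfig(nChemicals = 40, nGroups = 3,
                                     descriptorsPerGroup = 3, embedDim = 8,
                                     spectrumDim = 16, latentRank = 3,
                                     noiseSd = 0.01, seed = 77))
  sm <- buildSpectrumMatrix(w$spectra, w$mzWindow[1], w$mzWindow[2])
  asg <- cutToK(upgma(cosineDissimilarity(descriptorNames(w$catalog),
                                          w$embeddings)), 3)
  cfgs <- tiny_cfgs(16, 3, seed = 77,
                    epochs = c(ae = 300, map = 600, ft = 60))
  folds <- makeFolds(40, 5, seed = 77)
  cv <- crossvalidate(w$catalog, sm, asg, cfgs, folds)
  expect_gt(cv$pooled@tpRate, 50)
  expect_gt(cv$pooled@tnRate, 50)
  expect_length(cv$perFold, 5L)
  expect_length(cv$thresholds, 5L)

  # same seeds, same world: identical pooled rates
  cv2 <- crossvalidate(w$catalog, sm, asg, cfgs, folds)
  expect_identical(cv2$pooled@counts, cv$pooled@counts)
})

test_that("held-out predictions never depend on held-out labels", {
  w <- generateWorld(syntheticConfig(nChemicals = 30, nGroups = 2,
                                     descriptorsPerGroup = 3, embedDim = 6,
                                     spectrumDim = 12, latentRank = 2,
                                     seed = 55))
  sm <- buildSpectrumMatrix(w$spectra, w$mzWindow[1], w$mzWindow[2])
  asg <- cutToK(upgma(cosineDissimilarity(descriptorNames(w$catalog),
                                          w$embeddings)), 2)
  cfgs <- tiny_cfgs(12, 2, seed = 55, epochs = c(ae = 60, map = 100, ft = 20))
  folds <- makeFolds(30, 3, seed = 55)
  cv <- crossvalidate(w$catalog, sm, asg, cfgs, folds)

  # scramble the catalog rows of fold 1's held-out chemicals: training data
  # are untouched, so fold 1's predictions and threshold must be identical
  test1 <- foldIndices(folds, 1)
  m <- asMatrix(w$catalog)
  m[test1, ] <- m[rev(test1), ]
  cat2 <- suppressWarnings(SensoryCatalog(m))
  cv2 <- crossvalidate(cat2, sm, asg, cfgs, folds)
  expect_identical(cv2$predictions[test1, ], cv$predictions[test1, ])
  expect_identical(cv2$thresholds[1], cv$thresholds[1])
})

test_that("the K sweep emits one row per K with imbalance diagnostics", {
  w <- generateWorld(syntheticConfig(nChemicals = 30, nGroups = 3,
                                     descriptorsPerGroup = 2, embedDim = 6,
                                     spectrumDim = 12, latentRank = 3,
                                     seed = 21))
  sm <- buildSpectrumMatrix(w$spectra, w$mzWindow[1], w$mzWindow[2])
  dm <- cosineDissimilarity(descriptorNames(w$catalog), w$embeddings)
  folds <- makeFolds(30, 3, seed = 21)
  tab <- sweepK(w$catalog, sm, dm, c(2, 3, 6), folds, seed = 21,
                cfgsFor = function(K)
                  tiny_cfgs(12, K, 21, epochs = c(ae = 40, map = 60, ft = 10)))
  expect_identical(nrow(tab), 3L)
  expect_identical(tab$K, c(2, 3, 6))
  expect_true(all(tab$method == "cosine"))
  dists <- attr(tab, "sizeDistributions")
  expect_length(dists, 3L)
  expect_length(dists[["6"]], 6L)
})
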