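dm_from <- function(m, labels) {
  dimnames(m) <- list(labels, labels)
  new("DescriptorDistance", values = m, method = "cosine")
}

test_that("UPGMA handles hand-checkable cases", {
  two <- dm_from(matrix(c(0, 0.4, 0.4, 0), 2), c("a", "b"))
  d2 <- upgma(two)
  expect_equal(d2@height, 0.4)
  expect_identical(d2@merge, matrix(c(-1L, -2L), 1))

  three <- dm_from(matrix(c(0, 1, 4, 1, 0, 4, 4, 4, 0), 3), c("a", "b", "c"))
  d3 <- upgma(three)
  expect_equal(d3@height, c(1, 4))   # 4 = (4 + 4) / 2
  expect_identical(d3@merge, rbind(c(-1L, -2L), c(1L, -3L)))
  asg <- cutToK(d3, 2)
  expect_identical(unname(clusterMembers(asg)), c(1L, 1L, 2L))
})

test_that("UPGMA agrees with the naive leaf-pair-mean oracle, ties included", {
  set.seed(101)
  for (i in 1:60) {
    n <- sample(3:12, 1)
    dm <- rand_dissimilarity(n, ties = i %% 2 == 0)
    got <- upgma(dm)
    exp <- naive_upgma(asMatrix(dm))
    expect_identical(got@merge, exp$merge)
    expect_equal(got@height, exp$height, tolerance = 1e-10)
  }
})

test_that("UPGMA matches hclust average linkage on tie-free instances", {
  set.seed(33)
  for (i in 1:10) {
    n <- sample(5:20, 1)
    dm <- rand_dissimilarity(n, ties = FALSE)
    got <- upgma(dm)
    hc <- hclust(as.dist(asMatrix(dm)), method = "average")
    expect_equal(sort(got@height), sort(hc$height))
    for (K in c(2L, 3L, n %/% 2L)) {
      ours <- clusterMembers(cutToK(got, K))
      theirs <- cutree(hc, K)[names(ours)]
      expect_equal(mclust::adjustedRandIndex(ours, theirs), 1)
    }
  }
})

test_that("cutToK spans the full range and always partitions", {
  set.seed(5)
  dm <- rand_dissimilarity(9)
  dend <- upgma(dm)
  expect_identical(unname(clusterMembers(cutToK(dend, 1))), rep(1L, 9))
  expect_identical(sort(unname(clusterMembers(cutToK(dend, 9)))), 1:9)
  for (K in 1:9) {
    asg <- cutToK(dend, K)
    expect_identical(asg@K, K)
    expect_identical(sort(unique(unname(clusterMembers(asg)))), seq_len(K))
  }
  expect_error(cutToK(dend, 0), "K must lie")
  expect_error(cutToK(dend, 10), "K must lie")
})

test_that("cutAtHeight matches the merge structure", {
  three <- dm_from(matrix(c(0, 1, 4, 1, 0, 4, 4, 4, 0), 3), c("a", "b", "c"))
  dend <- upgma(three)
  expect_identical(cutAtHeight(dend, 2)@K, 2L)
  expect_identical(cutAtHeight(dend, 5)@K, 1L)
})

test_that("OR rule sets a cluster bit from any single member descriptor", {
  m <- matrix(0, 2, 3, dimnames = list(c("x", "y"),
                                       c("rose", "lavender", "iris")))
  m["x", "lavender"] <- 1
  cat0 <- make_catalog(m, ids = c("x", "y"), descr = colnames(m))
  asg <- new("ClusterAssignment", K = 1L,
             cluster = c(rose = 1L, lavender = 1L, iris = 1L))
  lab <- buildClusterLabels(cat0, asg)
  expect_equal(asMatrix(lab)["x", 1], 1)   # one member is enough
  expect_equal(asMatrix(lab)["y", 1], 0)   # all-zero row stays all-zero
})

test_that("singleton clusters reproduce the catalog up to column order", {
  set.seed(8)
  m <- matrix(rbinom(40, 1, 0.3), 8, 5)
  cat0 <- make_catalog(m)
  dm <- suppressWarnings(correlationDissimilarity(cat0))
  asg <- cutToK(upgma(dm), 5)
  lab <- buildClusterLabels(cat0, asg)
  perm <- clusterMembers(asg)[descriptorNames(cat0)]
  expect_equal(asMatrix(lab)[, perm], asMatrix(cat0), ignore_attr = TRUE)
})

test_that("positive bits per chemical are non-increasing as K decreases", {
  set.seed(21)
  m <- matrix(rbinom(120, 1, 0.25), 12, 10)
  cat0 <- make_catalog(m)
  dm <- suppressWarnings(correlationDissimilarity(cat0))
  dend <- upgma(dm)
  prev <- NULL
  for (K in 10:1) {
    bits <- rowSums(asMatrix(buildClusterLabels(cat0, cutToK(dend, K))))
    if (!is.null(prev)) expect_true(all(bits <= prev))
    prev <- bits
  }
})

test_that("cluster size distribution counts positive chemicals per cluster", {
  m1 <- diag(3)
  dimnames(m1) <- list(paste0("c", 1:3), NULL)
  lab <- new("ClusterLabelMatrix", K = 3L, matrix = m1)
  expect_identical(unname(clusterSizeDistribution(lab)), c(1L, 1L, 1L))
  m2 <- cbind(rep(1, 5), rep(0, 5))
  dimnames(m2) <- list(paste0("c", 1:5), NULL)
  lab2 <- new("ClusterLabelMatrix", K = 2L, matrix = m2)
  expect_identical(unname(clusterSizeDistribution(lab2)), c(5L, 0L))
})

test_that("balanced synthetic labels are less imbalanced than exclusive-correlation ones", {
  w <- generateWorld(syntheticConfig(nChemicals = 120, seed = 14))
  dendE <- upgma(cosineDissimilarity(descriptorNames(w$catalog), w$embeddings))
  dendC <- upgma(correlationDissimilarity(w$catalog))
  cv <- function(x) stats::sd(x) / mean(x)
  cvE <- cv(clusterSizeDistribution(buildClusterLabels(w$catalog, cutToK(dendE, 6))))
  cvC <- cv(clusterSizeDistribution(buildClusterLabels(w$catalog, cutToK(dendC, 6))))
  expect_lt(cvE, cvC)
})

test_that("dendrograms export to Newick readable by ape", {
  set.seed(4)
  dm <- rand_dissimilarity(6, labels = paste0("w", 1:6))
  dend <- upgma(dm)
  path <- withr::local_tempfile(fileext = ".nwk")
  exportNewick(dend, path)
  phy <- ape::read.tree(path)
  expect_setequal(phy$tip.label, paste0("w", 1:6))
  expect_identical(ape::Ntip(phy), 6L)
})

test_that("cluster assignments export as two-column CSV", {
  asg <- new("ClusterAssignment", K = 2L, cluster = c(rose = 1L, milk = 2L))
  path <- withr::local_tempfile(fileext = ".csv")
  writeClusterAssignments(asg, path)
  df <- read.csv(path)
  expect_identical(names(df), c("descriptor", "cluster_id"))
  expect_identical(df$cluster_id, c(1L, 2L))
})
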