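#' @import methods
#' @importFrom stats cor cmdscale rnorm runif as.dist
#' @importFrom utils read.csv write.csv head
#' @useDynLib odorlex, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' SensoryCatalog: a binary chemicals-by-descriptors table
#'
#' Stores the presence/absence odor-character profile of a set of chemicals:
#' one row per chemical, one column per verbal descriptor, every cell 0 or 1.
#' Row names are chemical identifiers, column names are lowercase descriptor
#' names; both must be unique.
#'
#' @slot matrix binary matrix, rownames = chemical ids, colnames = descriptors.
#' @seealso [readCatalog()], [filterRareDescriptors()], [sparsity()]
#' @export
setClass("SensoryCatalog", representation(matrix = "matrix"))

setValidity("SensoryCatalog", function(object) {
  m <- object@matrix
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("matrix must have chemical ids as rownames and descriptor names as colnames")
  if (anyDuplicated(rownames(m))) return("duplicate chemical ids")
  if (anyDuplicated(colnames(m))) return("duplicate descriptor names")
  if (!all(m %in% c(0, 1))) return("all entries must be 0 or 1")
  if (any(colnames(m) != trimws(tolower(colnames(m)))))
    return("descriptor names must be lowercase and stripped")
  TRUE
})

#' MassSpectrum: a single electron-ionization mass spectrum
#'
#' A sparse unit-resolution spectrum: integer m/z values with non-negative
#' intensities in arbitrary units. m/z values absent from the peak list are
#' implicit zeros.
#'
#' @slot chemicalId single identifier string.
#' @slot mz integer m/z values, all >= 1, strictly increasing.
#' @slot intensity non-negative intensities, same length as `mz`.
#' @seealso [readSpectra()], [buildSpectrumMatrix()]
#' @export
setClass("MassSpectrum", representation(
  chemicalId = "character", mz = "integer", intensity = "numeric"))

setValidity("MassSpectrum", function(object) {
  if (length(object@chemicalId) != 1L) return("chemicalId must be a single string")
  if (length(object@mz) != length(object@intensity))
    return("mz and intensity lengths differ")
  if (any(object@mz < 1L)) return("m/z values must be >= 1")
  if (is.unsorted(object@mz, strictly = TRUE)) return("m/z values must be strictly increasing")
  if (any(object@intensity < 0)) return("intensities must be non-negative")
  TRUE
})

#' SpectrumMatrix: windowed, globally normalized spectra
#'
#' Chemicals-by-m/z-bin intensity matrix on the inclusive window
#' `[mzLo, mzHi]`, normalized by a single global maximum so that all values
#' lie in `[0, 1]` and the dataset maximum is exactly 1 (global
#' normalization; a per-spectrum variant relaxes the global-max invariant).
#' Column `j` holds intensities at m/z = `mzLo + j - 1`.
#'
#' @slot matrix numeric matrix in `[0, 1]`, rownames = chemical ids.
#' @slot mzLo,mzHi inclusive integer window bounds.
#' @slot perSpectrum logical; TRUE if each row was normalized by its own max.
#' @seealso [buildSpectrumMatrix()]
#' @export
setClass("SpectrumMatrix", representation(
  matrix = "matrix", mzLo = "integer", mzHi = "integer", perSpectrum = "logical"))

setValidity("SpectrumMatrix", function(object) {
  m <- object@matrix
  if (ncol(m) != object@mzHi - object@mzLo + 1L)
    return("column count must equal mzHi - mzLo + 1")
  if (is.null(rownames(m))) return("rownames (chemical ids) required")
  if (any(m < 0) || any(m > 1)) return("values must lie in [0, 1]")
  if (!object@perSpectrum && nrow(m) > 0 && abs(max(m) - 1) > 1e-12)
    return("global normalization requires the dataset maximum to be exactly 1")
  TRUE
})

#' EmbeddingTable: word vectors keyed by lowercase words
#'
#' @slot vectors numeric matrix, one row per word (rownames = vocabulary),
#'   all rows the same length (the embedding dimension).
#' @seealso [readWordVectors()], [cosineDissimilarity()]
#' @export
setClass("EmbeddingTable", representation(vectors = "matrix"))

setValidity("EmbeddingTable", function(object) {
  if (nrow(object@vectors) == 0L) return("empty vocabulary")
  if (is.null(rownames(object@vectors))) return("rownames (vocabulary) required")
  if (anyDuplicated(rownames(object@vectors))) return("duplicate words")
  TRUE
})

#' DescriptorDistance: symmetric descriptor dissimilarity matrix
#'
#' Pairwise dissimilarities between odor descriptors, either
#' `1 - Pearson correlation` of binary catalog columns (method
#' `"correlation"`) or `1 - cosine similarity` of word embeddings (method
#' `"cosine"`). Both lie in `[0, 2]` with a zero diagonal.
#'
#' @slot values symmetric numeric matrix with dimnames = descriptor names.
#' @slot method `"correlation"` or `"cosine"`.
#' @seealso [correlationDissimilarity()], [cosineDissimilarity()], [upgma()]
#' @export
setClass("DescriptorDistance", representation(values = "matrix", method = "character"))

setValidity("DescriptorDistance", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("matrix must be square")
  if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
    return("dimnames must be identical descriptor names")
  if (max(abs(v - t(v))) > 1e-12) return("matrix must be symmetric (tol 1e-12)")
  if (max(abs(diag(v))) > 1e-12) return("diagonal must be zero")
  if (any(v < -1e-12)) return("dissimilarities must be non-negative")
  if (!object@method %in% c("correlation", "cosine"))
    return("method must be 'correlation' or 'cosine'")
  TRUE
})

#' OdorDendrogram: UPGMA merge tree over descriptors
#'
#' Agglomerative merge history in `stats::hclust` convention: row i of
#' `merge` gives the two clusters joined at `height[i]`; negative entries are
#' leaves, positive entries earlier merges. UPGMA on a proper dissimilarity is
#' monotone, so heights are non-decreasing.
#'
#' @slot labels leaf (descriptor) names in input order.
#' @slot merge (n-1) x 2 integer matrix, hclust convention.
#' @slot height merge heights, non-decreasing.
#' @seealso [upgma()], [cutToK()], [exportNewick()]
#' @export
setClass("OdorDendrogram", representation(
  labels = "character", merge = "matrix", height = "numeric"))

setValidity("OdorDendrogram", function(object) {
  n <- length(object@labels)
  if (nrow(object@merge) != n - 1L) return("need n-1 merges for n leaves")
  if (length(object@height) != n - 1L) return("one height per merge")
  if (n > 2L && any(diff(object@height) < -1e-9))
    return("heights must be non-decreasing (UPGMA monotonicity)")
  TRUE
})

#' ClusterAssignment: flat descriptor partition from a dendrogram cut
#'
#' @slot K number of clusters.
#' @slot cluster integer vector in `1..K`, named by descriptor; every cluster
#'   non-empty. Cluster indices are ordered by first-appearing descriptor.
#' @seealso [cutToK()], [buildClusterLabels()]
#' @export
setClass("ClusterAssignment", representation(K = "integer", cluster = "integer"))

setValidity("ClusterAssignment", function(object) {
  if (is.null(names(object@cluster))) return("cluster vector must be named by descriptor")
  if (anyDuplicated(names(object@cluster))) return("each descriptor assigned exactly once")
  if (!setequal(unique(object@cluster), seq_len(object@K)))
    return("all K clusters must be non-empty and indices must be 1..K")
  TRUE
})

#' ClusterLabelMatrix: OR-combined cluster labels per chemical
#'
#' Binary chemicals-by-clusters matrix: entry (i, c) is 1 iff at least one
#' descriptor of cluster c is 1 for chemical i in the catalog. This is the
#' desired output of the predictive network.
#'
#' @slot matrix binary matrix, rownames = chemical ids, ncol = K.
#' @slot K number of clusters.
#' @seealso [buildClusterLabels()], [clusterSizeDistribution()]
#' @export
setClass("ClusterLabelMatrix", representation(matrix = "matrix", K = "integer"))

setValidity("ClusterLabelMatrix", function(object) {
  if (ncol(object@matrix) != object@K) return("ncol must equal K")
  if (!all(object@matrix %in% c(0, 1))) return("entries must be 0 or 1")
  if (is.null(rownames(object@matrix))) return("rownames (chemical ids) required")
  TRUE
})

#' OdorNet: layered sigmoid feed-forward network
#'
#' Fully connected network with sigmoid activations on every hidden and
#' output layer. `weights[[l]]` is the (size_l x size_{l-1}) matrix feeding
#' layer l+1 of the layer list; `biases[[l]]` the matching bias vector.
#' Used for the spectrum autoencoder, the feature-to-label mapping network,
#' and their assembly.
#'
#' @slot layerSizes integer vector, input layer first, length >= 2.
#' @slot weights list of weight matrices.
#' @slot biases list of bias vectors.
#' @seealso [initNetwork()], [nnForward()], [trainNetwork()]
#' @export
setClass("OdorNet", representation(
  layerSizes = "integer", weights = "list", biases = "list"))

setValidity("OdorNet", function(object) {
  L <- length(object@layerSizes)
  if (L < 2L) return("need at least input and output layers")
  if (any(object@layerSizes < 1L)) return("all layer sizes must be >= 1")
  if (length(object@weights) != L - 1L || length(object@biases) != L - 1L)
    return("need one weight matrix and bias vector per connection")
  for (l in seq_len(L - 1L)) {
    if (!identical(dim(object@weights[[l]]),
                   c(object@layerSizes[l + 1L], object@layerSizes[l])))
      return(sprintf("weight matrix %d has wrong shape", l))
    if (length(object@biases[[l]]) != object@layerSizes[l + 1L])
      return(sprintf("bias vector %d has wrong length", l))
  }
  TRUE
})

#' ThresholdedOdorNet: network plus fitted step-function threshold
#'
#' Continuous sigmoid outputs are converted to 0/1 by comparison against a
#' single global threshold theta in (0, 1), fitted on training data.
#'
#' @slot net assembled [OdorNet].
#' @slot theta threshold, strictly inside (0, 1).
#' @seealso [fitThreshold()], [predictOdor()]
#' @export
setClass("ThresholdedOdorNet", representation(net = "OdorNet", theta = "numeric"))

setValidity("ThresholdedOdorNet", function(object) {
  if (length(object@theta) != 1L || object@theta <= 0 || object@theta >= 1)
    return("theta must be a single value strictly inside (0, 1)")
  TRUE
})

#' FoldPlan: cross-validation fold assignment
#'
#' A seeded random partition of `1..n` into k folds whose sizes differ by at
#' most one (remainder samples go to the first folds).
#'
#' @slot n total sample count.
#' @slot k fold count.
#' @slot assignment integer vector of length n mapping sample -> fold in 1..k.
#' @slot seed seed used for the permutation.
#' @seealso [makeFolds()], [crossvalidate()]
#' @export
setClass("FoldPlan", representation(
  n = "integer", k = "integer", assignment = "integer", seed = "integer"))

setValidity("FoldPlan", function(object) {
  if (length(object@assignment) != object@n) return("assignment length must be n")
  sizes <- tabulate(object@assignment, nbins = object@k)
  if (any(sizes == 0L)) return("all folds must be non-empty")
  if (max(sizes) - min(sizes) > 1L) return("fold sizes must differ by at most 1")
  TRUE
})

#' ConfusionRates: pooled binary confusion summary
#'
#' Rates are percentages column-normalized on the desired output, so
#' tpRate + fnRate = 100 and tnRate + fpRate = 100 whenever defined; a rate
#' whose denominator is empty (no positive or no negative truth cells) is NA.
#'
#' @slot tpRate,tnRate,fpRate,fnRate percentages (may be NA).
#' @slot counts 2x2 integer matrix, rows = predicted 1/0, cols = desired 1/0.
#' @seealso [confusionRates()]
#' @export
setClass("ConfusionRates", representation(
  tpRate = "numeric", tnRate = "numeric", fpRate = "numeric",
  fnRate = "numeric", counts = "matrix"))

setValidity("ConfusionRates", function(object) {
  if (!identical(dim(object@counts), c(2L, 2L))) return("counts must be 2x2")
  ok <- function(a, b) is.na(a) || abs(a + b - 100) < 1e-9
  if (!ok(object@tpRate, object@fnRate)) return("tpRate + fnRate must be 100")
  if (!ok(object@tnRate, object@fpRate)) return("tnRate + fpRate must be 100")
  TRUE
})
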