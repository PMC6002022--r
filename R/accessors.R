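#' Chemical identifiers of a container
#'
#' @param x a [SensoryCatalog], [SpectrumMatrix] or [ClusterLabelMatrix].
#' @return character vector of chemical ids (row order).
#' @export
setGeneric("chemicalIds", function(x) standardGeneric("chemicalIds"))

#' @rdname chemicalIds
#' @export
setMethod("chemicalIds", "SensoryCatalog", function(x) rownames(x@matrix))
#' @rdname chemicalIds
#' @export
setMethod("chemicalIds", "SpectrumMatrix", function(x) rownames(x@matrix))
#' @rdname chemicalIds
#' @export
setMethod("chemicalIds", "ClusterLabelMatrix", function(x) rownames(x@matrix))

#' Descriptor names of a container
#'
#' @param x a [SensoryCatalog], [DescriptorDistance], [OdorDendrogram] or
#'   [ClusterAssignment].
#' @return character vector of descriptor names.
#' @export
setGeneric("descriptorNames", function(x) standardGeneric("descriptorNames"))

#' @rdname descriptorNames
#' @export
setMethod("descriptorNames", "SensoryCatalog", function(x) colnames(x@matrix))
#' @rdname descriptorNames
#' @export
setMethod("descriptorNames", "DescriptorDistance", function(x) rownames(x@values))
#' @rdname descriptorNames
#' @export
setMethod("descriptorNames", "OdorDendrogram", function(x) x@labels)
#' @rdname descriptorNames
#' @export
setMethod("descriptorNames", "ClusterAssignment", function(x) names(x@cluster))

#' Underlying numeric matrix of a container
#'
#' @param x a container holding a matrix slot.
#' @return the matrix (binary for catalogs and labels, `[0,1]` for spectra,
#'   dissimilarities for distances, word vectors for embeddings).
#' @export
setGeneric("asMatrix", function(x) standardGeneric("asMatrix"))

#' @rdname asMatrix
#' @export
setMethod("asMatrix", "SensoryCatalog", function(x) x@matrix)
#' @rdname asMatrix
#' @export
setMethod("asMatrix", "SpectrumMatrix", function(x) x@matrix)
#' @rdname asMatrix
#' @export
setMethod("asMatrix", "DescriptorDistance", function(x) x@values)
#' @rdname asMatrix
#' @export
setMethod("asMatrix", "ClusterLabelMatrix", function(x) x@matrix)
#' @rdname asMatrix
#' @export
setMethod("asMatrix", "EmbeddingTable", function(x) x@vectors)

#' m/z window of a SpectrumMatrix
#' @param x a [SpectrumMatrix].
#' @return integer vector `c(mzLo, mzHi)` (inclusive bounds).
#' @export
mzWindow <- function(x) {
  stopifnot(is(x, "SpectrumMatrix"))
  c(x@mzLo, x@mzHi)
}

#' Cluster membership map of a ClusterAssignment
#' @param x a [ClusterAssignment].
#' @return named integer vector descriptor -> cluster index in 1..K.
#' @export
clusterMembers <- function(x) {
  stopifnot(is(x, "ClusterAssignment"))
  x@cluster
}

#' Number of clusters
#' @param x a [ClusterAssignment] or [ClusterLabelMatrix].
#' @return integer K.
#' @export
nClusters <- function(x) x@K

#' Layer sizes of a network
#' @param x an [OdorNet].
#' @return integer vector, input layer first.
#' @export
layerSizes <- function(x) {
  stopifnot(is(x, "OdorNet"))
  x@layerSizes
}

setMethod("show", "SensoryCatalog", function(object) {
  m <- object@matrix
  cat(sprintf("SensoryCatalog: %d chemicals x %d descriptors, sparsity %.4f\n",
              nrow(m), ncol(m), mean(m == 0)))
  cat("  descriptors: ", paste(head(colnames(m), 6), collapse = ", "),
      if (ncol(m) > 6) ", ..." else "", "\n", sep = "")
})

setMethod("show", "MassSpectrum", function(object) {
  cat(sprintf("MassSpectrum '%s': %d peaks, m/z %s\n", object@chemicalId,
              length(object@mz),
              if (length(object@mz)) sprintf("%d..%d", min(object@mz), max(object@mz))
              else "(none)"))
})

setMethod("show", "SpectrumMatrix", function(object) {
  cat(sprintf("SpectrumMatrix: %d chemicals x %d bins (m/z %d..%d), %s-normalized\n",
              nrow(object@matrix), ncol(object@matrix), object@mzLo, object@mzHi,
              if (object@perSpectrum) "per-spectrum" else "globally"))
})

setMethod("show", "EmbeddingTable", function(object) {
  cat(sprintf("EmbeddingTable: %d words, dimension %d\n",
              nrow(object@vectors), ncol(object@vectors)))
})

setMethod("show", "DescriptorDistance", function(object) {
  cat(sprintf("DescriptorDistance (%s): %d descriptors, range [%.3f, %.3f]\n",
              object@method, nrow(object@values), min(object@values),
              max(object@values)))
})

setMethod("show", "OdorDendrogram", function(object) {
  cat(sprintf("OdorDendrogram: %d leaves, %d merges, heights %.4f..%.4f\n",
              length(object@labels), nrow(object@merge),
              min(object@height), max(object@height)))
})

setMethod("show", "ClusterAssignment", function(object) {
  cat(sprintf("ClusterAssignment: %d descriptors in %d clusters (sizes: %s)\n",
              length(object@cluster), object@K,
              paste(tabulate(object@cluster, object@K), collapse = " ")))
})

setMethod("show", "ClusterLabelMatrix", function(object) {
  cat(sprintf("ClusterLabelMatrix: %d chemicals x %d clusters, %d positive cells\n",
              nrow(object@matrix), object@K, sum(object@matrix)))
})

setMethod("show", "OdorNet", function(object) {
  cat(sprintf("OdorNet: layers [%s], %d parameters\n",
              paste(object@layerSizes, collapse = ", "),
              sum(vapply(object@weights, length, 1L)) +
                sum(vapply(object@biases, length, 1L))))
})

setMethod("show", "ThresholdedOdorNet", function(object) {
  cat(sprintf("ThresholdedOdorNet: theta = %.2f over ", object@theta))
  show(object@net)
})

setMethod("show", "FoldPlan", function(object) {
  cat(sprintf("FoldPlan: n = %d, k = %d, sizes [%s], seed %d\n",
              object@n, object@k,
              paste(tabulate(object@assignment, object@k), collapse = ", "),
              object@seed))
})

setMethod("show", "ConfusionRates", function(object) {
  fmt <- function(x) if (is.na(x)) "NA" else sprintf("%.1f%%", x)
  cat(sprintf("ConfusionRates: TP %s, TN %s (FP %s, FN %s)\n",
              fmt(object@tpRate), fmt(object@tnRate), fmt(object@fpRate),
              fmt(object@fnRate)))
})
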