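#' Read word vectors in word2vec text format
#'
#' Format: a header line `vocab_size dim`, then one line per word with the
#' word followed by `dim` whitespace-separated floats. Words are lowercased
#' on ingest.
#'
#' @param path file path.
#' @return an [EmbeddingTable].
#' @seealso [writeWordVectors()], [cosineDissimilarity()]
#' @export
readWordVectors <- function(path) {
  if (!file.exists(path)) stop("word-vector file not found: ", path)
  lines <- readLines(path)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  if (length(hdr) != 2L || anyNA(hdr))
    stop("first line must be the 'vocab_size dim' header")
  nv <- hdr[1]; d <- hdr[2]
  if (length(lines) < nv + 1L) stop("fewer vector lines than the header declares")
  words <- character(nv)
  m <- matrix(NA_real_, nrow = nv, ncol = d)
  for (i in seq_len(nv)) {
    toks <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    if (length(toks) != d + 1L)
      stop(sprintf("line %d: expected word + %d floats", i + 1L, d))
    words[i] <- tolower(toks[1])
    m[i, ] <- as.numeric(toks[-1])
  }
  if (anyNA(m)) stop("non-numeric vector component")
  rownames(m) <- words
  new("EmbeddingTable", vectors = m)
}

#' Write an EmbeddingTable in word2vec text format
#'
#' @param emb an [EmbeddingTable].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeWordVectors <- function(emb, path) {
  stopifnot(is(emb, "EmbeddingTable"))
  m <- asMatrix(emb)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(m), ncol(m)), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste(rownames(m)[i],
                     paste(format(m[i, ], trim = TRUE, digits = 15),
                           collapse = " ")), con)
  invisible(path)
}

#' Resolve descriptors to embedding vectors
#'
#' Out-of-vocabulary policy: exact lowercase match first; failing that, a
#' compound descriptor is split on hyphens and spaces and the token vectors
#' are averaged (all tokens must resolve); otherwise a hard error listing
#' every unresolvable descriptor. A zero vector is an error (its cosine is
#' undefined).
#'
#' @param descriptors character vector of descriptor names.
#' @param emb an [EmbeddingTable].
#' @return matrix of vectors, one row per descriptor.
#' @export
resolveDescriptorVectors <- function(descriptors, emb) {
  stopifnot(is(emb, "EmbeddingTable"))
  m <- asMatrix(emb)
  vocab <- rownames(m)
  out <- matrix(NA_real_, nrow = length(descriptors), ncol = ncol(m),
                dimnames = list(descriptors, NULL))
  missing <- character(0)
  for (i in seq_along(descriptors)) {
    w <- trimws(tolower(descriptors[i]))
    if (w %in% vocab) {
      out[i, ] <- m[w, ]
      next
    }
    toks <- strsplit(w, "[-[:space:]]+")[[1]]
    toks <- toks[nzchar(toks)]
    if (length(toks) > 1L && all(toks %in% vocab)) {
      out[i, ] <- colMeans(m[toks, , drop = FALSE])
    } else {
      missing <- c(missing, descriptors[i])
    }
  }
  if (length(missing))
    stop("descriptors not resolvable in the embedding vocabulary: ",
         paste(missing, collapse = ", "))
  zero <- sqrt(rowSums(out^2)) == 0
  if (any(zero))
    stop("zero embedding vector for: ",
         paste(descriptors[zero], collapse = ", "))
  out
}

#' Correlation dissimilarity between catalog descriptors
#'
#' `d(i, j) = 1 - r(i, j)` with `r` the sample Pearson correlation of the
#' binary descriptor columns over chemicals; range `[0, 2]`, zero diagonal.
#' A zero-variance column has undefined correlations; its off-diagonal
#' correlations are set to 0 (dissimilarity 1) with a warning so the matrix
#' stays total and symmetric.
#'
#' @param cat a [SensoryCatalog] with at least two chemicals.
#' @return a [DescriptorDistance] with method `"correlation"`.
#' @export
correlationDissimilarity <- function(cat) {
  stopifnot(is(cat, "SensoryCatalog"))
  m <- asMatrix(cat)
  if (nrow(m) < 2L) stop("need at least two chemicals for sample correlations")
  sds <- apply(m, 2, stats::sd)
  r <- suppressWarnings(cor(m))
  if (any(sds == 0)) {
    warning(sprintf("%d zero-variance descriptor column(s); their correlations set to 0",
                    sum(sds == 0)), call. = FALSE)
    r[is.na(r)] <- 0
  }
  diag(r) <- 1
  d <- 1 - r
  d[d < 0] <- 0   # guard tiny negative rounding of r slightly above 1
  d <- (d + t(d)) / 2
  diag(d) <- 0
  new("DescriptorDistance", values = d, method = "correlation")
}

#' Cosine dissimilarity between descriptor embeddings
#'
#' `d(i, j) = 1 - (v_i . v_j) / (|v_i| |v_j|)`; range `[0, 2]` (real-valued
#' embeddings can be anti-aligned; no clipping), zero diagonal. Invariant to
#' positive rescaling of any vector.
#'
#' @param descriptors character vector of descriptor names.
#' @param emb an [EmbeddingTable]; descriptors are resolved with the policy
#'   of [resolveDescriptorVectors()].
#' @return a [DescriptorDistance] with method `"cosine"`.
#' @export
cosineDissimilarity <- function(descriptors, emb) {
  v <- resolveDescriptorVectors(descriptors, emb)
  v <- v / sqrt(rowSums(v^2))
  d <- 1 - tcrossprod(v)
  d[d < 0] <- 0
  d <- (d + t(d)) / 2
  diag(d) <- 0
  dimnames(d) <- list(descriptors, descriptors)
  new("DescriptorDistance", values = d, method = "cosine")
}

#' Classical multidimensional scaling of a descriptor distance matrix
#'
#' Metric (classical) MDS: double-center the squared-distance matrix,
#' eigendecompose, and return the top `outDim` coordinate columns (centered
#' at the origin). Negative eigenvalues are truncated at zero; if fewer than
#' `outDim` positive eigenvalues exist the remaining coordinates are
#' zero-padded with a warning.
#'
#' @param dm a [DescriptorDistance].
#' @param outDim target dimension (default 2, for plotting).
#' @return numeric matrix of coordinates, one row per descriptor.
#' @export
mdsEmbed <- function(dm, outDim = 2L) {
  stopifnot(is(dm, "DescriptorDistance"), outDim >= 1L)
  v <- asMatrix(dm)
  n <- nrow(v)
  # cmdscale warns on its own when positive eigenvalues run short; we emit
  # the single padding warning below instead
  fit <- suppressWarnings(cmdscale(as.dist(v), k = min(outDim, n - 1L),
                                   eig = TRUE))
  pts <- fit$points
  if (is.null(dim(pts))) pts <- matrix(pts, nrow = n)
  if (ncol(pts) < outDim) {
    warning(sprintf(
      "only %d positive-eigenvalue dimensions available; padding to %d with zeros",
      ncol(pts), outDim), call. = FALSE)
    pts <- cbind(pts, matrix(0, nrow = n, ncol = outDim - ncol(pts)))
  }
  rownames(pts) <- descriptorNames(dm)
  colnames(pts) <- paste0("dim", seq_len(ncol(pts)))
  pts
}

#' Export MDS coordinates as CSV
#'
#' @param coords matrix from [mdsEmbed()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeMdsCoordinates <- function(coords, path) {
  df <- data.frame(descriptor = rownames(coords), coords,
                   check.names = FALSE, row.names = NULL)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
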