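#' UPGMA (unweighted average linkage) clustering of descriptors
#'
#' Agglomerative clustering: repeatedly merge the closest pair of clusters,
#' where the distance from a merged cluster \eqn{A \cup B} to any other
#' cluster C is the size-weighted average
#' \eqn{(|A| d(A,C) + |B| d(B,C)) / (|A| + |B|)} — equivalently the
#' unweighted mean of the original leaf-pair distances. Deterministic
#' tie-break: active clusters are keyed by their smallest original leaf
#' index and among equally close pairs the lexicographically smallest
#' (key_a, key_b) pair is merged first.
#'
#' @param dm a [DescriptorDistance] with at least two descriptors (NaN
#'   entries are an error).
#' @return an [OdorDendrogram].
#' @seealso [cutToK()], [odorHclust()], [exportNewick()]
#' @export
upgma <- function(dm) {
  stopifnot(is(dm, "DescriptorDistance"))
  d <- asMatrix(dm)
  n <- nrow(d)
  if (n < 2L) stop("need at least two descriptors to cluster")
  if (any(is.nan(d)) || anyNA(d)) stop("NaN/NA in dissimilarity matrix")
  size <- rep(1L, n)
  node <- -(seq_len(n))          # hclust convention: negative = leaf
  active <- seq_len(n)           # cluster keys = smallest original leaf index
  work <- d
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (s in seq_len(n - 1L)) {
    best <- Inf
    for (a in seq_len(length(active) - 1L)) {
      i <- active[a]
      for (b in (a + 1L):length(active)) {
        j <- active[b]
        if (work[i, j] < best) best <- work[i, j]
      }
    }
    # ties (within fp tolerance): lexicographically smallest (key_i, key_j)
    bi <- 0L; bj <- 0L
    for (a in seq_len(length(active) - 1L)) {
      i <- active[a]
      if (bi > 0L) break
      for (b in (a + 1L):length(active)) {
        j <- active[b]
        if (work[i, j] <= best + 1e-12) { bi <- i; bj <- j; break }
      }
    }
    merge[s, ] <- c(node[bi], node[bj])
    height[s] <- best
    for (c0 in active) {
      if (c0 == bi || c0 == bj) next
      work[bi, c0] <- (size[bi] * work[bi, c0] + size[bj] * work[bj, c0]) /
        (size[bi] + size[bj])
      work[c0, bi] <- work[bi, c0]
    }
    size[bi] <- size[bi] + size[bj]
    node[bi] <- s
    active <- setdiff(active, bj)
  }
  new("OdorDendrogram", labels = descriptorNames(dm), merge = merge,
      height = height)
}

# leaf order for plotting / hclust coercion: left-to-right tree traversal
dend_leaf_order <- function(merge) {
  rec <- function(node) {
    if (node < 0L) return(-node)
    c(rec(merge[node, 1L]), rec(merge[node, 2L]))
  }
  rec(nrow(merge))
}

#' Coerce an OdorDendrogram to a stats::hclust object
#'
#' @param dend an [OdorDendrogram].
#' @return an object of class `hclust`, usable with `plot()`, `cutree()` etc.
#' @export
odorHclust <- function(dend) {
  stopifnot(is(dend, "OdorDendrogram"))
  structure(list(merge = dend@merge, height = dend@height,
                 order = dend_leaf_order(dend@merge), labels = dend@labels,
                 method = "average", call = match.call(),
                 dist.method = "descriptor dissimilarity"),
            class = "hclust")
}

#' Cut a dendrogram into exactly K clusters
#'
#' Undoes the last K-1 merges; the connected forests that remain are the
#' clusters. Cutting is by cluster count, not by height (the two coincide
#' for distinct merge heights; a height-based cut is available via
#' [cutAtHeight()]).
#'
#' @param dend an [OdorDendrogram] with n leaves.
#' @param K target number of clusters, `1 <= K <= n`.
#' @return a [ClusterAssignment]; cluster indices are ordered by
#'   first-appearing descriptor for stable output files.
#' @export
cutToK <- function(dend, K) {
  stopifnot(is(dend, "OdorDendrogram"))
  n <- length(dend@labels)
  K <- as.integer(K)
  if (K < 1L || K > n) stop(sprintf("K must lie in 1..%d, got %d", n, K))
  comp <- seq_len(n)
  find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
  applied <- n - K
  if (applied > 0L) {
    reps <- integer(n - 1L)  # representative leaf of each merge node
    for (s in seq_len(applied)) {
      a <- dend@merge[s, 1L]; b <- dend@merge[s, 2L]
      la <- if (a < 0L) -a else reps[a]
      lb <- if (b < 0L) -b else reps[b]
      ra <- find(la); rb <- find(lb)
      comp[max(ra, rb)] <- min(ra, rb)
      reps[s] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(n), find, 1L)
  ids <- match(root, unique(root))  # clusters ordered by first-appearing leaf
  names(ids) <- dend@labels
  new("ClusterAssignment", K = K, cluster = ids)
}

#' Cut a dendrogram at a height threshold
#'
#' Clusters are the forests obtained by undoing every merge whose height
#' exceeds `h`.
#'
#' @param dend an [OdorDendrogram].
#' @param h height threshold.
#' @return a [ClusterAssignment].
#' @export
cutAtHeight <- function(dend, h) {
  stopifnot(is(dend, "OdorDendrogram"))
  K <- length(dend@labels) - sum(dend@height <= h)
  cutToK(dend, max(K, 1L))
}

#' OR-combine catalog descriptors into cluster labels
#'
#' A chemical carries the odor character of a cluster iff at least one
#' member descriptor of that cluster is 1 in the catalog (e.g. a cluster
#' {rose, lavender, iris}: a chemical annotated only "lavender" still gets
#' the cluster bit).
#'
#' @param cat a [SensoryCatalog].
#' @param asg a [ClusterAssignment] covering exactly the catalog's
#'   descriptors.
#' @return a [ClusterLabelMatrix] (chemicals x K).
#' @export
buildClusterLabels <- function(cat, asg) {
  stopifnot(is(cat, "SensoryCatalog"), is(asg, "ClusterAssignment"))
  m <- asMatrix(cat)
  cl <- clusterMembers(asg)
  if (!setequal(colnames(m), names(cl)))
    stop("cluster assignment does not cover exactly the catalog's descriptors")
  lab <- matrix(0, nrow = nrow(m), ncol = asg@K,
                dimnames = list(rownames(m), paste0("cluster", seq_len(asg@K))))
  for (c0 in seq_len(asg@K)) {
    members <- names(cl)[cl == c0]
    lab[, c0] <- as.numeric(rowSums(m[, members, drop = FALSE]) > 0)
  }
  new("ClusterLabelMatrix", matrix = lab, K = asg@K)
}

#' Per-cluster positive-sample counts
#'
#' Column sums of the cluster-label matrix: how many chemicals carry each
#' cluster's odor character. A strongly unbalanced distribution (one huge
#' cluster) flags a degenerate clustering whose predictions carry little
#' information even at high accuracy.
#'
#' @param labels a [ClusterLabelMatrix].
#' @return named integer vector of per-cluster counts.
#' @export
clusterSizeDistribution <- function(labels) {
  stopifnot(is(labels, "ClusterLabelMatrix"))
  counts <- colSums(asMatrix(labels))
  storage.mode(counts) <- "integer"
  counts
}

#' Export a dendrogram as Newick
#'
#' @param dend an [OdorDendrogram].
#' @param path output path (.nwk).
#' @return `path`, invisibly.
#' @export
exportNewick <- function(dend, path) {
  phy <- ape::as.phylo(odorHclust(dend))
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Export a cluster assignment as two-column CSV
#'
#' @param asg a [ClusterAssignment].
#' @param path output CSV path (columns descriptor, cluster_id).
#' @return `path`, invisibly.
#' @export
writeClusterAssignments <- function(asg, path) {
  stopifnot(is(asg, "ClusterAssignment"))
  df <- data.frame(descriptor = names(clusterMembers(asg)),
                   cluster_id = unname(clusterMembers(asg)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
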