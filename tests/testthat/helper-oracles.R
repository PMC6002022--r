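# Independent oracles and small fixture builders shared across the suite.

# Naive UPGMA, coded independently of the package: cluster distance is the
# plain mean over all ORIGINAL leaf pairs (not the Lance-Williams update).
# Same tie-break contract: clusters keyed by smallest original leaf, ties
# within 1e-12 resolved to the lexicographically smallest key pair.
naive_upgma <- function(d) {
  n <- nrow(d)
  clusters <- lapply(seq_len(n), identity)   # leaf index sets
  keys <- seq_len(n)
  node <- -seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  cdist <- function(a, b) mean(d[clusters[[a]], clusters[[b]]])
  for (s in seq_len(n - 1L)) {
    live <- which(!is.na(keys))
    best <- Inf
    for (a in live) for (b in live) {
      if (keys[a] < keys[b]) best <- min(best, cdist(a, b))
    }
    pick <- NULL
    for (ka in sort(keys[live])) {
      for (kb in sort(keys[live])) {
        if (ka < kb && cdist(which(keys == ka), which(keys == kb)) <= best + 1e-12) {
          pick <- c(ka, kb); break
        }
      }
      if (!is.null(pick)) break
    }
    a <- which(keys == pick[1]); b <- which(keys == pick[2])
    merge[s, ] <- c(node[a], node[b])
    height[s] <- cdist(a, b)
    clusters[[a]] <- c(clusters[[a]], clusters[[b]])
    node[a] <- s
    keys[b] <- NA
  }
  list(merge = merge, height = height)
}

# plain-R forward pass oracle: explicit loops, no matrix products
r_forward <- function(weights, biases, x) {
  acts <- list(x)
  a <- x
  for (l in seq_along(weights)) {
    W <- weights[[l]]; b <- biases[[l]]
    z <- numeric(nrow(W))
    for (i in seq_len(nrow(W))) {
      s <- b[i]
      for (j in seq_len(ncol(W))) s <- s + W[i, j] * a[j]
      z[i] <- s
    }
    a <- 1 / (1 + exp(-z))
    acts[[l + 1L]] <- a
  }
  acts
}

# random symmetric dissimilarity; on a coarse grid when ties are wanted so
# tied merge distances actually occur
rand_dissimilarity <- function(n, ties = FALSE, labels = paste0("d", seq_len(n))) {
  v <- if (ties) sample(seq(0.25, 2, by = 0.25), n * (n - 1) / 2, replace = TRUE)
       else runif(n * (n - 1) / 2, 0.05, 2)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  m[lower.tri(m)] <- v
  m <- m + t(m)
  new("DescriptorDistance", values = m, method = "cosine")
}

# small catalog builder
make_catalog <- function(m, ids = sprintf("c%02d", seq_len(nrow(m))),
                         descr = sprintf("d%02d", seq_len(ncol(m)))) {
  suppressWarnings(SensoryCatalog(m, chemicalIds = ids, descriptorNames = descr))
}

# tiny hyperparameter blocks so cross-validation tests stay fast
tiny_cfgs <- function(d, K, seed = 1L, epochs = c(ae = 120, map = 200, ft = 30)) {
  bott <- max(2L, d %/% 4L)
  hid <- max(bott + 1L, d %/% 2L)
  list(aeLayers = c(d, hid, bott, hid, d),
       mapperLayers = c(bott, 8L, K),
       autoencoder = trainingConfig(0.5, 0.3, decay = 0.999, lam = 3e-7,
                                    epochs = epochs["ae"], seed = seed),
       mapper = trainingConfig(0.3, 0.1, decay = 0.999, lam = 2e-7,
                               epochs = epochs["map"], seed = seed + 1L),
       finetune = trainingConfig(0.3, 0.1, decay = 0.999, lam = 2e-7,
                                 epochs = epochs["ft"], seed = seed + 2L))
}

# mean pairwise Pearson correlation (absolute or signed) within/between
# planted groups of a binary catalog
group_correlation_summary <- function(cat, groups) {
  m <- asMatrix(cat)
  r <- suppressWarnings(cor(m[, names(groups), drop = FALSE]))
  r[is.na(r)] <- 0
  within <- c(); between <- c()
  nm <- names(groups)
  for (i in seq_along(nm)) for (j in seq_along(nm)) {
    if (i >= j) next
    if (groups[i] == groups[j]) within <- c(within, r[i, j])
    else between <- c(between, r[i, j])
  }
  list(within = within, between = between)
}

# mean cosine dissimilarity within/between planted groups
group_cosine_summary <- function(dm, groups) {
  v <- asMatrix(dm)[names(groups), names(groups)]
  within <- c(); between <- c()
  nm <- names(groups)
  for (i in seq_along(nm)) for (j in seq_along(nm)) {
    if (i >= j) next
    if (groups[i] == groups[j]) within <- c(within, v[i, j])
    else between <- c(between, v[i, j])
  }
  list(within = within, between = between)
}
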