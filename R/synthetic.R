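# curated odor vocabulary, grouped by semantic family; used for synthetic
# descriptor names so the embedding lookup path sees realistic words
odor_word_groups <- list(
  floral = c("rose", "jasmine", "lily", "iris", "violet", "lavender"),
  dairy = c("milk", "cheese", "butter", "cream", "yogurt", "whey"),
  smoky = c("smoky", "burnt", "roasted", "toasted", "charred", "ashy"),
  citrus = c("lemon", "orange", "lime", "grapefruit", "bergamot", "citrus"),
  woody = c("woody", "cedar", "pine", "sandalwood", "resinous", "balsamic"),
  minty = c("mint", "menthol", "camphor", "eucalyptus", "herbal", "cooling"),
  fruity = c("apple", "pear", "peach", "apricot", "plum", "cherry"),
  sweet = c("honey", "caramel", "vanilla", "sugary", "malty", "toffee"))

odor_rare_words <- c("ozone", "flinty", "metallic", "waxy", "mossy", "earthy",
                     "dusty", "leathery", "animalic", "ambery", "musky", "tarry")

#' Configuration for the synthetic odor world
#'
#' Defaults define the study conditions used throughout the package's
#' simulations: 240 chemicals, 6 semantic groups of 5 descriptors, mutually
#' exclusive descriptor usage, 16-dimensional embeddings with well-separated
#' group directions, 64-bin spectra with rank-6 latent structure and mild
#' additive noise.
#'
#' @param nChemicals number of chemicals.
#' @param nGroups number of planted semantic groups G.
#' @param descriptorsPerGroup descriptors per group.
#' @param exclusive if TRUE, each chemical expresses exactly one (uniformly
#'   chosen) descriptor per active group, reproducing the regime where
#'   semantically similar descriptors are used mutually exclusively and
#'   their pairwise correlations vanish; if FALSE, every member descriptor
#'   of an active group is set independently with probability 0.8,
#'   reproducing the graded-panel regime with high within-group correlation.
#' @param embedDim embedding dimension (>= nGroups).
#' @param groupSeparation scale of the orthogonal group mean directions;
#'   member vectors sit at `groupSeparation * mean + N(0, 0.5)` noise.
#' @param spectrumDim number of m/z bins (spectra occupy m/z 51 ..
#'   50 + spectrumDim).
#' @param latentRank number of nonnegative basis spectra; group g uses basis
#'   `(g - 1) %% latentRank + 1`.
#' @param noiseSd additive Gaussian noise on the unit-scale spectra before
#'   clipping at zero.
#' @param rareDescriptorCount extra descriptors occurring in at most 3
#'   chemicals, to exercise the rarity filter.
#' @param seed integer seed; the same seed gives a byte-identical world.
#' @return a list of class `odorlexSyntheticConfig`.
#' @export
syntheticConfig <- function(nChemicals = 240L, nGroups = 6L,
                            descriptorsPerGroup = 5L, exclusive = TRUE,
                            embedDim = 16L, groupSeparation = 6,
                            spectrumDim = 64L, latentRank = nGroups,
                            noiseSd = 0.02, rareDescriptorCount = 0L,
                            seed = 1L) {
  cfg <- list(nChemicals = as.integer(nChemicals), nGroups = as.integer(nGroups),
              descriptorsPerGroup = as.integer(descriptorsPerGroup),
              exclusive = isTRUE(exclusive), embedDim = as.integer(embedDim),
              groupSeparation = groupSeparation,
              spectrumDim = as.integer(spectrumDim),
              latentRank = as.integer(latentRank), noiseSd = noiseSd,
              rareDescriptorCount = as.integer(rareDescriptorCount),
              seed = as.integer(seed))
  stopifnot(cfg$nChemicals >= 1L, cfg$nGroups >= 1L,
            cfg$descriptorsPerGroup >= 1L, cfg$embedDim >= cfg$nGroups,
            cfg$groupSeparation > 0, cfg$spectrumDim >= 1L,
            cfg$latentRank >= 1L, cfg$noiseSd >= 0,
            cfg$rareDescriptorCount >= 0L)
  class(cfg) <- "odorlexSyntheticConfig"
  cfg
}

synthetic_descriptor_names <- function(cfg) {
  G <- cfg$nGroups; dpg <- cfg$descriptorsPerGroup
  if (G <= length(odor_word_groups) &&
      dpg <= min(lengths(odor_word_groups))) {
    nm <- unlist(lapply(odor_word_groups[seq_len(G)], function(w) w[seq_len(dpg)]),
                 use.names = FALSE)
  } else {
    nm <- paste0("odor", rep(seq_len(G), each = dpg), letters[rep(seq_len(dpg), G)])
  }
  nm
}

#' Generate a complete synthetic odor world
#'
#' Produces a coherent bundle with the statistical structure the prediction
#' method assumes: (1) every chemical gets 1-3 latent odor groups; (2) the
#' binary catalog expresses those groups exclusively or non-exclusively (see
#' [syntheticConfig()]); (3) descriptor embeddings carry the planted groups
#' as well-separated directions; (4) spectra are nonnegative mixtures of
#' group-linked basis spectra plus clipped Gaussian noise, so the catalog is
#' predictable from the spectrum through the group structure; (5) optional
#' rare descriptors occurring at most three times.
#'
#' @param cfg a [syntheticConfig()].
#' @return list with `catalog` ([SensoryCatalog]), `spectra` (list of
#'   [MassSpectrum], m/z starting at 51), `embeddings` ([EmbeddingTable]
#'   covering every descriptor), `trueGroups` ([ClusterAssignment] of the
#'   group descriptors), `groupActivity` (chemicals x G binary matrix),
#'   `mzWindow` (the window matching `spectrumDim`) and `config`.
#' @export
generateWorld <- function(cfg = syntheticConfig()) {
  stopifnot(inherits(cfg, "odorlexSyntheticConfig"))
  set.seed(cfg$seed)
  G <- cfg$nGroups; dpg <- cfg$descriptorsPerGroup
  n <- cfg$nChemicals
  descr <- synthetic_descriptor_names(cfg)
  groupOf <- rep(seq_len(G), each = dpg)

  # planted group activity: 1-3 groups per chemical
  nActive <- sample(seq_len(min(3L, G)), n, replace = TRUE)
  activity <- matrix(0, n, G)
  for (i in seq_len(n)) activity[i, sample.int(G, nActive[i])] <- 1

  # binary catalog
  m <- matrix(0, n, length(descr),
              dimnames = list(sprintf("chem%03d", seq_len(n)), descr))
  for (i in seq_len(n)) {
    for (g in which(activity[i, ] == 1)) {
      members <- which(groupOf == g)
      if (cfg$exclusive) {
        m[i, members[sample.int(dpg, 1L)]] <- 1
      } else {
        on <- members[runif(dpg) < 0.8]
        m[i, on] <- 1
      }
    }
  }

  # rare descriptors (occurrence <= 3), to exercise the rarity filter
  rare <- character(0)
  if (cfg$rareDescriptorCount > 0L) {
    rare <- if (cfg$rareDescriptorCount <= length(odor_rare_words))
      odor_rare_words[seq_len(cfg$rareDescriptorCount)]
    else paste0("rare", seq_len(cfg$rareDescriptorCount))
    rm <- matrix(0, n, length(rare), dimnames = list(rownames(m), rare))
    for (j in seq_along(rare))
      rm[sample.int(n, sample.int(3L, 1L)), j] <- 1
    m <- cbind(m, rm)
  }
  catalog <- suppressWarnings(SensoryCatalog(m))

  # embeddings: orthonormal group directions scaled by groupSeparation
  Q <- qr.Q(qr(matrix(rnorm(cfg$embedDim * G), cfg$embedDim, G)))
  vecs <- t(vapply(seq_along(descr), function(j)
    cfg$groupSeparation * Q[, groupOf[j]] + rnorm(cfg$embedDim, 0, 0.5),
    numeric(cfg$embedDim)))
  if (length(rare))
    vecs <- rbind(vecs, matrix(rnorm(length(rare) * cfg$embedDim),
                               length(rare), cfg$embedDim))
  rownames(vecs) <- c(descr, rare)
  embeddings <- new("EmbeddingTable", vectors = vecs)

  # spectra: nonnegative mixtures of latent basis spectra
  basis <- matrix(0, cfg$latentRank, cfg$spectrumDim)
  for (r in seq_len(cfg$latentRank)) {
    peaks <- runif(cfg$spectrumDim) < 0.25
    if (!any(peaks)) peaks[sample.int(cfg$spectrumDim, 1L)] <- TRUE
    basis[r, peaks] <- abs(rnorm(sum(peaks), 1, 0.5))
  }
  basisOf <- (seq_len(G) - 1L) %% cfg$latentRank + 1L
  mzs <- 51L:(50L + cfg$spectrumDim)
  spectra <- vector("list", n)
  for (i in seq_len(n)) {
    mix <- rep(0, cfg$spectrumDim)
    for (g in which(activity[i, ] == 1))
      mix <- mix + runif(1, 0.5, 1) * basis[basisOf[g], ]
    raw <- pmax(mix + rnorm(cfg$spectrumDim, 0, cfg$noiseSd), 0) * 100
    nz <- which(raw > 0)
    if (!length(nz)) { raw[1] <- 1e-6; nz <- 1L }
    spectra[[i]] <- new("MassSpectrum", chemicalId = rownames(m)[i],
                        mz = mzs[nz], intensity = raw[nz])
  }

  trueGroups <- new("ClusterAssignment", K = G,
                    cluster = stats::setNames(as.integer(groupOf), descr))
  list(catalog = catalog, spectra = spectra, embeddings = embeddings,
       trueGroups = trueGroups, groupActivity = activity,
       mzWindow = c(51L, 50L + cfg$spectrumDim), config = cfg)
}

#' Write a synthetic world to disk in the package's exchange formats
#'
#' Catalog as CSV, spectra as NIST-MSP-style text, embeddings as word2vec
#' text — the same formats the readers consume.
#'
#' @param world result of [generateWorld()].
#' @param dir output directory (created if needed).
#' @return named character vector of the files written, invisibly.
#' @export
writeWorld <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(catalog = file.path(dir, "catalog.csv"),
             spectra = file.path(dir, "spectra.msp"),
             embeddings = file.path(dir, "embeddings.vec"))
  writeCatalog(world$catalog, paths["catalog"])
  writeSpectra(world$spectra, paths["spectra"])
  writeWordVectors(world$embeddings, paths["embeddings"])
  invisible(paths)
}

#' Tiny deterministic worked fixture
#'
#' A hand-checkable bundle: 6 descriptors in 2 planted groups
#' (rose/lily/violet and milk/cheese/butter), 8 chemicals, 8-bin spectra
#' (m/z 51..58) and exact 3-dimensional embeddings. The UPGMA merge order
#' on its cosine matrix is (lily, violet) at 0.04, (cheese, butter) at
#' 0.04, rose joining at 0.30, milk joining at 0.30, and the two families
#' at ~0.782; cutting at K = 2 recovers the planted partition. Chemical
#' `mix1` carries rose and milk, so its OR-labels at K = 2 are (1, 1).
#' `oovDescriptor` names a word deliberately absent from the embedding
#' vocabulary for negative tests.
#'
#' @return list with `catalog`, `spectra`, `embeddings`, `trueGroups`,
#'   `mzWindow`, `oovDescriptor`.
#' @export
generateWorkedFixture <- function() {
  descr <- c("rose", "lily", "violet", "milk", "cheese", "butter")
  vecs <- rbind(
    rose = c(1, 0, 0),
    lily = c(0.8, 0.6, 0),
    violet = c(0.6, 0.8, 0),
    milk = c(0, 0, 1),
    cheese = c(0, 0.6, 0.8),
    butter = c(0, 0.8, 0.6))
  ids <- c("rose1", "lily1", "violet1", "mix1", "milk1", "cheese1", "butter1",
           "mix2")
  m <- matrix(0, 8, 6, dimnames = list(ids, descr))
  m["rose1", "rose"] <- 1
  m["lily1", "lily"] <- 1
  m["violet1", "violet"] <- 1
  m["mix1", c("rose", "milk")] <- 1
  m["milk1", "milk"] <- 1
  m["cheese1", "cheese"] <- 1
  m["butter1", "butter"] <- 1
  m["mix2", c("violet", "cheese")] <- 1
  floralBasis <- c(80, 0, 50, 0, 30, 0, 0, 0)
  dairyBasis <- c(0, 70, 0, 60, 0, 20, 0, 0)
  groupsOf <- list(rose1 = 1, lily1 = 1, violet1 = 1, mix1 = c(1, 2),
                   milk1 = 2, cheese1 = 2, butter1 = 2, mix2 = c(1, 2))
  spectra <- lapply(ids, function(id) {
    raw <- Reduce(`+`, lapply(groupsOf[[id]],
                              function(g) if (g == 1) floralBasis else dairyBasis))
    nz <- which(raw > 0)
    new("MassSpectrum", chemicalId = id, mz = (50L + nz), intensity = raw[nz])
  })
  list(catalog = SensoryCatalog(m),
       spectra = spectra,
       embeddings = new("EmbeddingTable", vectors = vecs),
       trueGroups = new("ClusterAssignment", K = 2L,
                        cluster = stats::setNames(c(1L, 1L, 1L, 2L, 2L, 2L),
                                                  descr)),
       mzWindow = c(51L, 58L),
       oovDescriptor = "petrichor")
}
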