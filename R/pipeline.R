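default_run_config <- function() {
  list(catalog = NULL, spectra = NULL, embeddings = NULL, outdir = "odorlex-out",
       mzWindow = c(51L, 262L), minCount = 4L, method = "word2vec",
       K = 20L, folds = 5L, seed = 1L, scale = "desk", epochs = NULL)
}

# optional per-stage epoch overrides: epochs = list(ae=, map=, ft=)
apply_epoch_overrides <- function(cfgs, epochs) {
  if (is.null(epochs)) return(cfgs)
  if (!is.null(epochs$ae)) cfgs$autoencoder$epochs <- as.integer(epochs$ae)
  if (!is.null(epochs$map)) cfgs$mapper$epochs <- as.integer(epochs$map)
  if (!is.null(epochs$ft)) cfgs$finetune$epochs <- as.integer(epochs$ft)
  cfgs
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full odor-character prediction pipeline
#'
#' Read the catalog, drop rare descriptors, window and normalize the
#' spectra, build the descriptor dissimilarity (word-embedding cosine or
#' catalog correlation), UPGMA-cluster, cut at K, OR-build cluster labels,
#' cross-validate the autoencoder + mapper predictor, and write result
#' files. Every random draw traces back to `seed`. Any stage error aborts
#' with the stage name.
#'
#' @param config a named list, or the path to a YAML file with the same
#'   fields: `catalog`, `spectra`, `embeddings` (paths; `embeddings` may be
#'   omitted for `method = "correlation"`), `outdir`, `mzWindow` (2 ints),
#'   `minCount`, `method` (`"word2vec"` or `"correlation"`), `K` (scalar, or
#'   vector for a sweep), `folds`, `seed`, `scale` (`"desk"` or
#'   `"reference"`).
#' @param world optional in-memory world (as from [generateWorld()]); when
#'   given, the path fields are ignored.
#' @return list with the result table (`results`), the cluster assignment,
#'   the dendrogram and the output file paths; files written to `outdir`:
#'   `clusters.csv`, `dendrogram.nwk`, `mds.csv`, `results.csv`,
#'   `model.json`, `manifest.json`.
#' @export
runPipeline <- function(config = list(), world = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_run_config(), config)
  cfg$method <- match.arg(cfg$method, c("word2vec", "correlation"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(world)) {
    cat0 <- world$catalog
    specs <- world$spectra
    emb <- world$embeddings
    if (!is.null(world$mzWindow)) cfg$mzWindow <- world$mzWindow
  } else {
    cat0 <- run_stage("read_catalog", readCatalog(cfg$catalog))
    specs <- run_stage("read_spectra", readSpectra(cfg$spectra))
    emb <- if (cfg$method == "word2vec")
      run_stage("read_embeddings", readWordVectors(cfg$embeddings)) else NULL
  }

  filt <- run_stage("filter_rare_descriptors",
                    filterRareDescriptors(cat0, cfg$minCount))
  cat1 <- filt$catalog
  message(sprintf("filtered %d rare descriptor(s): %s", length(filt$removed),
                  paste(head(filt$removed, 8), collapse = ", ")))

  sm <- run_stage("build_spectrum_matrix", {
    ord <- match(chemicalIds(cat1), vapply(specs, function(s) s@chemicalId, ""))
    if (anyNA(ord)) stop("spectra missing for some catalog chemicals")
    buildSpectrumMatrix(specs[ord], cfg$mzWindow[1], cfg$mzWindow[2])
  })

  dm <- run_stage("dissimilarity", switch(cfg$method,
    word2vec = cosineDissimilarity(descriptorNames(cat1), emb),
    correlation = correlationDissimilarity(cat1)))

  dend <- run_stage("upgma", upgma(dm))
  coords <- run_stage("mds", mdsEmbed(dm, 2L))

  paths <- c(clusters = file.path(cfg$outdir, "clusters.csv"),
             dendrogram = file.path(cfg$outdir, "dendrogram.nwk"),
             mds = file.path(cfg$outdir, "mds.csv"),
             results = file.path(cfg$outdir, "results.csv"),
             model = file.path(cfg$outdir, "model.json"),
             manifest = file.path(cfg$outdir, "manifest.json"))
  exportNewick(dend, paths["dendrogram"])
  writeMdsCoordinates(coords, paths["mds"])

  folds <- run_stage("make_folds",
                     makeFolds(length(chemicalIds(cat1)), cfg$folds, cfg$seed))

  rows <- list()
  lastAsg <- NULL
  for (K in cfg$K) {
    asg <- run_stage("cut_to_k", cutToK(dend, K))
    lastAsg <- asg
    cfgs <- apply_epoch_overrides(
      pipelineConfigs(ncol(asMatrix(sm)), K, seed = cfg$seed,
                      scale = cfg$scale), cfg$epochs)
    cv <- run_stage("crossvalidate", crossvalidate(cat1, sm, asg, cfgs, folds))
    for (f in seq_len(folds@k)) {
      r <- cv$perFold[[f]]
      rows[[length(rows) + 1L]] <- data.frame(
        fold = f, method = cfg$method, K = K, tp_rate = r@tpRate,
        tn_rate = r@tnRate, threshold = cv$thresholds[f], seed = cfg$seed)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      fold = NA_integer_, method = cfg$method, K = K,
      tp_rate = cv$pooled@tpRate, tn_rate = cv$pooled@tnRate,
      threshold = mean(cv$thresholds), seed = cfg$seed)
  }
  results <- do.call(rbind, rows)
  write.csv(results, paths["results"], row.names = FALSE)
  writeClusterAssignments(lastAsg, paths["clusters"])

  # final model on the full dataset at the last K
  finalK <- cfg$K[length(cfg$K)]
  cfgs <- apply_epoch_overrides(
    pipelineConfigs(ncol(asMatrix(sm)), finalK, seed = cfg$seed,
                    scale = cfg$scale), cfg$epochs)
  labels <- buildClusterLabels(cat1, lastAsg)
  predictor <- run_stage("final_fit",
                         train_fold_predictor(asMatrix(sm), asMatrix(labels),
                                              cfgs))
  writeNetwork(predictor@net, paths["model"],
               meta = list(theta = predictor@theta, K = finalK,
                           method = cfg$method, seed = cfg$seed))

  manifest <- list(
    package_version = as.character(utils::packageVersion("odorlex")),
    config = cfg,
    n_chemicals = length(chemicalIds(cat1)),
    n_descriptors = length(descriptorNames(cat1)),
    removed_descriptors = filt$removed,
    sparsity = sparsity(cat1),
    spectrum_dimensions = ncol(asMatrix(sm)),
    hyperparameters = list(
      ae_layers = cfgs$aeLayers, mapper_layers = cfgs$mapperLayers,
      autoencoder = unclass(cfgs$autoencoder),
      mapper = unclass(cfgs$mapper), finetune = unclass(cfgs$finetune),
      eta_epoch0 = list(autoencoder = cfgs$autoencoder$eta0,
                        mapper = cfgs$mapper$eta0),
      alpha_epoch0 = list(autoencoder = cfgs$autoencoder$alpha0,
                          mapper = cfgs$mapper$alpha0)),
    skipgram_provenance = list(hidden_units = 400L, window_size = 10L,
                               minimum_count = 5L,
                               note = "pre-trained word-vector metadata; embedding training is out of scope"))
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA, null = "null")
  list(results = results, assignment = lastAsg, dendrogram = dend,
       paths = paths)
}
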