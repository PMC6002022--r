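#' Construct a SensoryCatalog from a binary matrix
#'
#' Descriptor names are lowercased and stripped of surrounding whitespace so
#' they can later key into a word-embedding table.
#'
#' @param m numeric/integer matrix of 0/1 values.
#' @param chemicalIds row identifiers (defaults to existing rownames).
#' @param descriptorNames column names (defaults to existing colnames).
#' @return a validated [SensoryCatalog]. Chemicals whose descriptor row is
#'   all-zero are kept but reported in a warning.
#' @export
SensoryCatalog <- function(m, chemicalIds = rownames(m),
                           descriptorNames = colnames(m)) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  rownames(m) <- as.character(chemicalIds)
  colnames(m) <- trimws(tolower(as.character(descriptorNames)))
  obj <- new("SensoryCatalog", matrix = m)
  empty <- rownames(m)[rowSums(m) == 0]
  if (length(empty))
    warning(sprintf("%d chemical(s) have an all-zero descriptor row: %s",
                    length(empty), paste(head(empty, 5), collapse = ", ")),
            call. = FALSE)
  obj
}

#' Read a binary sensory catalog from CSV
#'
#' Expected layout: header row of descriptor names, first column the chemical
#' identifier, remaining cells strictly 0 or 1. A summary (number of
#' chemicals, descriptors, sparsity) is logged on every read.
#'
#' @param path CSV file path.
#' @param idColumn index of the chemical-id column (default 1).
#' @return a [SensoryCatalog].
#' @details Any cell that is not exactly 0 or 1 aborts with an error naming
#'   the offending chemical row and descriptor column; duplicate chemical ids
#'   or descriptor names are validation errors.
#' @seealso [writeCatalog()]
#' @export
readCatalog <- function(path, idColumn = 1L) {
  if (!file.exists(path)) stop("catalog file not found: ", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("catalog needs an id column and at least one descriptor")
  ids <- as.character(df[[idColumn]])
  descNames <- names(df)[-idColumn]   # before subsetting: `[.data.frame` dedupes
  vals <- df[, -idColumn, drop = FALSE]
  names(vals) <- descNames
  m <- matrix(NA_real_, nrow = nrow(vals), ncol = ncol(vals),
              dimnames = list(NULL, descNames))
  for (j in seq_len(ncol(vals)))
    m[, j] <- suppressWarnings(as.numeric(as.character(vals[[j]])))
  bad <- which(is.na(m) | !(m %in% c(0, 1)), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "non-binary cell at chemical '%s', descriptor '%s' (value '%s')",
      ids[bad[1, 1]], names(vals)[bad[1, 2]],
      as.character(vals[bad[1, 1], bad[1, 2]])))
  }
  cat <- SensoryCatalog(m, chemicalIds = ids, descriptorNames = names(vals))
  message(sprintf("read catalog: %d chemicals, %d descriptors, sparsity %.4f",
                  nrow(m), ncol(m), sparsity(cat)))
  cat
}

#' Write a SensoryCatalog to CSV
#'
#' Inverse of [readCatalog()]: first column `chemical_id`, then one 0/1
#' column per descriptor.
#'
#' @param cat a [SensoryCatalog].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeCatalog <- function(cat, path) {
  stopifnot(is(cat, "SensoryCatalog"))
  df <- data.frame(chemical_id = chemicalIds(cat), check.names = FALSE)
  df <- cbind(df, as.data.frame(asMatrix(cat), check.names = FALSE))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Drop descriptors that occur too rarely
#'
#' A descriptor is removed iff its occurrence count (column sum) is strictly
#' below `minCount`; with the default `minCount = 4` this drops descriptors
#' used three times or less. Chemicals are never removed.
#'
#' @param cat a [SensoryCatalog].
#' @param minCount minimum occurrences a descriptor must have to be kept
#'   (positive integer).
#' @return list with elements `catalog` (filtered [SensoryCatalog]) and
#'   `removed` (character vector of dropped descriptor names). Removing every
#'   descriptor is an error.
#' @examples
#' m <- cbind(common = c(1, 1, 1, 1, 0), rare = c(1, 0, 0, 0, 0))
#' rownames(m) <- paste0("chem", 1:5)
#' f <- filterRareDescriptors(SensoryCatalog(m), minCount = 2)
#' f$removed  # "rare"
#' @export
filterRareDescriptors <- function(cat, minCount = 4L) {
  stopifnot(is(cat, "SensoryCatalog"), minCount >= 1L)
  m <- asMatrix(cat)
  keep <- colSums(m) >= minCount
  if (!any(keep)) stop("all descriptors fall below minCount; empty catalog unusable")
  removed <- colnames(m)[!keep]
  out <- suppressWarnings(
    SensoryCatalog(m[, keep, drop = FALSE]))
  list(catalog = out, removed = removed)
}

#' Fraction of zero cells in a catalog
#'
#' @param cat a [SensoryCatalog] with a non-empty matrix.
#' @return fraction of entries equal to zero, in `[0, 1]`.
#' @export
sparsity <- function(cat) {
  stopifnot(is(cat, "SensoryCatalog"))
  m <- asMatrix(cat)
  if (length(m) == 0L) stop("sparsity undefined for an empty catalog")
  mean(m == 0)
}
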