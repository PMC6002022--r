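#' Construct a MassSpectrum
#'
#' Non-integer m/z values are rounded to the nearest unit-resolution bin with
#' a warning (electron-ionization spectra are conventionally unit
#' resolution); intensities landing in the same bin are summed.
#'
#' @param chemicalId identifier string.
#' @param mz m/z values (>= 1).
#' @param intensity non-negative intensities, same length as `mz`.
#' @return a [MassSpectrum].
#' @export
MassSpectrum <- function(chemicalId, mz, intensity) {
  if (any(abs(mz - round(mz)) > 1e-9)) {
    warning(sprintf("non-integer m/z in spectrum '%s' rounded to nearest bin",
                    chemicalId), call. = FALSE)
  }
  mz <- as.integer(round(mz))
  if (any(intensity < 0))
    stop(sprintf("negative intensity in spectrum '%s'", chemicalId))
  agg <- tapply(intensity, mz, sum)
  new("MassSpectrum", chemicalId = as.character(chemicalId),
      mz = as.integer(names(agg)), intensity = as.numeric(agg))
}

parse_msp <- function(lines) {
  specs <- list()
  name <- NULL; npeaks <- NA_integer_; mz <- c(); it <- c(); inpeaks <- FALSE
  flush <- function() {
    if (is.null(name)) return()
    specs[[length(specs) + 1L]] <<- MassSpectrum(name, mz, it)
    name <<- NULL; npeaks <<- NA_integer_; mz <<- c(); it <<- c(); inpeaks <<- FALSE
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") { flush(); next }
    if (grepl("^name\\s*:", ln, ignore.case = TRUE)) {
      flush()
      name <- trimws(sub("^name\\s*:", "", ln, ignore.case = TRUE))
      next
    }
    if (grepl("^num\\s*peaks\\s*:", ln, ignore.case = TRUE)) {
      npeaks <- as.integer(trimws(sub("^num\\s*peaks\\s*:", "", ln,
                                      ignore.case = TRUE)))
      inpeaks <- TRUE
      next
    }
    if (grepl("^[A-Za-z_][A-Za-z0-9_ ]*:", ln) && !inpeaks) next  # other headers
    if (is.null(name)) stop(sprintf("line %d: peak data before 'Name:' record", i))
    toks <- strsplit(gsub(";", " ", ln), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    if (length(vals) == 0L || length(vals) %% 2L != 0L || anyNA(vals))
      stop(sprintf("line %d: malformed peak line '%s'", i, lines[i]))
    idx <- seq(1L, length(vals), by = 2L)
    mz <- c(mz, vals[idx]); it <- c(it, vals[idx + 1L])
  }
  flush()
  specs
}

#' Read electron-ionization mass spectra
#'
#' Two plain-text carriers are supported. NIST-MSP-style text: records with
#' `Name:` and `Num Peaks:` headers followed by whitespace- or
#' semicolon-separated m/z intensity pairs, blank-line separated. Wide CSV:
#' first column the chemical id, remaining columns named by integer m/z.
#' Missing m/z values are implicit zeros in both formats.
#'
#' @param path file path.
#' @param format `"msp"`, `"csv"`, or `"auto"` (by file extension).
#' @return list of [MassSpectrum], one per record.
#' @seealso [writeSpectra()], [buildSpectrumMatrix()]
#' @export
readSpectra <- function(path, format = c("auto", "msp", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("spectrum file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "msp"
  if (format == "msp") return(parse_msp(readLines(path)))
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  mzcols <- names(df)[-1]
  mzvals <- suppressWarnings(as.numeric(mzcols))
  if (anyNA(mzvals)) stop("CSV spectrum columns must be named by m/z value")
  lapply(seq_len(nrow(df)), function(i) {
    it <- as.numeric(df[i, -1])
    nz <- which(it != 0)
    MassSpectrum(df[i, 1], mzvals[nz], it[nz])
  })
}

#' Write spectra as NIST-MSP-style text
#'
#' @param specs list of [MassSpectrum].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSpectra <- function(specs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in specs) {
    stopifnot(is(s, "MassSpectrum"))
    writeLines(sprintf("Name: %s", s@chemicalId), con)
    writeLines(sprintf("Num Peaks: %d", length(s@mz)), con)
    if (length(s@mz))
      writeLines(paste(s@mz, format(s@intensity, trim = TRUE, digits = 15)), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Window and normalize spectra into a SpectrumMatrix
#'
#' Extracts the inclusive m/z window `[mzLo, mzHi]` (defaults 51..262, the
#' odor-relevant range: lighter fragments come from odorless gases, heavier
#' ones from low-volatility molecules) and divides every retained intensity
#' by the single maximum over the whole dataset, giving values in `[0, 1]`
#' whose overall maximum is exactly 1. The default window yields
#' 262 - 51 + 1 = 212 columns.
#'
#' @param specs list of [MassSpectrum].
#' @param mzLo,mzHi inclusive integer window bounds, `mzLo <= mzHi`.
#' @param perSpectrum if TRUE each spectrum is divided by its own window
#'   maximum instead (sensitivity-study option, not the default).
#' @return a [SpectrumMatrix] with one row per spectrum.
#' @details An all-zero window across the dataset leaves the normalization
#'   undefined and is an error. Under `perSpectrum = TRUE`, all-zero rows are
#'   likewise an error.
#' @export
buildSpectrumMatrix <- function(specs, mzLo = 51L, mzHi = 262L,
                                perSpectrum = FALSE) {
  stopifnot(length(specs) > 0L, mzLo <= mzHi)
  mzLo <- as.integer(mzLo); mzHi <- as.integer(mzHi)
  bins <- mzLo:mzHi
  m <- matrix(0, nrow = length(specs), ncol = length(bins),
              dimnames = list(vapply(specs, function(s) s@chemicalId, ""),
                              as.character(bins)))
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    sel <- s@mz >= mzLo & s@mz <= mzHi
    m[i, s@mz[sel] - mzLo + 1L] <- s@intensity[sel]
  }
  if (perSpectrum) {
    rowmax <- apply(m, 1, max)
    if (any(rowmax == 0))
      stop("per-spectrum normalization undefined: all-zero window for some spectra")
    m <- m / rowmax
  } else {
    gmax <- max(m)
    if (gmax == 0)
      stop("normalization undefined: window is all-zero across the dataset")
    m <- m / gmax
  }
  new("SpectrumMatrix", matrix = m, mzLo = mzLo, mzHi = mzHi,
      perSpectrum = perSpectrum)
}
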