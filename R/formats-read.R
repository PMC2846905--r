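## Readers for the five text dialects of pre-processed MRS spectra, plus
## dialect detection. All numeric parsing is strict: plain or scientific
## notation with '.' decimals, fields separated by runs of spaces/tabs,
## '\n' or '\r\n' line endings.

CANONICAL_NPOINTS <- 512L
CANONICAL_PPM_MAX <- 7.2
CANONICAL_PPM_MIN <- -2.8
HRMAS_PPM_MAX <- 4.5
HRMAS_PPM_MIN <- 0.5

#' Detect the dialect of an MRS data file
#'
#' Decides among the supported input dialects: the file extension is
#' consulted first, then content sniffing (XML root tag, the
#' "Number of voxels:" header of 3DiCSI ASCII exports, jMRUI header keys,
#' column/token counts). Detection is deterministic; a file matching no
#' dialect raises an \code{UnknownFormat} error rather than guessing.
#'
#' @param path path to an existing readable file.
#' @return one of \code{"interpret_canonical"}, \code{"interpret_dat"},
#'   \code{"jmrui_txt"}, \code{"dicsi_bsp"}, \code{"hrmas_txt"},
#'   \code{"dataset_xml"}.
#' @export
detectFormat <- function(path) {
  if (!file.exists(path)) mrsStop("UnknownFormat",
                                  sprintf("no such file: %s", path))
  ext <- tolower(sub(".*\\.", "", basename(path)))
  lines <- readLinesCompat(path)
  nonblank <- lines[nzchar(trimws(lines))]
  if (!length(nonblank)) mrsStop("UnknownFormat",
                                 sprintf("empty file: %s", path))

  if (ext == "xml" || grepl("^\\s*<", nonblank[1L])) {
    root <- tryCatch(xml2::xml_name(xml2::xml_root(xml2::read_xml(path))),
                     error = function(e) NA_character_)
    if (identical(root, "DATASET")) return("dataset_xml")
    if (identical(root, "CLASSIFIER")) return("classifier_xml")
    mrsStop("UnknownFormat",
            sprintf("XML root '%s' is neither DATASET nor CLASSIFIER", root))
  }
  if (ext == "bsp") return("dicsi_bsp")
  if (length(nonblank) >= 2L && grepl("^Number of voxels:", nonblank[2L]))
    return("dicsi_bsp")
  if (ext == "dat") return("interpret_dat")
  if (any(grepl("PointsInDataset", head(nonblank, 20L))))
    return("jmrui_txt")
  if (ext %in% c("txt", "art")) {
    tok1 <- splitTokens(nonblank[1L])
    if (length(nonblank) == 1L && length(tok1) == CANONICAL_NPOINTS)
      return("interpret_canonical")
    if (all(vapply(nonblank, function(l) length(splitTokens(l)) == 1L,
                   logical(1L))))
      return("hrmas_txt")
  }
  mrsStop("UnknownFormat",
          sprintf("cannot determine the dialect of %s", path))
}

#' Read a canonical single-voxel spectrum (.txt/.art)
#'
#' One spectrum in one whitespace-separated row of exactly 512 intensities,
#' on the canonical \[7.2; -2.8\] ppm axis (endpoint-inclusive linear
#' mapping). The .art layout is byte-identical to .txt.
#'
#' @param path file path.
#' @return a \linkS4class{Spectrum} of length 512.
#' @export
readInterpretCanonical <- function(path) {
  tokens <- splitTokens(readLinesCompat(path))
  if (length(tokens) != CANONICAL_NPOINTS)
    mrsStop("ParseError", sprintf(
      "%s: expected %d intensities, found %d", path, CANONICAL_NPOINTS,
      length(tokens)))
  Spectrum(parseNumericTokens(tokens, what = "intensity"),
           ppmMax = CANONICAL_PPM_MAX, ppmMin = CANONICAL_PPM_MIN)
}

#' Read an SPSS-style .dat dataset
#'
#' Rows of 514 tokens: class identifier, case identifier, then 512
#' intensities on the canonical axis. The first row is a column-label header
#' and is skipped unread; its contents never influence the result. The class
#' identifier (numeric or textual) is stored as the case's tissue type.
#'
#' @param path file path.
#' @return an \linkS4class{MrsDataset}, one case per data row.
#' @export
readInterpretDat <- function(path) {
  lines <- readLinesCompat(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) mrsStop("ParseError", sprintf("%s: empty file", path))
  body <- lines[-1L]                       # header row skipped, never parsed
  cs <- vector("list", length(body))
  for (i in seq_along(body)) {
    tok <- splitTokens(body[i])
    if (length(tok) != CANONICAL_NPOINTS + 2L)
      mrsStop("ParseError", sprintf(
        "%s row %d: expected %d tokens, found %d", path, i + 1L,
        CANONICAL_NPOINTS + 2L, length(tok)))
    cs[[i]] <- MrsCase(
      id = tok[2L], tissueType = tok[1L],
      spectra = Spectrum(
        parseNumericTokens(tok[-(1:2)], what = "intensity"),
        ppmMax = CANONICAL_PPM_MAX, ppmMin = CANONICAL_PPM_MIN))
  }
  ids <- vapply(cs, function(x) x@id, character(1L))
  if (anyDuplicated(ids))
    mrsStop("DuplicateCaseId", sprintf(
      "%s: duplicate case id '%s'", path, ids[anyDuplicated(ids)]))
  MrsDataset(cs, provenance = path)
}

#' Read a jMRUI text export
#'
#' The header must provide \code{PointsInDataset}, \code{SamplingInterval}
#' (ms) and \code{TransmitterFrequency} (Hz). The data block is a matrix of
#' at least four numeric columns of which only the third — the real part of
#' the FFT — is read; the other columns are ignored entirely. The spectral
#' width in ppm is inferred as (1000 / SamplingInterval) Hz divided by
#' (TransmitterFrequency * 1e-6) Hz-per-ppm, and the descending axis is
#' centred on \code{referencePpm} (default 4.7 ppm, the water resonance; the
#' file does not state a ppm origin, so the inferred range is reported via a
#' message for the user to verify).
#'
#' @param path file path.
#' @param referencePpm chemical shift assigned to the centre of the axis.
#' @return a \linkS4class{Spectrum}.
#' @export
readJmruiTxt <- function(path, referencePpm = 4.7) {
  lines <- readLinesCompat(path)
  getKey <- function(key) {
    hit <- grep(paste0("^\\s*", key, "\\s*:"), lines, value = TRUE)
    if (!length(hit)) mrsStop("ParseError", sprintf(
      "%s: mandatory jMRUI header key '%s' missing", path, key))
    val <- trimws(sub(".*?:", "", hit[1L]))
    parseNumericTokens(val, what = sprintf("header value for %s", key))
  }
  nPoints <- as.integer(getKey("PointsInDataset"))
  samplingMs <- getKey("SamplingInterval")
  freqHz <- getKey("TransmitterFrequency")
  if (nPoints <= 0L || samplingMs <= 0 || freqHz <= 0)
    mrsStop("ParseError", sprintf(
      "%s: jMRUI header fields must be positive", path))

  numericRow <- function(l) {
    tok <- splitTokens(l)
    if (length(tok) < 4L) return(NULL)
    ok <- grepl("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$", tok)
    if (!all(ok)) return(NULL)
    as.numeric(tok)
  }
  rows <- Filter(Negate(is.null), lapply(lines, numericRow))
  if (length(rows) != nPoints)
    mrsStop("ParseError", sprintf(
      "%s: %d data rows but PointsInDataset = %d", path, length(rows),
      nPoints))
  fftReal <- vapply(rows, function(r) r[3L], numeric(1L))

  widthPpm <- (1000 / samplingMs) / (freqHz * 1e-6)
  ppmMax <- referencePpm + widthPpm / 2
  ppmMin <- referencePpm - widthPpm / 2
  message(sprintf(
    "jMRUI import: inferred spectral range [%.4f; %.4f] ppm (width %.4f, centre %.2f)",
    ppmMax, ppmMin, widthPpm, referencePpm))
  Spectrum(fftReal, ppmMax = ppmMax, ppmMin = ppmMin,
           params = c(PointsInDataset = as.character(nPoints),
                      SamplingInterval = as.character(samplingMs),
                      TransmitterFrequency = as.character(freqHz)))
}

#' Read a 3DiCSI ASCII multi-voxel export (.bsp)
#'
#' Header: a free-text name line, "Number of voxels: n",
#' "Number of points per voxel: p", a "Voxel Index:" block, then two numeric
#' columns (Real and Imaginary). Only the Real column is read; total data
#' rows must equal n * p, split into n spectra in file order. When the Voxel
#' Index block parses as (x, y) pairs the grid positions are attached to the
#' spectra (kept for the XML MapPosition node; classification ignores them).
#'
#' @param path file path.
#' @param ppmMax,ppmMin ppm axis endpoints assigned to every voxel spectrum
#'   (the export itself carries no ppm calibration).
#' @return list of \linkS4class{Spectrum}, one per voxel.
#' @export
read3dicsiBsp <- function(path, ppmMax = CANONICAL_PPM_MAX,
                          ppmMin = CANONICAL_PPM_MIN) {
  lines <- readLinesCompat(path)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) < 4L)
    mrsStop("ParseError", sprintf("%s: truncated .bsp header", path))
  getCount <- function(idx, label) {
    l <- lines[nonblank[idx]]
    if (!grepl(paste0("^", label, ":"), l))
      mrsStop("ParseError", sprintf(
        "%s: expected '%s:' on header line %d", path, label, idx))
    as.integer(parseNumericTokens(trimws(sub(".*?:", "", l)), what = label))
  }
  nVox <- getCount(2L, "Number of voxels")
  nPts <- getCount(3L, "Number of points per voxel")
  idxLine <- nonblank[4L]
  if (!grepl("^Voxel Index:", lines[idxLine]))
    mrsStop("ParseError", sprintf(
      "%s: expected 'Voxel Index:' header line", path))

  # Voxel Index block: everything up to the first 2-column numeric row.
  isDataRow <- function(l) {
    tok <- splitTokens(l)
    length(tok) == 2L &&
      all(grepl("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$", tok))
  }
  rest <- lines[seq(idxLine, length(lines))]
  dataStart <- which(vapply(rest, isDataRow, logical(1L)))[1L]
  if (is.na(dataStart))
    mrsStop("ParseError", sprintf("%s: no Real/Imaginary data rows", path))
  idxText <- paste(rest[seq_len(dataStart - 1L)], collapse = " ")
  posMatches <- regmatches(idxText,
    gregexpr("\\(\\s*([0-9]+)\\s*,\\s*([0-9]+)\\s*\\)", idxText))[[1L]]
  positions <- NULL
  if (length(posMatches) == nVox) {
    positions <- lapply(posMatches, function(m) {
      as.integer(splitTokens(gsub("[(),]", " ", m)))
    })
  }

  dataRows <- rest[seq(dataStart, length(rest))]
  dataRows <- dataRows[nzchar(trimws(dataRows))]
  vals <- lapply(dataRows, function(l) {
    tok <- splitTokens(l)
    if (length(tok) != 2L)
      mrsStop("ParseError", sprintf(
        "%s: data rows must have exactly Real and Imaginary columns", path))
    parseNumericTokens(tok[1L], what = "Real value")   # Imaginary never read
  })
  if (length(vals) != nVox * nPts)
    mrsStop("ParseError", sprintf(
      "%s: %d data rows but %d voxels x %d points expected", path,
      length(vals), nVox, nPts))
  real <- unlist(vals)
  lapply(seq_len(nVox), function(v) {
    Spectrum(real[seq((v - 1L) * nPts + 1L, v * nPts)],
             ppmMax = ppmMax, ppmMin = ppmMin,
             mapPosition = if (is.null(positions)) NULL else positions[[v]])
  })
}

#' Read a single-column HRMAS spectrum
#'
#' One intensity per line, any length >= 2 (commonly 1600-3200 points), on a
#' default \[4.5; 0.5\] ppm descending axis.
#'
#' @param path file path.
#' @param ppmMax,ppmMin axis endpoints (defaults 4.5 and 0.5 ppm).
#' @return a \linkS4class{Spectrum}.
#' @export
readHrmasTxt <- function(path, ppmMax = HRMAS_PPM_MAX,
                         ppmMin = HRMAS_PPM_MIN) {
  lines <- readLinesCompat(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L)
    mrsStop("ParseError", sprintf("%s: need at least 2 points", path))
  if (any(vapply(lines, function(l) length(splitTokens(l)) != 1L,
                 logical(1L))))
    mrsStop("ParseError", sprintf("%s: expected a single column", path))
  Spectrum(parseNumericTokens(lines, what = "intensity"),
           ppmMax = ppmMax, ppmMin = ppmMin)
}

#' Read any supported MRS file into a dataset
#'
#' Convenience dispatcher: detects the dialect and wraps single-spectrum
#' dialects into one-case datasets (case id = file base name, tissue type
#' \code{"unknown"} unless given).
#'
#' @param path file path.
#' @param format dialect name, or NULL to auto-detect.
#' @param tissueType tissue type for dialects that do not carry one.
#' @param ... passed through to the dialect reader.
#' @return an \linkS4class{MrsDataset}.
#' @export
readMrsFile <- function(path, format = NULL, tissueType = "unknown", ...) {
  if (is.null(format)) format <- detectFormat(path)
  base <- sub("\\.[^.]*$", "", basename(path))
  wrap <- function(spectra, ids) {
    MrsDataset(mapply(function(s, id) MrsCase(id, tissueType, s), spectra,
                      ids, SIMPLIFY = FALSE),
               provenance = path)
  }
  switch(format,
    interpret_canonical = wrap(list(readInterpretCanonical(path)), base),
    interpret_dat = readInterpretDat(path),
    jmrui_txt = wrap(list(readJmruiTxt(path, ...)), base),
    dicsi_bsp = {
      sp <- read3dicsiBsp(path, ...)
      wrap(sp, paste0(base, "_v", seq_along(sp)))
    },
    hrmas_txt = wrap(list(readHrmasTxt(path, ...)), base),
    dataset_xml = readDatasetXml(path),
    mrsStop("UnknownFormat", sprintf("unsupported dialect '%s'", format))
  )
}
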