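## Synthetic class-structured MRS spectra with known ground truth.
##
## Spectra are sums of Gaussian or Lorentzian lineshapes on a descending
## ppm axis plus i.i.d. Gaussian noise. Peak positions are fixed per class;
## amplitudes vary per case following a lognormal law (so they stay
## positive), mimicking metabolite-concentration variation without
## chemical-shift drift. One global seed drives a per-case seed sequence,
## so a dataset can be extended without changing existing cases.

#' Describe one synthetic resonance peak
#'
#' @param centerPpm peak centre (ppm).
#' @param widthPpm full width at half maximum (ppm), > 0.
#' @param amplitudeMean mean peak height (arbitrary intensity units), > 0.
#' @param amplitudeSd per-case standard deviation of the height (lognormal
#'   amplitude law), >= 0.
#' @param lineshape "gaussian" or "lorentzian".
#' @return a \code{PeakSpec} (a validated list).
#' @export
peakSpec <- function(centerPpm, widthPpm, amplitudeMean, amplitudeSd = 0,
                     lineshape = c("gaussian", "lorentzian")) {
  lineshape <- match.arg(lineshape)
  if (widthPpm <= 0) mrsStop("ParseError", "peak width must be positive")
  if (amplitudeMean <= 0) mrsStop("ParseError", "amplitude must be positive")
  if (amplitudeSd < 0) mrsStop("ParseError", "amplitude sd must be >= 0")
  structure(list(centerPpm = centerPpm, widthPpm = widthPpm,
                 amplitudeMean = amplitudeMean, amplitudeSd = amplitudeSd,
                 lineshape = lineshape), class = "PeakSpec")
}

#' Describe one synthetic class of cases
#'
#' @param name class name.
#' @param tissueTypes named integer vector: tissue-type code -> number of
#'   cases of that type.
#' @param peaks list of \code{\link{peakSpec}} shared by the class.
#' @param noiseSd standard deviation of the additive Gaussian noise, >= 0.
#' @return a \code{ClassSpec} (a validated list).
#' @export
classSpec <- function(name, tissueTypes, peaks, noiseSd = 1) {
  if (is.null(names(tissueTypes)) || any(!nzchar(names(tissueTypes))))
    mrsStop("ParseError", "tissueTypes must be a named count vector")
  if (any(tissueTypes < 1L)) mrsStop("ParseError", "counts must be >= 1")
  if (noiseSd < 0) mrsStop("ParseError", "noiseSd must be >= 0")
  structure(list(name = name, tissueTypes = tissueTypes, peaks = peaks,
                 noiseSd = noiseSd), class = "ClassSpec")
}

lineshapeValues <- function(peak, ppms, amplitude) {
  dx <- ppms - peak$centerPpm
  h <- peak$widthPpm / 2
  shape <- switch(peak$lineshape,
    gaussian = exp(-log(2) * (dx / h)^2),    # unit height, FWHM = widthPpm
    lorentzian = h^2 / (dx^2 + h^2))
  amplitude * shape
}

## Lognormal with prescribed mean m and sd s (s = 0 -> constant m).
drawAmplitude <- function(m, s) {
  if (s == 0) return(m)
  sdlog <- sqrt(log1p((s / m)^2))
  rlnorm(1L, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate one synthetic spectrum
#'
#' Sum of the peak lineshapes on the descending linear ppm axis plus
#' i.i.d. Gaussian noise; bit-for-bit deterministic for a given seed.
#'
#' @param peaks list of \code{\link{peakSpec}}.
#' @param nPoints number of axis points (>= 2).
#' @param ppmHigh,ppmLow axis endpoints.
#' @param noiseSd additive noise standard deviation.
#' @param seed RNG seed.
#' @param mapPosition optional (x, y) grid position to attach.
#' @return a \linkS4class{Spectrum}.
#' @export
generateSpectrum <- function(peaks, nPoints = 512L, ppmHigh = 7.2,
                             ppmLow = -2.8, noiseSd = 1, seed = 1L,
                             mapPosition = NULL) {
  set.seed(as.integer(seed))
  ppms <- ppmAxis(nPoints, ppmHigh, ppmLow)
  v <- numeric(nPoints)
  for (pk in peaks) {
    amp <- drawAmplitude(pk$amplitudeMean, pk$amplitudeSd)
    v <- v + lineshapeValues(pk, ppms, amp)
  }
  if (noiseSd > 0) v <- v + rnorm(nPoints, sd = noiseSd)
  Spectrum(v, ppm = ppms, mapPosition = mapPosition)
}

#' Generate a class-structured synthetic dataset
#'
#' Cases are named \code{<type>_<k>}; the generating class is recorded as
#' the tissue type, so classification accuracy against ground truth is
#' computable. Single-voxel layout attaches one spectrum per case; a
#' multi-voxel layout \code{c(nx, ny)} attaches one spectrum per grid
#' position, each with its (x, y) recorded.
#'
#' @param specs list of \code{\link{classSpec}} with pairwise disjoint
#'   tissue types.
#' @param nPoints,ppmHigh,ppmLow axis geometry shared by all spectra.
#' @param layout "SV" or an integer pair (grid dimensions) for MV.
#' @param seed global seed driving the per-case seed sequence.
#' @return an \linkS4class{MrsDataset}.
#' @export
generateClassDataset <- function(specs, nPoints = 512L, ppmHigh = 7.2,
                                 ppmLow = -2.8, layout = "SV", seed = 1L) {
  if (inherits(specs, "ClassSpec")) specs <- list(specs)
  allTypes <- unlist(lapply(specs, function(s) names(s$tissueTypes)))
  if (anyDuplicated(allTypes))
    mrsStop("OverlappingTypes", sprintf(
      "tissue type '%s' appears in more than one class spec",
      allTypes[anyDuplicated(allTypes)]))
  mv <- !identical(layout, "SV")
  if (mv) layout <- as.integer(layout)

  cs <- list()
  caseIndex <- 0L
  for (sp in specs) {
    for (tt in names(sp$tissueTypes)) {
      for (k in seq_len(sp$tissueTypes[[tt]])) {
        caseIndex <- caseIndex + 1L
        caseSeed <- deriveSeed(seed, caseIndex)
        if (!mv) {
          spectra <- list(generateSpectrum(sp$peaks, nPoints, ppmHigh,
                                           ppmLow, sp$noiseSd, caseSeed))
        } else {
          grid <- expand.grid(x = seq_len(layout[1L]),
                              y = seq_len(layout[2L]))
          spectra <- lapply(seq_len(nrow(grid)), function(v)
            generateSpectrum(sp$peaks, nPoints, ppmHigh, ppmLow,
                             sp$noiseSd, deriveSeed(caseSeed, v),
                             mapPosition = c(grid$x[v], grid$y[v])))
        }
        cs[[caseIndex]] <- MrsCase(sprintf("%s_%d", tt, k), tt, spectra)
      }
    }
  }
  MrsDataset(cs, role = "training")
}

#' The packaged three-super-class scenario
#'
#' A synthetic imitation of a short-TE single-voxel brain-tumour study:
#' 512-point spectra on the canonical \[7.2; -2.8\] ppm axis, three
#' super-classes with the tissue-type composition of a typical multicentre
#' training set (58 meningiomas; 86 glioblastomas + 38 metastases; 22
#' low-grade astrocytomas + 6 oligoastrocytomas + 7 oligodendrogliomas).
#' All classes share creatine (3.03 ppm) and N-acetylaspartate (2.01 ppm)
#' resonances; each has one discriminative marker peak — choline (3.21 ppm)
#' for the meningioma class, lipids/lactate (1.30 ppm) for the aggressive
#' class, myo-inositol (3.55 ppm) for the low-grade glial class — whose
#' height exceeds the other classes' by \code{separation} noise standard
#' deviations (default 10, giving a construction Bayes accuracy of
#' essentially 100\%).
#'
#' @param separation marker-height difference in units of the noise sd.
#' @param noiseSd additive noise sd (intensity units).
#' @param amplitudeCv per-case coefficient of variation of peak heights.
#' @return list of \code{\link{classSpec}} (pass to
#'   [generateClassDataset()]).
#' @export
defaultScenario <- function(separation = 10, noiseSd = 1,
                            amplitudeCv = 0.05) {
  common <- list(
    peakSpec(3.03, 0.07, 12, 12 * amplitudeCv),           # creatine
    peakSpec(2.01, 0.07, 15, 15 * amplitudeCv))           # NAA
  marker <- function(ppm) peakSpec(ppm, 0.07, separation * noiseSd,
                                   separation * noiseSd * amplitudeCv)
  list(
    classSpec("low-grade m", c(mm = 58L),
              c(common, list(marker(3.21))), noiseSd),    # choline
    classSpec("aggressive", c(gl = 86L, me = 38L),
              c(common, list(marker(1.30))), noiseSd),    # lipids/lactate
    classSpec("low-grade g", c(a2 = 22L, oa = 6L, od = 7L),
              c(common, list(marker(3.55))), noiseSd))    # myo-inositol
}

#' Class definitions matching a scenario
#'
#' @param specs list of \code{\link{classSpec}}.
#' @return list of \linkS4class{ClassDefinition} with the same grouping.
#' @export
scenarioClasses <- function(specs) {
  lapply(specs, function(s) ClassDefinition(s$name, names(s$tissueTypes)))
}

#' Discriminative marker positions of a scenario
#'
#' The ppm positions of peaks that appear in exactly one class — the
#' features a sensible selection method should recover.
#'
#' @param specs list of \code{\link{classSpec}}.
#' @return numeric vector of ppm positions.
#' @export
scenarioMarkers <- function(specs) {
  centers <- lapply(specs, function(s)
    vapply(s$peaks, function(p) p$centerPpm, numeric(1L)))
  all <- unlist(centers)
  unique(all[vapply(all, function(ppm)
    sum(vapply(centers, function(cc) ppm %in% cc, logical(1L))) == 1L,
    logical(1L))])
}

#' Write a dataset out as fixture files in a given dialect
#'
#' Emits files that the corresponding reader parses back to the same
#' intensities (printed at 17 significant digits, so doubles survive
#' exactly). Single-spectrum dialects write one file per case named
#' \code{<tissue>__<id>.<ext>}, so the tissue type survives the round trip;
#' multi-voxel datasets are supported by the .bsp and XML dialects only.
#'
#' @param dataset an \linkS4class{MrsDataset}.
#' @param dialect one of the five input dialects or "dataset_xml".
#' @param dir output directory (created if needed).
#' @return character vector of the files written.
#' @export
writeFixtureFiles <- function(dataset, dialect, dir) {
  stopifnot(is(dataset, "MrsDataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cs <- cases(dataset)
  multiVoxel <- any(vapply(cs, function(x) length(x@spectra) > 1L,
                           logical(1L)))
  if (multiVoxel && !dialect %in% c("dicsi_bsp", "dataset_xml"))
    mrsStop("UnsupportedCombination", sprintf(
      "multi-voxel datasets cannot be written as %s", dialect))
  stem <- function(cs) file.path(dir, sprintf("%s__%s", cs@tissueType, cs@id))

  if (dialect == "interpret_canonical") {
    vapply(cs, function(x) {
      v <- x@spectra[[1L]]@intensities
      if (length(v) != CANONICAL_NPOINTS)
        mrsStop("UnsupportedCombination",
                "canonical dialect requires 512-point spectra")
      f <- paste0(stem(x), ".txt")
      writeLines(paste(formatFull(v), collapse = " "), f)
      f
    }, character(1L))
  } else if (dialect == "interpret_dat") {
    if (any(vapply(cs, function(x)
      length(x@spectra[[1L]]@intensities) != CANONICAL_NPOINTS,
      logical(1L))))
      mrsStop("UnsupportedCombination", ".dat requires 512-point spectra")
    f <- file.path(dir, "dataset.dat")
    header <- paste(c("class", "case", paste0("p", seq_len(CANONICAL_NPOINTS))),
                    collapse = " ")
    rows <- vapply(cs, function(x)
      paste(c(x@tissueType, x@id, formatFull(x@spectra[[1L]]@intensities)),
            collapse = " "), character(1L))
    writeLines(c(header, rows), f)
    f
  } else if (dialect == "jmrui_txt") {
    vapply(cs, function(x) {
      sp <- x@spectra[[1L]]
      n <- length(sp@intensities)
      width <- sp@ppm[1L] - sp@ppm[n]
      freq <- 63860000
      sampling <- 1000 / (width * freq * 1e-6)   # ms, reproduces the width
      f <- paste0(stem(x), ".txt")
      # cols 1/2/4 are documented-ignored; filled with placeholder values
      rows <- sprintf("%s %s %s %s", "0.0", "0.0",
                      formatFull(sp@intensities), "0.0")
      writeLines(c("jMRUI fixture export",
                   sprintf("PointsInDataset: %d", n),
                   sprintf("SamplingInterval: %s", formatFull(sampling)),
                   sprintf("TransmitterFrequency: %d", freq),
                   "", "Signal and FFT", rows), f)
      f
    }, character(1L))
  } else if (dialect == "hrmas_txt") {
    vapply(cs, function(x) {
      f <- paste0(stem(x), ".txt")
      writeLines(formatFull(x@spectra[[1L]]@intensities), f)
      f
    }, character(1L))
  } else if (dialect == "dicsi_bsp") {
    vapply(cs, function(x) {
      nPts <- length(x@spectra[[1L]]@intensities)
      f <- paste0(stem(x), ".bsp")
      idx <- vapply(x@spectra, function(sp)
        if (length(sp@mapPosition) == 2L)
          sprintf("(%d, %d)", sp@mapPosition[1L], sp@mapPosition[2L])
        else "(0, 0)", character(1L))
      dataRows <- unlist(lapply(x@spectra, function(sp)
        sprintf("%s 0.0", formatFull(sp@intensities))))
      writeLines(c(sprintf("Fixture set %s", x@id),
                   sprintf("Number of voxels: %d", length(x@spectra)),
                   sprintf("Number of points per voxel: %d", nPts),
                   paste("Voxel Index:", paste(idx, collapse = "\t")),
                   dataRows), f)
      f
    }, character(1L))
  } else if (dialect == "dataset_xml") {
    f <- file.path(dir, "dataset.xml")
    writeDatasetXml(dataset, f)
    f
  } else {
    mrsStop("UnknownFormat", sprintf("unsupported dialect '%s'", dialect))
  }
}

#' Read back a directory of fixture files
#'
#' Inverse of [writeFixtureFiles()]: reconstructs the dataset, recovering
#' tissue types from the \code{<tissue>__<id>} file naming (or from the
#' file contents for .dat and XML).
#'
#' @param dir directory written by [writeFixtureFiles()].
#' @param dialect the dialect that was written.
#' @param ... passed to the dialect reader (e.g. ppm overrides).
#' @return an \linkS4class{MrsDataset}.
#' @export
readFixtureFiles <- function(dir, dialect, ...) {
  if (dialect == "interpret_dat")
    return(readInterpretDat(file.path(dir, "dataset.dat")))
  if (dialect == "dataset_xml")
    return(readDatasetXml(file.path(dir, "dataset.xml"), ...))
  ext <- if (dialect == "dicsi_bsp") "\\.bsp$" else "\\.txt$"
  files <- sort(list.files(dir, pattern = ext, full.names = TRUE))
  cs <- lapply(files, function(f) {
    base <- sub("\\.[^.]*$", "", basename(f))
    parts <- strsplit(base, "__", fixed = TRUE)[[1L]]
    tissue <- parts[1L]; id <- paste(parts[-1L], collapse = "__")
    spectra <- switch(dialect,
      interpret_canonical = list(readInterpretCanonical(f)),
      jmrui_txt = list(suppressMessages(readJmruiTxt(f, ...))),
      hrmas_txt = list(readHrmasTxt(f, ...)),
      dicsi_bsp = read3dicsiBsp(f, ...),
      mrsStop("UnknownFormat", sprintf("unsupported dialect '%s'", dialect)))
    MrsCase(id, tissue, spectra)
  })
  MrsDataset(cs, provenance = files)
}
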