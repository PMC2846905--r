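#' Extract a region of interest from a spectrum
#'
#' Returns the intensities at every axis point p with
#' \code{ppmLow <= p <= ppmHigh} (interval closed on both ends), in
#' descending-ppm order, together with their ppm labels.
#'
#' @param spectrum a \linkS4class{Spectrum}.
#' @param roi a \linkS4class{RegionOfInterest}.
#' @return list with \code{intensities} and \code{ppm}.
#' @examples
#' s <- Spectrum(seq_len(512), ppmMax = 7.2, ppmMin = -2.8)
#' length(extractRoi(s, RegionOfInterest(4.5, 0.5))$ppm)  # 205
#' @export
extractRoi <- function(spectrum, roi) {
  stopifnot(is(spectrum, "Spectrum"), is(roi, "RegionOfInterest"))
  keep <- spectrum@ppm >= roi@ppmLow & spectrum@ppm <= roi@ppmHigh
  if (!any(keep))
    mrsStop("EmptyRoi", sprintf(
      "no axis point falls in [%g; %g] ppm", roi@ppmHigh, roi@ppmLow))
  list(intensities = spectrum@intensities[keep], ppm = spectrum@ppm[keep])
}

#' Build the cases x features design matrix
#'
#' In single-dataset mode each row is the region of interest of the case's
#' first spectrum (features tagged DS1). When a second dataset is supplied,
#' cases are matched by ID across the two datasets and each row is the ROI
#' of the DS1 spectrum followed by the ROI of the DS2 spectrum (two
#' acquisitions of the same case, e.g. at two echo times, concatenated into
#' one feature vector). Cases present in only one dataset are dropped with a
#' warning; cases whose tissue type belongs to no class are excluded.
#'
#' @param train an \linkS4class{MrsDataset}.
#' @param classes list of \linkS4class{ClassDefinition}; 2-4 classes with
#'   pairwise disjoint tissue types.
#' @param roi a \linkS4class{RegionOfInterest}.
#' @param second optional second \linkS4class{MrsDataset} for concatenation.
#' @return a \linkS4class{DesignMatrix}.
#' @export
buildDesignMatrix <- function(train, classes, roi, second = NULL) {
  stopifnot(is(train, "MrsDataset"), is(roi, "RegionOfInterest"))
  if (is(classes, "ClassDefinition")) classes <- list(classes)
  if (length(classes) < 2L || length(classes) > 4L)
    mrsStop("ClassOverlap", "between 2 and 4 classes are required")
  allTypes <- unlist(lapply(classes, function(cd) cd@memberTypes))
  if (anyDuplicated(allTypes))
    mrsStop("ClassOverlap", sprintf(
      "tissue type '%s' appears in more than one class",
      allTypes[anyDuplicated(allTypes)]))

  typeToClass <- setNames(
    rep(seq_along(classes), vapply(classes, function(cd)
      length(cd@memberTypes), integer(1L))),
    allTypes)

  cs1 <- cases(train)
  if (!is.null(second)) {
    ids1 <- caseIds(train)
    ids2 <- caseIds(second)
    common <- intersect(ids1, ids2)
    dropped <- c(setdiff(ids1, ids2), setdiff(ids2, ids1))
    if (length(dropped))
      warning(sprintf(
        "%d case(s) present in only one dataset dropped: %s",
        length(dropped), paste(head(dropped, 5L), collapse = ", ")))
    cs1 <- cases(train)[match(common, ids1)]
    cs2 <- cases(second)[match(common, ids2)]
  }

  rows <- list(); ys <- integer(); ids <- character(); tts <- character()
  labels <- NULL
  for (i in seq_along(cs1)) {
    cls <- typeToClass[cs1[[i]]@tissueType]
    if (is.na(cls)) next                      # tissue type outside all classes
    r1 <- extractRoi(cs1[[i]]@spectra[[1L]], roi)
    vec <- r1$intensities
    lab <- data.frame(dataset = "DS1", ppm = r1$ppm)
    if (!is.null(second)) {
      r2 <- extractRoi(cs2[[i]]@spectra[[1L]], roi)
      vec <- c(vec, r2$intensities)
      lab <- rbind(lab, data.frame(dataset = "DS2", ppm = r2$ppm))
    }
    if (is.null(labels)) {
      labels <- lab
    } else if (nrow(lab) != nrow(labels) ||
               any(abs(lab$ppm - labels$ppm) > 1e-9)) {
      mrsStop("ParseError", sprintf(
        "case '%s': spectra in one dataset must share resolution and axis",
        cs1[[i]]@id))
    }
    rows[[length(rows) + 1L]] <- vec
    ys <- c(ys, cls)
    ids <- c(ids, cs1[[i]]@id)
    tts <- c(tts, cs1[[i]]@tissueType)
  }
  if (!length(rows))
    mrsStop("NoCases", "no case matches the defined classes")
  new("DesignMatrix",
      X = do.call(rbind, rows), y = as.integer(ys), caseIds = ids,
      tissueTypes = tts,
      featureDataset = labels$dataset, featurePpm = labels$ppm,
      classNames = vapply(classes, function(cd) cd@name, character(1L)),
      classDefs = classes)
}

#' Assemble a design matrix from a plain matrix
#'
#' Convenience constructor for workflows that already hold a cases x
#' features matrix (simulations, tests); [buildDesignMatrix()] is the
#' spectra-based route.
#'
#' @param X numeric matrix, cases x features.
#' @param y class labels: integers in \code{1..length(classNames)}.
#' @param classNames class names; default "C1", "C2", ...
#' @param featurePpm per-column ppm labels; default a descending index.
#' @param featureDataset per-column dataset tags; default "DS1".
#' @param caseIds row identifiers; default "case_1", ...
#' @return a \linkS4class{DesignMatrix}.
#' @export
designMatrix <- function(X, y, classNames = NULL, featurePpm = NULL,
                         featureDataset = NULL, caseIds = NULL) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (is.null(classNames)) classNames <- paste0("C", seq_len(max(y)))
  if (is.null(featurePpm)) featurePpm <- rev(seq_len(ncol(X)))
  if (is.null(featureDataset)) featureDataset <- rep("DS1", ncol(X))
  if (is.null(caseIds)) caseIds <- paste0("case_", seq_len(nrow(X)))
  new("DesignMatrix", X = X, y = y, caseIds = as.character(caseIds),
      tissueTypes = character(),
      featureDataset = featureDataset, featurePpm = as.numeric(featurePpm),
      classNames = classNames,
      classDefs = lapply(classNames, function(nm) ClassDefinition(nm, nm)))
}

#' Per-class mean and standard-deviation profile
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of the
#' design-matrix rows of one class, per feature — the summary used to plot a
#' class mean spectrum with its dispersion band.
#'
#' @param dm a \linkS4class{DesignMatrix}.
#' @param classIndex class index (1-based).
#' @return list with \code{mean} and \code{sd} vectors.
#' @export
classProfile <- function(dm, classIndex) {
  stopifnot(is(dm, "DesignMatrix"))
  rows <- which(dm@y == classIndex)
  if (!length(rows)) mrsStop("EmptyClass", sprintf(
    "class %d has no member", classIndex))
  if (length(rows) < 2L) mrsStop("EmptyClass", sprintf(
    "class %d has a single member: sd undefined", classIndex))
  sub <- dm@X[rows, , drop = FALSE]
  list(mean = colMeans(sub), sd = apply(sub, 2L, sd))
}

#' Subset a design matrix to selected feature columns
#'
#' @param dm a \linkS4class{DesignMatrix}.
#' @param columns integer column indices to keep (in the given order).
#' @return a \linkS4class{DesignMatrix} on the selected columns.
#' @export
selectColumns <- function(dm, columns) {
  new("DesignMatrix", X = dm@X[, columns, drop = FALSE], y = dm@y,
      caseIds = dm@caseIds, tissueTypes = dm@tissueTypes,
      featureDataset = dm@featureDataset[columns],
      featurePpm = dm@featurePpm[columns],
      classNames = dm@classNames, classDefs = dm@classDefs)
}

#' Read class definitions from a YAML config
#'
#' The config maps class names to lists of tissue-type codes, e.g.
#' \preformatted{
#' low-grade m: [mm]
#' aggressive: [gl, me]
#' low-grade g: [a2, oa, od]
#' }
#'
#' @param path YAML file path.
#' @return list of \linkS4class{ClassDefinition}.
#' @export
readClassConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  lapply(names(cfg), function(nm)
    ClassDefinition(nm, as.character(unlist(cfg[[nm]]))))
}
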