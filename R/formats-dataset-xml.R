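## DATASET XML interchange format.
##
## <DATASET>
##   <Case ID="...">
##     <Tissue Type="..."/>
##     <Spectrum>
##       <Parameters><Param key="..." value="..."/>...</Parameters>
##       <Points>intensity intensity ...</Points>
##       <MapPosition x="..." y="..."/>
##     </Spectrum>
##     ...
##   </Case>
##   ...
## </DATASET>
##
## Parameters and MapPosition are optional. Parameters children are opaque
## key-value pairs round-tripped verbatim; the writer adds PpmMax/PpmMin so
## the axis survives the round trip. Numbers are printed at 17 significant
## digits, so doubles round-trip exactly.

schemaStop <- function(pathStr, msg) {
  mrsStop("SchemaError", sprintf("%s: %s", pathStr, msg))
}

#' Write a dataset to DATASET XML
#'
#' @param dataset an \linkS4class{MrsDataset}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @seealso [readDatasetXml()]
#' @export
writeDatasetXml <- function(dataset, path) {
  stopifnot(is(dataset, "MrsDataset"))
  doc <- xml2::xml_new_root("DATASET")
  for (cs in dataset@cases) {
    caseNode <- xml2::xml_add_child(doc, "Case", ID = cs@id)
    xml2::xml_add_child(caseNode, "Tissue", Type = cs@tissueType)
    for (sp in cs@spectra) {
      spNode <- xml2::xml_add_child(caseNode, "Spectrum")
      n <- length(sp@intensities)
      pars <- c(PpmMax = formatFull(sp@ppm[1L]),
                PpmMin = formatFull(sp@ppm[n]),
                sp@params[setdiff(names(sp@params), c("PpmMax", "PpmMin"))])
      parNode <- xml2::xml_add_child(spNode, "Parameters")
      for (k in names(pars))
        xml2::xml_add_child(parNode, "Param", key = k,
                            value = unname(pars[[k]]))
      xml2::xml_add_child(spNode, "Points",
                          paste(formatFull(sp@intensities), collapse = " "))
      if (length(sp@mapPosition) == 2L)
        xml2::xml_add_child(spNode, "MapPosition",
                            x = as.character(sp@mapPosition[1L]),
                            y = as.character(sp@mapPosition[2L]))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a DATASET XML file
#'
#' Validates the structure while reading; the first offending node is named
#' in the \code{SchemaError} (e.g. \code{/DATASET/Case[2]}).
#'
#' @param path file path.
#' @param ppmMax,ppmMin fallback axis endpoints for spectra whose Parameters
#'   node does not carry PpmMax/PpmMin.
#' @return an \linkS4class{MrsDataset}.
#' @export
readDatasetXml <- function(path, ppmMax = CANONICAL_PPM_MAX,
                           ppmMin = CANONICAL_PPM_MIN) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) mrsStop("SchemaError", conditionMessage(e)))
  if (xml2::xml_name(doc) != "DATASET")
    schemaStop("/", sprintf("root element is '%s', expected DATASET",
                            xml2::xml_name(doc)))
  caseNodes <- xml2::xml_find_all(doc, "./Case")
  cs <- vector("list", length(caseNodes))
  for (i in seq_along(caseNodes)) {
    cpath <- sprintf("/DATASET/Case[%d]", i)
    cn <- caseNodes[[i]]
    id <- xml2::xml_attr(cn, "ID")
    if (is.na(id) || !nzchar(id)) schemaStop(cpath, "missing ID attribute")
    tissue <- xml2::xml_find_first(cn, "./Tissue")
    if (inherits(tissue, "xml_missing"))
      schemaStop(cpath, "missing Tissue node")
    type <- xml2::xml_attr(tissue, "Type")
    if (is.na(type)) schemaStop(paste0(cpath, "/Tissue"),
                                "missing Type attribute")
    spNodes <- xml2::xml_find_all(cn, "./Spectrum")
    if (!length(spNodes)) schemaStop(cpath, "case has no Spectrum node")
    spectra <- vector("list", length(spNodes))
    for (j in seq_along(spNodes)) {
      spath <- sprintf("%s/Spectrum[%d]", cpath, j)
      sn <- spNodes[[j]]
      ptsNode <- xml2::xml_find_first(sn, "./Points")
      if (inherits(ptsNode, "xml_missing"))
        schemaStop(spath, "missing Points node")
      vals <- tryCatch(
        parseNumericTokens(splitTokens(xml2::xml_text(ptsNode)),
                           what = "intensity"),
        error = function(e) schemaStop(paste0(spath, "/Points"),
                                       conditionMessage(e)))
      params <- character()
      parNode <- xml2::xml_find_first(sn, "./Parameters")
      if (!inherits(parNode, "xml_missing")) {
        kids <- xml2::xml_find_all(parNode, "./Param")
        params <- setNames(xml2::xml_attr(kids, "value"),
                           xml2::xml_attr(kids, "key"))
      }
      hi <- ppmMax; lo <- ppmMin
      if (all(c("PpmMax", "PpmMin") %in% names(params))) {
        hi <- as.numeric(params[["PpmMax"]])
        lo <- as.numeric(params[["PpmMin"]])
      }
      mp <- NULL
      mpNode <- xml2::xml_find_first(sn, "./MapPosition")
      if (!inherits(mpNode, "xml_missing")) {
        mp <- c(as.integer(xml2::xml_attr(mpNode, "x")),
                as.integer(xml2::xml_attr(mpNode, "y")))
        if (anyNA(mp)) schemaStop(paste0(spath, "/MapPosition"),
                                  "x and y attributes required")
      }
      keep <- setdiff(names(params), c("PpmMax", "PpmMin"))
      spectra[[j]] <- Spectrum(vals, ppmMax = hi, ppmMin = lo,
                               mapPosition = mp, params = params[keep])
    }
    cs[[i]] <- MrsCase(id, type, spectra)
  }
  ids <- vapply(cs, function(x) x@id, character(1L))
  if (anyDuplicated(ids))
    schemaStop(sprintf("/DATASET/Case[%d]", anyDuplicated(ids)),
               sprintf("duplicate case id '%s'", ids[anyDuplicated(ids)]))
  MrsDataset(cs, provenance = path)
}
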