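## CLASSIFIER XML interchange format.
##
## <CLASSIFIER name classification-method creation-date sigma>
##   <Dataset path="..."/>
##   <Classes>
##     <Class name prior mean><TumourType>..</TumourType>...</Class>...
##   </Classes>
##   <Boundaries>                                    (optional; C = 2 or 3)
##     <IntersectionPoint coords="..."/>             (optional)
##     <Point pair="a|b" coords="..."/>...
##   </Boundaries>
##   <Features Method="..."><Feature dataset ppm/>...</Features>
##   <Weights><Weight dataset ppm>w1 [w2 ...]</Weight>...</Weights>
##   <EvaluationResults>                             (optional)
##     <Bootstrapping mean sd><Class name mean sd/>...</Bootstrapping>
##     <AUC><Class name auc/>...</AUC>
##   </EvaluationResults>
## </CLASSIFIER>
##
## The Gaussian-posterior parameters (per-class projected mean and prior,
## common sigma) are stored alongside the six main nodes so a classifier
## file alone reconstructs the full model. All numbers at 17 significant
## digits; the creation-date attribute is ignored on equality comparison.

#' Write a trained classifier to CLASSIFIER XML
#'
#' @param model a fitted \linkS4class{FisherLDAModel}.
#' @param path output file path.
#' @param features optional \linkS4class{FeatureSelectionResult} that
#'   produced the model's feature set.
#' @param boundaries optional \linkS4class{Boundaries}; computed
#'   automatically for 2- and 3-class models when omitted.
#' @param bootstrap optional bootstrap \linkS4class{ResamplingResult}.
#' @param roc optional \linkS4class{RocResult} with per-class AUCs.
#' @param name classifier name attribute.
#' @param datasetPath path of the training dataset file, recorded verbatim.
#' @param date creation date (ISO-8601); defaults to now.
#' @return \code{path}, invisibly.
#' @export
writeClassifierXml <- function(model, path, features = NULL,
                               boundaries = NULL, bootstrap = NULL,
                               roc = NULL, name = "classifier",
                               datasetPath = "",
                               date = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")) {
  stopifnot(is(model, "FisherLDAModel"))
  C <- length(model@classNames)
  if (is.null(boundaries) && C <= 3L) boundaries <- computeBoundaries(model)

  doc <- xml2::xml_new_root("CLASSIFIER", name = name,
                            `classification-method` = "Fisher LDA",
                            `creation-date` = date,
                            sigma = formatFull(model@sigma))
  xml2::xml_add_child(doc, "Dataset", path = datasetPath)

  clsNode <- xml2::xml_add_child(doc, "Classes")
  defs <- attr(model, "classDefs")
  for (k in seq_len(C)) {
    types <- model@classNames[k]
    if (!is.null(defs) && length(defs) >= k)
      types <- defs[[k]]@memberTypes
    cn <- xml2::xml_add_child(clsNode, "Class", name = model@classNames[k],
                              prior = formatFull(model@priors[k]),
                              mean = paste(formatFull(model@classMeansProj[k, ]),
                                           collapse = " "))
    for (tt in types) xml2::xml_add_child(cn, "TumourType", tt)
  }

  if (!is.null(boundaries)) {
    bNode <- xml2::xml_add_child(doc, "Boundaries")
    if (length(boundaries@intersectionPoint))
      xml2::xml_add_child(bNode, "IntersectionPoint",
        coords = paste(formatFull(boundaries@intersectionPoint),
                       collapse = " "))
    for (r in seq_len(nrow(boundaries@points)))
      xml2::xml_add_child(bNode, "Point", pair = boundaries@pairs[r],
        coords = paste(formatFull(boundaries@points[r, ]), collapse = " "))
  }

  method <- if (is.null(features)) "none" else features@method
  fNode <- xml2::xml_add_child(doc, "Features", Method = method)
  for (j in seq_along(model@featurePpm))
    xml2::xml_add_child(fNode, "Feature", dataset = model@featureDataset[j],
                        ppm = formatFull(model@featurePpm[j]))

  wNode <- xml2::xml_add_child(doc, "Weights")
  for (j in seq_along(model@featurePpm))
    xml2::xml_add_child(wNode, "Weight", dataset = model@featureDataset[j],
                        ppm = formatFull(model@featurePpm[j]),
                        paste(formatFull(model@weights[j, ]), collapse = " "))

  if (!is.null(bootstrap) || !is.null(roc)) {
    eNode <- xml2::xml_add_child(doc, "EvaluationResults")
    if (!is.null(bootstrap)) {
      bsNode <- xml2::xml_add_child(eNode, "Bootstrapping",
                                    mean = formatFull(bootstrap@overallMean),
                                    sd = formatFull(bootstrap@overallSd))
      for (k in seq_along(bootstrap@perClassMean))
        xml2::xml_add_child(bsNode, "Class",
          name = model@classNames[k],
          mean = formatFull(bootstrap@perClassMean[k]),
          sd = formatFull(bootstrap@perClassSd[k]))
    }
    if (!is.null(roc)) {
      aNode <- xml2::xml_add_child(eNode, "AUC")
      for (nm in names(roc@perClass))
        xml2::xml_add_child(aNode, "Class", name = nm,
                            auc = formatFull(roc@perClass[[nm]]$auc))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

parseCoords <- function(node, attrName = "coords") {
  parseNumericTokens(splitTokens(xml2::xml_attr(node, attrName)),
                     what = attrName)
}

#' Read a CLASSIFIER XML file
#'
#' @param path file path.
#' @return a list with components \code{model}
#'   (\linkS4class{FisherLDAModel}), \code{classes} (list of
#'   \linkS4class{ClassDefinition}), \code{boundaries}
#'   (\linkS4class{Boundaries} or NULL), \code{featureMethod},
#'   \code{evaluation} (list with \code{bootstrapMean}, \code{bootstrapSd},
#'   \code{perClass} data frame and \code{auc} named vector, or NULL),
#'   \code{name}, \code{date} and \code{datasetPath}.
#' @export
readClassifierXml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) mrsStop("SchemaError",
                                              conditionMessage(e)))
  if (xml2::xml_name(doc) != "CLASSIFIER")
    schemaStop("/", sprintf("root element is '%s', expected CLASSIFIER",
                            xml2::xml_name(doc)))
  sigma <- as.numeric(xml2::xml_attr(doc, "sigma"))
  if (is.na(sigma)) schemaStop("/CLASSIFIER", "missing sigma attribute")

  clsNodes <- xml2::xml_find_all(doc, "./Classes/Class")
  if (!length(clsNodes)) schemaStop("/CLASSIFIER/Classes", "no Class nodes")
  classNames <- xml2::xml_attr(clsNodes, "name")
  priors <- as.numeric(xml2::xml_attr(clsNodes, "prior"))
  means <- do.call(rbind, lapply(clsNodes, parseCoords, attrName = "mean"))
  defs <- lapply(seq_along(clsNodes), function(k) {
    ClassDefinition(classNames[k],
      xml2::xml_text(xml2::xml_find_all(clsNodes[[k]], "./TumourType")))
  })

  fNodes <- xml2::xml_find_all(doc, "./Weights/Weight")
  if (!length(fNodes)) schemaStop("/CLASSIFIER/Weights", "no Weight nodes")
  featureDataset <- xml2::xml_attr(fNodes, "dataset")
  featurePpm <- as.numeric(xml2::xml_attr(fNodes, "ppm"))
  W <- do.call(rbind, lapply(fNodes, function(n)
    parseNumericTokens(splitTokens(xml2::xml_text(n)), what = "weight")))

  model <- new("FisherLDAModel", weights = W, classMeansProj = means,
               sigma = sigma, priors = priors, classNames = classNames,
               featureDataset = featureDataset, featurePpm = featurePpm)
  attr(model, "classDefs") <- defs

  boundaries <- NULL
  bNode <- xml2::xml_find_first(doc, "./Boundaries")
  if (!inherits(bNode, "xml_missing")) {
    ipNode <- xml2::xml_find_first(bNode, "./IntersectionPoint")
    ip <- if (inherits(ipNode, "xml_missing")) numeric() else
      parseCoords(ipNode)
    pNodes <- xml2::xml_find_all(bNode, "./Point")
    pts <- if (length(pNodes))
      do.call(rbind, lapply(pNodes, parseCoords)) else
      matrix(numeric(), 0L, max(1L, length(ip)))
    boundaries <- new("Boundaries", intersectionPoint = ip, points = pts,
                      pairs = if (length(pNodes))
                        xml2::xml_attr(pNodes, "pair") else character())
  }

  evaluation <- NULL
  eNode <- xml2::xml_find_first(doc, "./EvaluationResults")
  if (!inherits(eNode, "xml_missing")) {
    evaluation <- list(bootstrapMean = NULL, bootstrapSd = NULL,
                       perClass = NULL, auc = NULL)
    bsNode <- xml2::xml_find_first(eNode, "./Bootstrapping")
    if (!inherits(bsNode, "xml_missing")) {
      evaluation$bootstrapMean <- as.numeric(xml2::xml_attr(bsNode, "mean"))
      evaluation$bootstrapSd <- as.numeric(xml2::xml_attr(bsNode, "sd"))
      kids <- xml2::xml_find_all(bsNode, "./Class")
      evaluation$perClass <- data.frame(
        class = xml2::xml_attr(kids, "name"),
        mean = as.numeric(xml2::xml_attr(kids, "mean")),
        sd = as.numeric(xml2::xml_attr(kids, "sd")))
    }
    aKids <- xml2::xml_find_all(eNode, "./AUC/Class")
    if (length(aKids))
      evaluation$auc <- setNames(as.numeric(xml2::xml_attr(aKids, "auc")),
                                 xml2::xml_attr(aKids, "name"))
  }

  list(model = model, classes = defs, boundaries = boundaries,
       featureMethod = xml2::xml_attr(
         xml2::xml_find_first(doc, "./Features"), "Method"),
       evaluation = evaluation,
       name = xml2::xml_attr(doc, "name"),
       date = xml2::xml_attr(doc, "creation-date"),
       datasetPath = xml2::xml_attr(
         xml2::xml_find_first(doc, "./Dataset"), "path"))
}
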