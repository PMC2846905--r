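writeTmp <- function(lines, ext = "txt") {
  f <- tempfile(fileext = paste0(".", ext))
  writeLines(lines, f)
  f
}

test_that("format detection is deterministic and refuses the unknown", {
  xmlFile <- tempfile(fileext = ".xml")
  writeDatasetXml(MrsDataset(list(MrsCase("c1", "mm",
    Spectrum(rep(0, 8), ppmMax = 4, ppmMin = 1)))), xmlFile)
  expect_identical(detectFormat(xmlFile), "dataset_xml")

  bsp <- writeTmp(c("some set", "Number of voxels: 1",
                    "Number of points per voxel: 2", "Voxel Index: (1, 1)",
                    "1.0 0.0", "2.0 0.0"), "weird")
  expect_identical(detectFormat(bsp), "dicsi_bsp")

  canonical <- writeTmp(paste(rep("0.0", 512), collapse = " "))
  expect_identical(detectFormat(canonical), "interpret_canonical")

  hrmas <- writeTmp(as.character(seq_len(40)))
  expect_identical(detectFormat(hrmas), "hrmas_txt")

  expect_error(detectFormat(writeTmp(character())), class = "UnknownFormat")
  expect_error(detectFormat(writeTmp("not a spectrum at all")),
               class = "UnknownFormat")
})

test_that("canonical single-row reader enforces 512 points on the [7.2; -2.8] axis", {
  s <- readInterpretCanonical(writeTmp(paste(rep("0.0", 512),
                                             collapse = " ")))
  expect_length(intensities(s), 512L)
  expect_equal(ppm(s)[1], 7.2)
  expect_equal(ppm(s)[512], -2.8)
  expect_lt(max(diff(ppm(s))), 0)

  expect_error(
    readInterpretCanonical(writeTmp(paste(rep("1", 511), collapse = " "))),
    class = "ParseError")
  badTok <- c(rep("1.0", 511), "x")
  expect_error(
    readInterpretCanonical(writeTmp(paste(badTok, collapse = " "))),
    class = "ParseError")

  # increasing intensities survive a DATASET XML round trip bit-for-bit
  s2 <- readInterpretCanonical(writeTmp(paste(
    sprintf("%.17g", seq(1, 512) + 0.25), collapse = " ")))
  f <- tempfile(fileext = ".xml")
  writeDatasetXml(MrsDataset(list(MrsCase("c", "mm", s2))), f)
  back <- readDatasetXml(f)
  expect_identical(intensities(cases(back)[[1]]@spectra[[1]]),
                   intensities(s2))
})

test_that(".dat reader: header skipped, 514 tokens per row, duplicate ids rejected", {
  row <- function(cls, id) paste(c(cls, id, sprintf("%.1f", seq_len(512))),
                                 collapse = " ")
  f <- writeTmp(c("these labels are ignored", row("mm", "c1"),
                  row("gl", "c2"), row("gl", "c3")))
  ds <- readInterpretDat(f)
  expect_identical(nCases(ds), 3L)
  expect_identical(tissueTypes(ds), c("mm", "gl", "gl"))
  expect_length(intensities(cases(ds)[[1]]@spectra[[1]]), 512L)

  # header-only file is an empty dataset, not an error
  expect_identical(nCases(readInterpretDat(writeTmp("just a header"))), 0L)

  short <- paste(c("mm", "c1", sprintf("%.1f", seq_len(511))),
                 collapse = " ")
  expect_error(readInterpretDat(writeTmp(c("h", short))),
               class = "ParseError")
  expect_error(readInterpretDat(writeTmp(c("h", row("mm", "c1"),
                                           row("gl", "c1")))),
               class = "DuplicateCaseId")

  # corrupting the ignored header row changes nothing
  f2 <- writeTmp(c("@@@ utterly ~ different ### header @@@",
                   row("mm", "c1"), row("gl", "c2"), row("gl", "c3")))
  ds2 <- readInterpretDat(f2)
  expect_identical(intensities(cases(ds2)[[2]]@spectra[[1]]),
                   intensities(cases(ds)[[2]]@spectra[[1]]))
})

jmruiLines <- function(n = 8L, col3 = sprintf("%d.5", seq_len(8L)),
                       col4 = 99 * seq_along(col3),
                       freqLine = "TransmitterFrequency: 63860000") {
  k <- seq_along(col3)                      # data rows follow col3's length
  c("jMRUI export", sprintf("PointsInDataset: %d", n),
    "SamplingInterval: 1", freqLine, "",
    sprintf("%g %g %s %g", k, -k, col3, col4))
}

test_that("jMRUI reader: spectral width inferred from header, only fft(real) column read", {
  f <- writeTmp(jmruiLines())
  s <- suppressMessages(readJmruiTxt(f))
  # 1000 Hz sweep width over 63.86 Hz-per-ppm
  expect_equal(ppm(s)[1] - ppm(s)[8], 1000 / 63.86, tolerance = 1e-12)
  expect_equal(mean(ppm(s)[c(1, 8)]), 4.7)           # centred on water
  expect_identical(intensities(s), as.numeric(sprintf("%d.5", 1:8)))

  # corrupting the ignored 4th column never changes the parsed result
  f4 <- writeTmp(jmruiLines(col4 = rnorm(8L)))
  expect_identical(intensities(suppressMessages(readJmruiTxt(f4))),
                   intensities(s))

  expect_error(
    suppressMessages(readJmruiTxt(writeTmp(
      jmruiLines(freqLine = "SomethingElse: 1")))),
    class = "ParseError")
  expect_error(
    suppressMessages(readJmruiTxt(writeTmp(jmruiLines(n = 9L)))),
    class = "ParseError")
})

bspLines <- function(nVox = 4L, nPts = 256L, real = NULL, imag = NULL) {
  total <- nVox * nPts
  if (is.null(real)) real <- seq_len(total) / 7
  if (is.null(imag)) imag <- rep(0, total)
  idx <- paste(sprintf("(%d, %d)", rep(1:2, length.out = nVox),
                       rep(1:2, each = 2, length.out = nVox)),
               collapse = "\t")
  c("a multivoxel set", sprintf("Number of voxels: %d", nVox),
    sprintf("Number of points per voxel: %d", nPts),
    paste("Voxel Index:", idx),
    sprintf("%.10g %.10g", real, imag))
}

test_that(".bsp reader: voxel splitting, Real column only, grid positions", {
  sp <- read3dicsiBsp(writeTmp(bspLines(), "bsp"))
  expect_length(sp, 4L)
  expect_length(intensities(sp[[1]]), 256L)
  expect_identical(mapPosition(sp[[1]]), c(1L, 1L))

  one <- read3dicsiBsp(writeTmp(bspLines(1L, 8L, real = 1:8,
                                         imag = rnorm(8)), "bsp"))
  expect_identical(intensities(one[[1]]), as.numeric(1:8))

  # corrupting the Imaginary column never changes the parsed result
  a <- read3dicsiBsp(writeTmp(bspLines(2L, 8L, imag = rep(0, 16)), "bsp"))
  b <- read3dicsiBsp(writeTmp(bspLines(2L, 8L, imag = rnorm(16)), "bsp"))
  expect_identical(lapply(a, intensities), lapply(b, intensities))

  truncated <- bspLines(4L, 256L)
  expect_error(read3dicsiBsp(writeTmp(head(truncated, -1L), "bsp")),
               class = "ParseError")
})

test_that("HRMAS reader: single column, default [4.5; 0.5] ppm axis", {
  s <- readHrmasTxt(writeTmp(sprintf("%.6f", rnorm(1639))))
  expect_length(intensities(s), 1639L)
  expect_equal(ppm(s)[1], 4.5)
  expect_equal(ppm(s)[1639], 0.5)

  expect_length(intensities(readHrmasTxt(writeTmp(c("1.5", "2.5")))), 2L)
  expect_error(readHrmasTxt(writeTmp(c("1.0", "abc", "2.0"))),
               class = "ParseError")
})

test_that("DATASET XML round-trips the data model and validates structure", {
  set.seed(11)
  mv <- lapply(1:4, function(v)
    Spectrum(rnorm(16), ppmMax = 7.2, ppmMin = -2.8,
             mapPosition = c((v - 1L) %% 2L + 1L, (v - 1L) %/% 2L + 1L)))
  ds <- MrsDataset(list(
    MrsCase("sv1", "mm", Spectrum(rnorm(32), ppmMax = 7.2, ppmMin = -2.8,
                                  params = c(EchoTime = "30"))),
    MrsCase("mv1", "gl", mv)))
  f <- tempfile(fileext = ".xml")
  writeDatasetXml(ds, f)
  back <- readDatasetXml(f)

  expect_identical(caseIds(back), caseIds(ds))
  expect_identical(tissueTypes(back), tissueTypes(ds))
  for (i in 1:2) for (j in seq_along(cases(ds)[[i]]@spectra)) {
    expect_identical(intensities(cases(back)[[i]]@spectra[[j]]),
                     intensities(cases(ds)[[i]]@spectra[[j]]))
    expect_identical(mapPosition(cases(back)[[i]]@spectra[[j]]),
                     mapPosition(cases(ds)[[i]]@spectra[[j]]))
  }
  # opaque Parameters children round-trip verbatim
  expect_identical(cases(back)[[1]]@spectra[[1]]@params[["EchoTime"]], "30")

  # write(read(write(x))) reproduces the file byte-for-byte
  f2 <- tempfile(fileext = ".xml")
  writeDatasetXml(back, f2)
  expect_identical(readBin(f, "raw", file.size(f)),
                   readBin(f2, "raw", file.size(f2)))

  # a Case without its Tissue node is named in the error
  bad <- tempfile(fileext = ".xml")
  writeLines(c("<DATASET><Case ID='x'>",
               "<Spectrum><Points>1 2</Points></Spectrum>",
               "</Case></DATASET>"), bad)
  expect_error(readDatasetXml(bad), "/DATASET/Case\\[1\\]",
               class = "SchemaError")
})

test_that("CLASSIFIER XML stores the model, boundaries and evaluation losslessly", {
  dm <- randomDesignMatrix(n = 30L, p = 4L, C = 3L, seed = 5L, sep = 6)
  model <- fitFisherLDA(dm)
  fsel <- greedyStepwiseFS(dm, "forward")
  bs <- bootstrapEval(dm, N = 25L, seed = 3L)
  rr <- multiclassRoc(model, dm)

  f <- tempfile(fileext = ".xml")
  writeClassifierXml(model, f, features = fsel, bootstrap = bs, roc = rr,
                     name = "demo", date = "2026-01-01T00:00:00")
  doc <- xml2::read_xml(f)
  # three-class model: 1 intersection point, 3 boundary segment endpoints
  expect_length(xml2::xml_find_all(doc, "/CLASSIFIER/Boundaries/IntersectionPoint"), 1L)
  expect_length(xml2::xml_find_all(doc, "/CLASSIFIER/Boundaries/Point"), 3L)
  bsNode <- xml2::xml_find_first(doc, "/CLASSIFIER/EvaluationResults/Bootstrapping")
  expect_false(is.na(xml2::xml_attr(bsNode, "mean")))
  expect_false(is.na(xml2::xml_attr(bsNode, "sd")))
  expect_length(xml2::xml_find_all(bsNode, "./Class"), 3L)
  expect_length(xml2::xml_find_all(doc, "/CLASSIFIER/EvaluationResults/AUC/Class"), 3L)

  back <- readClassifierXml(f)
  expect_identical(unname(weights(back$model)), unname(weights(model)))
  expect_identical(sigma(back$model), sigma(model))
  expect_identical(unname(classMeans(back$model)), unname(classMeans(model)))
  expect_identical(unname(priors(back$model)), unname(priors(model)))
  expect_identical(back$featureMethod, "sequential-forward")
  expect_identical(back$evaluation$bootstrapMean, bs@overallMean)
  expect_identical(unname(back$evaluation$auc),
                   unname(vapply(rr@perClass, function(x) x$auc, numeric(1))))

  # two-class model: a single threshold point, no segment endpoints
  dm2 <- separatedDesignMatrix()
  m2 <- fitFisherLDA(dm2)
  f2 <- tempfile(fileext = ".xml")
  writeClassifierXml(m2, f2, date = "2026-01-01T00:00:00")
  doc2 <- xml2::read_xml(f2)
  expect_length(xml2::xml_find_all(doc2, "/CLASSIFIER/Boundaries/IntersectionPoint"), 1L)
  expect_length(xml2::xml_find_all(doc2, "/CLASSIFIER/Boundaries/Point"), 0L)
})

test_that("every dialect writer round-trips through its reader", {
  sc <- tinyScenario(nPerType = 2L)
  sv <- generateClassDataset(sc, seed = 9L)
  svIntensities <- lapply(cases(sv), function(cs)
    intensities(cs@spectra[[1]]))

  for (dialect in c("interpret_canonical", "interpret_dat", "jmrui_txt",
                    "hrmas_txt", "dataset_xml")) {
    dir <- file.path(tempfile(), dialect)
    writeFixtureFiles(sv, dialect, dir)
    back <- readFixtureFiles(dir, dialect)
    expect_identical(sort(caseIds(back)), sort(caseIds(sv)),
                     info = dialect)
    ord <- match(caseIds(sv), caseIds(back))
    expect_identical(lapply(cases(back)[ord], function(cs)
      intensities(cs@spectra[[1]])), svIntensities, info = dialect)
    expect_identical(tissueTypes(back)[ord], tissueTypes(sv),
                     info = dialect)
  }

  # multi-voxel dataset through .bsp, grid positions preserved
  mv <- generateClassDataset(tinyScenario(nPerType = 1L), seed = 2L,
                             nPoints = 64L, layout = c(2L, 2L))
  dir <- tempfile()
  writeFixtureFiles(mv, "dicsi_bsp", dir)
  backMv <- readFixtureFiles(dir, "dicsi_bsp")
  ord <- match(caseIds(mv), caseIds(backMv))
  for (i in seq_along(cases(mv))) {
    orig <- cases(mv)[[i]]; got <- cases(backMv)[[ord[i]]]
    expect_identical(lapply(got@spectra, intensities),
                     lapply(orig@spectra, intensities))
    expect_identical(lapply(got@spectra, mapPosition),
                     lapply(orig@spectra, mapPosition))
  }
  expect_error(writeFixtureFiles(mv, "interpret_canonical", tempfile()),
               class = "UnsupportedCombination")
})
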