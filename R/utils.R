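#' @import methods
#' @importFrom stats cor sd var predict rnorm rlnorm runif setNames
#' @importFrom utils head tail
NULL

## Classed conditions: every user-facing failure carries a condition class
## (e.g. "ParseError", "SchemaError") so callers can branch on the kind of
## failure rather than on message text.
mrsStop <- function(class, msg, call. = FALSE) {
  stop(structure(
    class = c(class, "mrsError", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

mrsWarn <- function(class, msg) {
  warning(structure(
    class = c(class, "mrsWarning", "warning", "condition"),
    list(message = msg, call = NULL)
  ))
}

## Strict numeric token parsing: plain or scientific notation, '.' decimal
## separator only. Anything else (including "1,5" or "abc") is an error.
parseNumericTokens <- function(tokens, class = "ParseError",
                               what = "numeric field") {
  ok <- grepl("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$", tokens)
  if (!all(ok)) {
    mrsStop(class, sprintf("non-numeric %s: '%s'", what,
                           tokens[which(!ok)[1L]]))
  }
  as.numeric(tokens)
}

## Split a line (or whole file content) on runs of spaces/tabs.
splitTokens <- function(x) {
  x <- gsub("^[ \t]+|[ \t]+$", "", x)
  x <- x[nzchar(x)]
  unlist(strsplit(x, "[ \t]+"))
}

## Read text lines accepting both '\n' and '\r\n'.
readLinesCompat <- function(path) {
  raw <- readLines(path, warn = FALSE)
  sub("\r$", "", raw)
}

#' Linear descending ppm axis
#'
#' Maps point index \code{i} (1-based) to
#' \code{ppmMax - (i-1) * (ppmMax - ppmMin) / (n - 1)}: both endpoints are
#' included and the axis is strictly decreasing, matching the convention of
#' writing a spectral range high-to-low (e.g. \[7.2; -2.8\] ppm).
#'
#' @param n number of points (>= 2)
#' @param ppmMax chemical shift of the first point (ppm)
#' @param ppmMin chemical shift of the last point (ppm); must be < ppmMax
#' @return numeric vector of length \code{n}, strictly decreasing
#' @examples
#' ppmAxis(512, 7.2, -2.8)[c(1, 512)]
#' @export
ppmAxis <- function(n, ppmMax, ppmMin) {
  if (n < 2L) mrsStop("ParseError", "a ppm axis needs at least 2 points")
  if (ppmMax <= ppmMin) {
    mrsStop("ParseError", "ppmMax must be greater than ppmMin")
  }
  ppmMax - (seq_len(n) - 1) * (ppmMax - ppmMin) / (n - 1)
}

## Full-precision decimal representation for XML serialisation (17
## significant digits: doubles round-trip exactly).
formatFull <- function(x) {
  vapply(x, function(v) sprintf("%.17g", v), character(1L))
}

## Deterministic per-case seed sequence derived from one global seed, so a
## dataset can be extended without changing already-generated cases.
deriveSeed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + as.double(k) * 7919) %% 2147483587)
}
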