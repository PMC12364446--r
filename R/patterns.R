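# Projector pattern generation: sinusoidal and binary fringes plus the
# four-step phase-shift sequences used by the classical pipeline.

patternCosArg <- function(spec) {
  # cos argument along the fringe axis, one value per pixel of that axis
  n <- if (spec@orientation == "vertical") spec@width else spec@height
  u <- seq_len(n) - 1
  2 * pi * spec@frequency * u / n + spec@phaseShift
}

patternFromProfile <- function(spec, profile) {
  if (spec@orientation == "vertical")
    matrix(profile, nrow = spec@height, ncol = spec@width, byrow = TRUE)
  else
    matrix(profile, nrow = spec@height, ncol = spec@width)
}

#' Render a sinusoidal fringe pattern
#'
#' Vertical fringes follow `I(u) = lo + (hi - lo) * (1 + cos(2*pi*f*u/W +
#' delta)) / 2` with `u` the 0-based column index; horizontal fringes vary
#' along rows instead.
#'
#' @param spec A [PatternSpec-class] with `kind == "sinusoidal"`.
#' @return Intensity matrix (rows = height) with values in the spec's range.
#' @examples
#' p <- sinusoidalPattern(patternSpec("sinusoidal", 1, width = 4, height = 2))
#' p[1, ]  # 1.0 0.5 0.0 0.5
#' @export
sinusoidalPattern <- function(spec) {
  stopifnot(is(spec, "PatternSpec"))
  validObject(spec)
  if (spec@kind != "sinusoidal")
    stop("invalid spec: sinusoidalPattern requires kind 'sinusoidal'")
  lo <- spec@intensityRange[1]
  hi <- spec@intensityRange[2]
  patternFromProfile(spec, lo + (hi - lo) * (1 + cos(patternCosArg(spec))) / 2)
}

#' Render a binary fringe pattern
#'
#' The 50%-duty-cycle square wave: `hi` where `cos(2*pi*f*u/W + delta) >= 0`,
#' otherwise `lo` -- i.e. the sinusoid of the same spec thresholded at its
#' midpoint.
#'
#' @param spec A [PatternSpec-class] with `kind == "binary"`.
#' @return Intensity matrix containing only the two values `lo` and `hi`.
#' @export
binaryPattern <- function(spec) {
  stopifnot(is(spec, "PatternSpec"))
  validObject(spec)
  if (spec@kind != "binary")
    stop("invalid spec: binaryPattern requires kind 'binary'")
  lo <- spec@intensityRange[1]
  hi <- spec@intensityRange[2]
  patternFromProfile(spec, ifelse(cos(patternCosArg(spec)) >= 0, hi, lo))
}

#' Render any pattern spec
#'
#' Dispatches on `spec@kind` to [sinusoidalPattern()] or [binaryPattern()].
#'
#' @param spec A [PatternSpec-class].
#' @return Intensity matrix.
#' @export
renderPattern <- function(spec) {
  if (spec@kind == "sinusoidal") sinusoidalPattern(spec) else
    binaryPattern(spec)
}

#' Four-step phase-shift sequence at one frequency
#'
#' Returns the four pattern specs with phase shifts `0, pi/2, pi, 3*pi/2` (in
#' that order) used by the four-step phase retrieval.
#'
#' @param frequency Cycles across the pattern width; must be positive.
#' @param kind `"sinusoidal"` (default; phase retrieval assumes a cosine
#'   profile) or `"binary"`.
#' @param ... Further arguments passed to [patternSpec()].
#' @return List of four [PatternSpec-class] objects.
#' @export
phaseShiftSequence <- function(frequency, kind = "sinusoidal", ...) {
  if (!is.finite(frequency) || frequency <= 0)
    stop("phase-shift sequences need a positive frequency")
  lapply(c(0, pi / 2, pi, 3 * pi / 2), function(delta)
    patternSpec(kind, frequency = frequency, phaseShift = delta, ...))
}

#' Write a pattern as a grayscale PNG
#'
#' @param pattern Intensity matrix in `[0, 1]`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writePattern <- function(pattern, path) {
  png::writePNG(pattern, path)
  invisible(path)
}
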