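## Phred symbol conversions and the two published basecaller quality-score
## formulas (Chiron/Causalcall log-ratio score; Flappie/Nanonet scaled score
## with six built-in coefficient sets).

.SCALING_TABLE <- data.frame(
  model = c("flappie", "nanonet_template_high_p", "nanonet_template_low_p",
            "nanonet_complement", "nanonet_2d", "nanonet_another"),
  x = c(1.00000, 0.05524, 0.20938, 0.13120, 0.02657, 1.00000),
  y = c(1.00000, 0.70268, 1.00776, 0.88952, 0.65590, 1.00000),
  stringsAsFactors = FALSE)

#' Convert a quality symbol to its Phred value and error probability
#'
#' Sanger (Phred+33) convention: a symbol with ordinal \code{o} encodes
#' Phred score \code{Q = o - 33} and base error probability
#' \eqn{10^{-Q/10}}. '!' is Phred 0 (error probability 1); '?' is Phred 30
#' (error probability 1e-3).
#'
#' @param symbol character vector of single characters with ordinals in
#'   \[33,126\].
#' @return data.frame with columns \code{symbol}, \code{phred},
#'   \code{error_prob}.
#' @examples
#' phredFromSymbol(c("!", "?", "I"))
#' @export
phredFromSymbol <- function(symbol) {
  if (!is.character(symbol) || any(nchar(symbol) != 1L)) {
    stop("symbol must be single characters")
  }
  ords <- vapply(symbol, utf8ToInt, integer(1), USE.NAMES = FALSE)
  if (any(ords < 33L | ords > 126L)) {
    stop("symbol ordinal outside [33,126]: '",
         symbol[which(ords < 33L | ords > 126L)[1]], "'")
  }
  q <- ords - 33L
  data.frame(symbol = symbol, phred = q, error_prob = 10^(-q / 10),
             stringsAsFactors = FALSE)
}

#' Convert a Phred value to its quality symbol
#'
#' Inverse of [phredFromSymbol()]: Phred \code{Q} in \[0,93\] maps to the
#' character with ordinal \code{Q + 33}.
#'
#' @param phred integer vector in \[0,93\].
#' @return character vector of symbols.
#' @export
symbolFromPhred <- function(phred) {
  phred <- as.integer(phred)
  if (any(phred < 0L | phred > 93L)) stop("phred must lie in [0,93]")
  vapply(phred + 33L, intToUtf8, character(1))
}

#' Round and clamp a real quality score to an emittable Phred value
#'
#' Scores from the formulas are unrounded reals; basecallers must emit an
#' integer Phred symbol. This helper rounds half-up and clamps to \[0,93\]
#' (the printable Phred+33 range).
#'
#' @param score numeric vector of quality scores.
#' @return integer Phred values in \[0,93\].
#' @export
clampPhred <- function(score) {
  as.integer(pmin(93, pmax(0, floor(score + 0.5))))
}

#' Chiron/Causalcall quality score
#'
#' \eqn{qs = 10 \log_{10}(P_1 / P_2)} where \eqn{P_1} is the probability of
#' the most likely nucleotide and \eqn{P_2} that of the second most likely.
#' The score is 0 when the two are tied and grows with their ratio; it is
#' scale-free in (P1, P2).
#'
#' @param p1 probability of the most likely nucleotide, in (0,1\].
#' @param p2 probability of the second most likely nucleotide, in (0,1\],
#'   with \code{p2 <= p1}.
#' @return numeric quality score (>= 0).
#' @examples
#' chironQuality(0.9, 0.09)  # 10
#' @export
chironQuality <- function(p1, p2) {
  if (any(p2 <= 0)) stop("p2 must be > 0")
  if (any(p1 > 1) || any(p1 <= 0)) stop("p1 must lie in (0,1]")
  if (any(p2 > p1)) stop("p2 must not exceed p1")
  10 * log10(p1 / p2)
}

#' Flappie/Nanonet scaled quality score
#'
#' \eqn{qs = -10 (y \log_{10}(1-p) + \log_{10} x)} where \eqn{p} is the
#' probability of the most likely nucleotide and \eqn{(x, y)} are
#' model-specific scaling coefficients (see [scalingCoefficients()]). With
#' \code{x = y = 1} this is the standard Phred transform
#' \eqn{-10 \log_{10}(1-p)}.
#'
#' @param p probability of the most likely nucleotide, in (0,1).
#' @param coeffs a [ScalingCoefficients-class], e.g. from
#'   [scalingCoefficients()] or [selectNanonetCoefficients()].
#' @return numeric quality score.
#' @examples
#' scaledQuality(0.9, scalingCoefficients("flappie"))  # 10
#' @export
scaledQuality <- function(p, coeffs) {
  stopifnot(is(coeffs, "ScalingCoefficients"))
  if (any(p <= 0)) stop("p must be > 0")
  if (any(p >= 1)) stop("p must be < 1 (p = 1 gives an infinite score)")
  -10 * (coeffs@y * log10(1 - p) + log10(coeffs@x))
}

#' Built-in scaling-coefficient sets
#'
#' Returns the (x, y) pair for one of the six built-in quality-scaling
#' models: \code{flappie}, \code{nanonet_template_high_p} (template reads
#' with p > 0.1), \code{nanonet_template_low_p} (template, p <= 0.1),
#' \code{nanonet_complement}, \code{nanonet_2d} and \code{nanonet_another}.
#'
#' @param model one of the six model names above.
#' @return A [ScalingCoefficients-class].
#' @export
scalingCoefficients <- function(model = .SCALING_TABLE$model) {
  model <- match.arg(model)
  row <- .SCALING_TABLE[.SCALING_TABLE$model == model, ]
  new("ScalingCoefficients", modelName = model, x = row$x, y = row$y)
}

#' The full coefficient table
#'
#' @return data.frame with columns \code{model}, \code{x}, \code{y}.
#' @export
scalingCoefficientTable <- function() .SCALING_TABLE

#' Select the Nanonet coefficient set for a read kind and probability
#'
#' Nanonet's coefficients depend on the DNA read type and, for template
#' reads, on the probability of the most likely nucleotide: template reads
#' with p > 0.1 use one pair, template reads with p <= 0.1 another (the
#' boundary p = 0.1 falls in the "<= 0.1" set); complement, 2d and the
#' remaining ("another") category each have a single pair.
#'
#' @param read_kind one of \code{"template"}, \code{"complement"},
#'   \code{"2d"}, \code{"another"}.
#' @param p probability of the most likely nucleotide, in (0,1).
#' @return A [ScalingCoefficients-class].
#' @examples
#' selectNanonetCoefficients("template", 0.5)
#' @export
selectNanonetCoefficients <- function(read_kind, p) {
  if (!is.character(read_kind) || length(read_kind) != 1L ||
      !read_kind %in% c("template", "complement", "2d", "another")) {
    stop("read_kind must be one of 'template', 'complement', '2d', 'another'")
  }
  if (p <= 0 || p >= 1) stop("p must lie in (0,1)")
  model <- switch(read_kind,
    template = if (p > 0.1) "nanonet_template_high_p" else "nanonet_template_low_p",
    complement = "nanonet_complement",
    `2d` = "nanonet_2d",
    another = "nanonet_another")
  scalingCoefficients(model)
}
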