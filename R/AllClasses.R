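#' @import methods
#' @importFrom stats rnorm runif rbinom setNames sd
#' @importFrom utils write.table read.table head tail
NULL

#' ReadSet: a set of sequencing reads with optional per-base qualities
#'
#' A lightweight container for basecalled reads. Sequences are nucleotide
#' strings over \code{A,C,G,T,N} (case preserved); qualities, when present,
#' are Sanger-encoded (Phred+33) printable-ASCII strings of the same length
#' as their sequence. Quality-less read sets (FASTA-derived) carry
#' \code{NA_character_} qualities.
#'
#' @slot id character vector of read identifiers.
#' @slot sequence character vector of nucleotide strings.
#' @slot quality character vector of quality strings, or \code{NA} per read.
#'
#' @export
setClass("ReadSet",
  representation(id = "character", sequence = "character",
                 quality = "character"))

setValidity("ReadSet", function(object) {
  msgs <- character(0)
  n <- length(object@id)
  if (length(object@sequence) != n || length(object@quality) != n) {
    return("id, sequence and quality must have equal length")
  }
  has_q <- !is.na(object@quality)
  if (any(nchar(object@quality[has_q]) != nchar(object@sequence[has_q]))) {
    bad <- which(has_q & nchar(object@quality) != nchar(object@sequence))[1]
    msgs <- c(msgs, paste0("record ", bad, " ('", object@id[bad],
                           "'): quality length != sequence length"))
  }
  if (any(has_q)) {
    ords <- utf8ToInt(paste(object@quality[has_q], collapse = ""))
    if (length(ords) && (min(ords) < 33L || max(ords) > 126L)) {
      msgs <- c(msgs, "quality characters must have ordinals in [33,126]")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a ReadSet
#'
#' @param id character vector of read identifiers.
#' @param sequence character vector of nucleotide strings.
#' @param quality optional character vector of Phred+33 quality strings
#'   (\code{NA} entries allowed for quality-less reads).
#' @return A [ReadSet-class] object.
#' @examples
#' ReadSet("r1", "ACGT", "!!5I")
#' @export
ReadSet <- function(id, sequence, quality = NA_character_) {
  if (length(quality) == 1L && length(id) != 1L) {
    quality <- rep(quality, length(id))
  }
  new("ReadSet", id = as.character(id), sequence = as.character(sequence),
      quality = as.character(quality))
}

setMethod("show", "ReadSet", function(object) {
  nq <- sum(!is.na(object@quality))
  cat("ReadSet with", length(object@id), "reads (",
      nq, "with qualities );",
      format(sum(nchar(object@sequence)), big.mark = ","), "bp total\n")
})

#' @describeIn ReadSet-class number of reads
#' @param x,object a \code{ReadSet}.
#' @export
setMethod("length", "ReadSet", function(x) length(x@id))

#' @export
setMethod("[", "ReadSet", function(x, i, j, ..., drop = TRUE) {
  new("ReadSet", id = x@id[i], sequence = x@sequence[i],
      quality = x@quality[i])
})

#' Accessors for ReadSet slots
#' @param x a [ReadSet-class].
#' @return character vector.
#' @export
readIds <- function(x) x@id

#' @rdname readIds
#' @export
readSequences <- function(x) x@sequence

#' @rdname readIds
#' @export
readQualities <- function(x) x@quality

#' AlignmentSet: parsed SAM alignment records
#'
#' Column-oriented container for SAM body records. CIGAR strings are kept
#' verbatim; \code{seq}/\code{qual} are \code{NA} when the SAM field is
#' \code{*}; the MD tag is captured when present.
#'
#' @slot qname,rname,cigar,seq,qual,md character vectors.
#' @slot flag,pos integer vectors (SAM FLAG bitfield; 1-based POS).
#' @slot header character vector of verbatim header lines.
#' @export
setClass("AlignmentSet",
  representation(qname = "character", flag = "integer", rname = "character",
                 pos = "integer", cigar = "character", seq = "character",
                 qual = "character", md = "character", header = "character"))

setValidity("AlignmentSet", function(object) {
  n <- length(object@qname)
  lens <- c(length(object@flag), length(object@rname), length(object@pos),
            length(object@cigar), length(object@seq), length(object@qual),
            length(object@md))
  if (any(lens != n)) return("all record slots must have equal length")
  mapped <- !bitwAnd(object@flag, 4L)
  if (any(mapped & !is.na(object@pos) & object@pos < 1L)) {
    return("mapped records must have position >= 1")
  }
  TRUE
})

setMethod("show", "AlignmentSet", function(object) {
  mapped <- sum(!bitwAnd(object@flag, 4L))
  cat("AlignmentSet with", length(object@qname), "records (",
      mapped, "mapped )\n")
})

#' @describeIn AlignmentSet-class number of alignment records
#' @param x,object an \code{AlignmentSet}.
#' @export
setMethod("length", "AlignmentSet", function(x) length(x@qname))

#' Logical masks over SAM flag bits
#' @param x an [AlignmentSet-class].
#' @return logical vector, one element per record.
#' @export
isUnmapped <- function(x) bitwAnd(x@flag, 4L) != 0L

#' @rdname isUnmapped
#' @export
isReverseStrand <- function(x) bitwAnd(x@flag, 16L) != 0L

#' @rdname isUnmapped
#' @export
isSecondary <- function(x) bitwAnd(x@flag, 256L) != 0L

#' @rdname isUnmapped
#' @export
isSupplementary <- function(x) bitwAnd(x@flag, 2048L) != 0L

#' @rdname isUnmapped
#' @export
isPrimaryMapped <- function(x) {
  !isUnmapped(x) & !isSecondary(x) & !isSupplementary(x)
}

#' ScalingCoefficients: a basecaller quality-scaling model
#'
#' Holds an (x, y) pair for the scaled quality formula
#' \eqn{qs = -10 (y \log_{10}(1-p) + \log_{10} x)} together with the model
#' it belongs to. The six built-in pairs are available through
#' [scalingCoefficients()].
#'
#' @slot modelName character scalar.
#' @slot x,y positive numeric scalars.
#' @export
setClass("ScalingCoefficients",
  representation(modelName = "character", x = "numeric", y = "numeric"))

setValidity("ScalingCoefficients", function(object) {
  if (length(object@x) != 1L || length(object@y) != 1L ||
      object@x <= 0 || object@y <= 0) {
    return("x and y must be positive scalars")
  }
  TRUE
})

setMethod("show", "ScalingCoefficients", function(object) {
  cat(sprintf("ScalingCoefficients '%s': x = %.5f, y = %.5f\n",
              object@modelName, object@x, object@y))
})

#' StratifiedCounts: per-quality-symbol alignment outcome tallies
#'
#' The central result object: for every quality symbol seen in a read set,
#' counts of read bases classified as matched / mismatched / inserted /
#' clipped from primary alignments, the symbol's total base count in the
#' whole FASTQ, and its total in reads that have a primary alignment.
#' Deleted reference bases carry no read symbol and are tallied once at set
#' level in \code{deletionsTotal}.
#'
#' @slot counts integer matrix, one row per symbol (rownames are symbols),
#'   columns \code{matched, mismatched, inserted, clipped, total_in_fastq,
#'   total_in_mapped_reads}.
#' @slot deletionsTotal numeric scalar.
#' @export
setClass("StratifiedCounts",
  representation(counts = "matrix", deletionsTotal = "numeric"))

.STRAT_COLS <- c("matched", "mismatched", "inserted", "clipped",
                 "total_in_fastq", "total_in_mapped_reads")

setValidity("StratifiedCounts", function(object) {
  m <- object@counts
  if (!identical(colnames(m), .STRAT_COLS)) {
    return(paste("counts columns must be", paste(.STRAT_COLS, collapse = ", ")))
  }
  if (nrow(m) > 0) {
    out <- m[, "matched"] + m[, "mismatched"] + m[, "inserted"] + m[, "clipped"]
    if (any(out != m[, "total_in_mapped_reads"])) {
      return("matched+mismatched+inserted+clipped must equal total_in_mapped_reads")
    }
    if (any(m[, "total_in_fastq"] < m[, "total_in_mapped_reads"])) {
      return("total_in_fastq must be >= total_in_mapped_reads")
    }
  }
  TRUE
})

setMethod("show", "StratifiedCounts", function(object) {
  cat("StratifiedCounts over", nrow(object@counts), "quality symbols;",
      format(sum(object@counts[, "total_in_fastq"]), big.mark = ","),
      "bases in FASTQ;", object@deletionsTotal, "deleted reference bases\n")
})

#' Extract the per-symbol count table
#'
#' @param x a [StratifiedCounts-class].
#' @return integer matrix with symbols as rownames.
#' @export
strataCounts <- function(x) x@counts

#' @rdname strataCounts
#' @export
deletionsTotal <- function(x) x@deletionsTotal

#' MaskingReport: statistics of repeat-masking a reference
#'
#' @slot perSequence data.frame with columns \code{chrom, masked_bp,
#'   preexisting_n_bp, total_bp}.
#' @slot maskedBpTotal,totalBp numeric scalars.
#' @slot maskedPercent numeric, \code{100 * maskedBpTotal / totalBp} rounded
#'   half-up to two decimals.
#' @export
setClass("MaskingReport",
  representation(perSequence = "data.frame", maskedBpTotal = "numeric",
                 totalBp = "numeric", maskedPercent = "numeric"))

setValidity("MaskingReport", function(object) {
  if (object@maskedBpTotal < 0 || object@maskedBpTotal > object@totalBp) {
    return("masked bp must lie in [0, total bp]")
  }
  expect <- roundHalfUp(100 * object@maskedBpTotal / object@totalBp, 2L)
  if (object@totalBp > 0 && abs(object@maskedPercent - expect) > 1e-9) {
    return("maskedPercent must be recomputable from the two counts")
  }
  TRUE
})

setMethod("show", "MaskingReport", function(object) {
  cat(sprintf("MaskingReport: %s bp masked out of %s bp (%.2f%%)\n",
              format(object@maskedBpTotal, big.mark = ","),
              format(object@totalBp, big.mark = ","),
              object@maskedPercent))
})

#' @rdname maskingPercent
#' @export
maskedBp <- function(x) x@maskedBpTotal

#' Accessors for MaskingReport
#' @param x a [MaskingReport-class].
#' @return numeric scalar (or data.frame for \code{maskingPerSequence}).
#' @export
maskingPercent <- function(x) x@maskedPercent

#' @rdname maskingPercent
#' @export
maskingPerSequence <- function(x) x@perSequence

#' ErrorModel: symbol-conditioned read error model for simulation
#'
#' Describes how the simulator assigns quality symbols and errors. Each read
#' base draws its symbol from \code{symbolProfile}; conditional on a symbol
#' with Phred value Q, the base is substituted with probability
#' \eqn{f \cdot 10^{-Q/10}}, followed by an insertion with probability
#' \eqn{f \cdot insFraction \cdot 10^{-Q/10}}, and the next reference base is
#' deleted with probability \eqn{f \cdot delFraction \cdot 10^{-Q/10}}, where
#' \code{f} is \code{miscalibrationFactor} (1 = perfectly calibrated
#' qualities). Unalignable clip flanks of geometric length (mean
#' \code{clipFlankMean} per read end) are appended.
#'
#' @slot symbolProfile named numeric, symbol -> sampling probability
#'   (sums to 1).
#' @slot insFraction,delFraction numeric scalars in \[0,1\]: indel rates as
#'   fractions of the substitution rate.
#' @slot miscalibrationFactor positive numeric multiplier on all rates.
#' @slot clipFlankMean non-negative numeric, mean clip length per read end.
#' @export
setClass("ErrorModel",
  representation(symbolProfile = "numeric", insFraction = "numeric",
                 delFraction = "numeric", miscalibrationFactor = "numeric",
                 clipFlankMean = "numeric"))

setValidity("ErrorModel", function(object) {
  p <- object@symbolProfile
  if (is.null(names(p)) || any(nchar(names(p)) != 1L)) {
    return("symbolProfile must be named by single quality symbols")
  }
  ords <- utf8ToInt(paste(names(p), collapse = ""))
  if (any(ords < 33L | ords > 126L)) {
    return("symbolProfile symbols must have ordinals in [33,126]")
  }
  if (abs(sum(p) - 1) > 1e-9) return("symbolProfile must sum to 1")
  if (any(p < 0)) return("symbolProfile probabilities must be >= 0")
  rates <- errorRates(object)
  if (any(rates$sub + rates$ins + rates$del >= 1)) {
    return("per-symbol sub+ins+del must be < 1; reduce miscalibrationFactor")
  }
  if (object@miscalibrationFactor <= 0) {
    return("miscalibrationFactor must be positive")
  }
  if (object@clipFlankMean < 0) return("clipFlankMean must be >= 0")
  TRUE
})

setMethod("show", "ErrorModel", function(object) {
  qs <- utf8ToInt(paste(names(object@symbolProfile), collapse = "")) - 33L
  cat(sprintf(paste0("ErrorModel: %d symbols (Q %d..%d), ins/del fractions ",
                     "%.2f/%.2f, miscalibration x%.2f, clip mean %.1f\n"),
              length(object@symbolProfile), min(qs), max(qs),
              object@insFraction, object@delFraction,
              object@miscalibrationFactor, object@clipFlankMean))
})

#' VariantSet: the three quality-variant datasets
#'
#' Paths to the three files of the invariance experiment: the original FASTQ
#' (real quality symbols), the fake-quality FASTQ (every symbol replaced by a
#' constant, '?' by default), and the FASTA (qualities removed). All three
#' contain identical read ids and sequences in identical order.
#'
#' @slot fastqReal,fastqFake,fasta file paths.
#' @slot fakeSymbol the constant symbol used in the fake variant.
#' @export
setClass("VariantSet",
  representation(fastqReal = "character", fastqFake = "character",
                 fasta = "character", fakeSymbol = "character"))

setMethod("show", "VariantSet", function(object) {
  cat("VariantSet:\n  real FASTQ:", object@fastqReal,
      "\n  fake FASTQ:", object@fastqFake,
      sprintf("(symbol '%s')", object@fakeSymbol),
      "\n  FASTA:     ", object@fasta, "\n")
})

#' InvarianceReport: verdicts of the three-variant comparison
#'
#' @slot verdicts named character vector (\code{"identical"} or
#'   \code{"differs"}) for the pairs \code{real_vs_fake, real_vs_fasta,
#'   fake_vs_fasta}.
#' @slot detail named list of first-difference descriptions for pairs that
#'   differ.
#' @slot overallInvariant logical: \code{TRUE} iff all three pairs are
#'   identical.
#' @export
setClass("InvarianceReport",
  representation(verdicts = "character", detail = "list",
                 overallInvariant = "logical"))

setValidity("InvarianceReport", function(object) {
  ok <- all(object@verdicts == "identical")
  if (!identical(object@overallInvariant, ok)) {
    return("overallInvariant must be TRUE iff all pairwise verdicts are 'identical'")
  }
  TRUE
})

setMethod("show", "InvarianceReport", function(object) {
  cat("InvarianceReport:\n")
  for (p in names(object@verdicts)) {
    cat(sprintf("  %-14s %s\n", p, object@verdicts[[p]]))
  }
  cat("  overall invariant:", object@overallInvariant, "\n")
})

#' @rdname overallInvariant
#' @export
invarianceVerdicts <- function(x) x@verdicts

#' Accessors for InvarianceReport
#' @param x an [InvarianceReport-class].
#' @export
overallInvariant <- function(x) x@overallInvariant
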