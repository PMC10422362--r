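## Internal helpers shared across modules.

## round-half-up, not round-half-even: printed percentages follow the
## conventional half-up style (2.335 -> 2.34).
roundHalfUp <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

.COMPLEMENT_FROM <- "ACGTNacgtn"
.COMPLEMENT_TO <- "TGCANtgcan"

reverseComplement <- function(x) {
  stopifnot(is.character(x))
  vapply(x, function(s) {
    chartr(.COMPLEMENT_FROM, .COMPLEMENT_TO,
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

reverseString <- function(s) {
  paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
}

## CIGAR tokenising is delegated to GenomicAlignments; returns a two-column
## structure (op, len) or zero-row for "*".
parseCigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*" || !nzchar(cigar)) {
    return(list(op = character(0), len = integer(0)))
  }
  if (!grepl("^([0-9]+[MIDNSHP=X])+$", cigar)) {
    stop("CIGAR '", cigar, "' could not be parsed: unsupported operator")
  }
  tok <- tryCatch({
    list(op = GenomicAlignments::explodeCigarOps(cigar)[[1]],
         len = GenomicAlignments::explodeCigarOpLengths(cigar)[[1]])
  }, error = function(e) NULL)
  if (is.null(tok)) {
    stop("CIGAR '", cigar, "' could not be parsed: unsupported operator")
  }
  ops <- tok$op
  lens <- tok$len
  bad <- setdiff(ops, c("M", "=", "X", "I", "D", "S", "H", "N", "P"))
  if (length(bad) > 0) {
    stop("CIGAR '", cigar, "' contains unsupported operator(s): ",
         paste(bad, collapse = ", "))
  }
  list(op = ops, len = lens)
}

## Query (read) length implied by a CIGAR: ops that consume query bases,
## including hard clips so the full original read length is recovered.
cigarFullReadLength <- function(cigar) {
  cg <- parseCigar(cigar)
  sum(cg$len[cg$op %in% c("M", "=", "X", "I", "S", "H")])
}

cigarSeqLength <- function(cigar) {
  cg <- parseCigar(cigar)
  sum(cg$len[cg$op %in% c("M", "=", "X", "I", "S")])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
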