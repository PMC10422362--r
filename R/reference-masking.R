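## Repeat masking: substitute 'N' over BED intervals of a reference FASTA
## and report per-sequence and total masking statistics.

#' Merge repeat intervals into their union
#'
#' Sorts per chromosome and merges overlapping and adjacent intervals so
#' repeat annotations that overlap (common in RepeatMasker output) are not
#' double-counted. Delegates to \code{\link[GenomicRanges]{reduce}}.
#'
#' @param intervals a \code{GRanges} (e.g. from [readBed()]).
#' @return A \code{GRanges} covering exactly the union, sorted.
#' @export
mergeIntervals <- function(intervals) {
  stopifnot(is(intervals, "GRanges"))
  GenomicRanges::reduce(GenomicRanges::sort(intervals))
}

#' Mask repetitive reference regions with 'N'
#'
#' Replaces every base inside the (merged) intervals with uppercase 'N',
#' leaving all other bases — including their case — untouched. Sequence
#' lengths are preserved. Intervals extending past a sequence end are
#' clipped with a warning; intervals naming an unknown chromosome are an
#' error. The report counts the merged-union size per sequence, and
#' separately the bases that were already 'N' before masking.
#'
#' @param reference path to the reference FASTA.
#' @param intervals a \code{GRanges} of repeat intervals, or a BED3 path.
#' @param out path for the masked FASTA.
#' @return A list with elements \code{path} (the masked FASTA) and
#'   \code{report} (a [MaskingReport-class]).
#' @export
maskReference <- function(reference, intervals, out = tempfile(fileext = ".fasta")) {
  ref <- readFasta(reference)
  if (is.character(intervals)) intervals <- readBed(intervals)
  merged <- mergeIntervals(intervals)
  chroms <- as.character(GenomicRanges::seqnames(merged))
  unknown <- setdiff(unique(chroms), ref@id)
  if (length(unknown)) {
    stop("interval(s) reference unknown chromosome(s): ",
         paste(unknown, collapse = ", "))
  }
  seqs <- ref@sequence
  names(seqs) <- ref@id
  masked_bp <- setNames(numeric(length(ref@id)), ref@id)
  preexist_n <- setNames(numeric(length(ref@id)), ref@id)
  starts <- GenomicRanges::start(merged)
  ends <- GenomicRanges::end(merged)
  for (i in seq_along(merged)) {
    chrom <- chroms[i]
    len <- nchar(seqs[[chrom]])
    s <- starts[i]; e <- ends[i]
    if (s > len) next
    if (e > len) {
      warning("interval ", chrom, ":", s - 1, "-", e,
              " extends past sequence end (", len, " bp); clipped")
      e <- len
    }
    span <- substring(seqs[[chrom]], s, e)
    preexist_n[chrom] <- preexist_n[chrom] +
      sum(strsplit(span, "", fixed = TRUE)[[1]] %in% c("N", "n"))
    substring(seqs[[chrom]], s, e) <- strrep("N", e - s + 1L)
    masked_bp[chrom] <- masked_bp[chrom] + (e - s + 1L)
  }
  total_bp <- setNames(nchar(ref@sequence), ref@id)
  writeFasta(ReadSet(ref@id, unname(seqs)), out)
  report <- new("MaskingReport",
    perSequence = data.frame(chrom = ref@id,
                             masked_bp = unname(masked_bp),
                             preexisting_n_bp = unname(preexist_n),
                             total_bp = unname(total_bp),
                             stringsAsFactors = FALSE),
    maskedBpTotal = sum(masked_bp), totalBp = sum(total_bp),
    maskedPercent = roundHalfUp(100 * sum(masked_bp) / sum(total_bp), 2L))
  list(path = out, report = report)
}

#' Masking percentage from base counts
#'
#' The report arithmetic on its own: \code{100 * masked_bp / total_bp},
#' rounded half-up to two decimals (e.g. 89,222 bp masked out of
#' 3,814,719 bp gives 2.34).
#'
#' @param masked_bp,total_bp base counts.
#' @return numeric percentage with two decimals.
#' @examples
#' maskedPercentFromCounts(89222, 3814719)  # 2.34
#' @export
maskedPercentFromCounts <- function(masked_bp, total_bp) {
  stopifnot(masked_bp >= 0, total_bp > 0, masked_bp <= total_bp)
  roundHalfUp(100 * masked_bp / total_bp, 2L)
}

#' Write a MaskingReport as TSV
#'
#' @param report a [MaskingReport-class].
#' @param path output path.
#' @export
writeMaskingReport <- function(report, path) {
  stopifnot(is(report, "MaskingReport"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# qualstrat masking report: %d/%d bp masked (%.2f%%)",
                     as.integer(report@maskedBpTotal),
                     as.integer(report@totalBp), report@maskedPercent), con)
  write.table(report@perSequence, con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
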