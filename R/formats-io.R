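## Strict 4-line FASTQ, unwrapped FASTA and text SAM readers/writers.
## Parsers are deliberately strict: basecaller FASTQ is always 4-line, and
## byte-exact round trips (including lowercase soft-masked bases) are part of
## the contract, so records are validated and errors name the offending
## record.

.checkQualityOrdinals <- function(qual, where) {
  if (!nzchar(qual)) return(invisible(NULL))
  ords <- utf8ToInt(qual)
  if (min(ords) < 33L || max(ords) > 126L) {
    stop(where, ": quality character with ordinal outside [33,126]")
  }
  invisible(NULL)
}

#' Read a strict 4-line FASTQ file
#'
#' Parses Sanger (Phred+33) FASTQ with exactly four lines per record and no
#' line wrapping — the format every supported basecaller emits. Malformed
#' records (missing \code{@}/\code{+} sentinels, quality/sequence length
#' mismatch, out-of-range quality characters) raise errors naming the record
#' index.
#'
#' @param path path to a FASTQ file.
#' @return A [ReadSet-class] with qualities.
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "ACGT", "+", "!!5I"), fq)
#' readFastq(fq)
#' @export
readFastq <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  if (length(lines) == 0L) {
    return(ReadSet(character(0), character(0), character(0)))
  }
  if (length(lines) %% 4L != 0L) {
    stop("FASTQ '", path, "': line count ", length(lines),
         " is not a multiple of 4 (only strict 4-line FASTQ is supported)")
  }
  n <- length(lines) %/% 4L
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seqs <- lines[seq(2L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qual <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad)) stop("FASTQ record ", bad[1], ": header does not start with '@'")
  bad <- which(!startsWith(plus, "+"))
  if (length(bad)) stop("FASTQ record ", bad[1], ": separator line does not start with '+'")
  bad <- which(nchar(qual) != nchar(seqs))
  if (length(bad)) {
    stop("FASTQ record ", bad[1], ": quality length (", nchar(qual[bad[1]]),
         ") != sequence length (", nchar(seqs[bad[1]]), ")")
  }
  for (i in seq_len(n)) {
    .checkQualityOrdinals(qual[i], paste0("FASTQ record ", i))
  }
  ids <- sub("\\s.*$", "", substring(hdr, 2L))
  ## duplicate ids are disambiguated with a numeric suffix so downstream
  ## id-keyed joins stay well defined
  if (anyDuplicated(ids)) {
    dup <- duplicated(ids) | duplicated(ids, fromLast = TRUE)
    ids[dup] <- paste0(ids[dup], "/", stats::ave(seq_along(ids), ids,
                                                 FUN = seq_along)[dup])
    warning("FASTQ '", path, "' contains duplicate read ids; suffixed")
  }
  ReadSet(ids, seqs, qual)
}

#' Write a ReadSet as strict 4-line FASTQ
#'
#' @param records a [ReadSet-class]; every record must carry a quality
#'   string (use [stripToFasta()] for quality-less sets).
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeFastq <- function(records, path) {
  stopifnot(is(records, "ReadSet"))
  if (anyNA(records@quality)) {
    stop("record(s) without quality strings: write them with stripToFasta()")
  }
  out <- character(4L * length(records))
  if (length(records)) {
    out[seq(1L, by = 4L, length.out = length(records))] <- paste0("@", records@id)
    out[seq(2L, by = 4L, length.out = length(records))] <- records@sequence
    out[seq(3L, by = 4L, length.out = length(records))] <- "+"
    out[seq(4L, by = 4L, length.out = length(records))] <- records@quality
  }
  writeLines(out, path)
  invisible(path)
}

#' Replace every quality symbol with a constant
#'
#' Produces the "fake quality" variant of the invariance experiment: ids and
#' sequences are untouched, every quality string becomes the single
#' \code{symbol} repeated to the read length ('?' by default, Phred 30).
#'
#' @param records a [ReadSet-class].
#' @param symbol a single printable character (ordinal 33..126).
#' @return A [ReadSet-class].
#' @examples
#' fakeQuality(ReadSet("r1", "ACGT", "$$%%"))
#' @export
fakeQuality <- function(records, symbol = "?") {
  stopifnot(is(records, "ReadSet"))
  if (!is.character(symbol) || length(symbol) != 1L || nchar(symbol) != 1L) {
    stop("symbol must be a single character")
  }
  ord <- utf8ToInt(symbol)
  if (ord < 33L || ord > 126L) {
    stop("symbol ordinal ", ord, " outside printable range [33,126]")
  }
  new("ReadSet", id = records@id, sequence = records@sequence,
      quality = strrep(symbol, nchar(records@sequence)))
}

#' Write a ReadSet as unwrapped FASTA, discarding qualities
#'
#' The "no quality" variant: one header line and one sequence line per read,
#' identical sequence bytes, qualities dropped.
#'
#' @param records a [ReadSet-class] (qualities optional; ignored).
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
stripToFasta <- function(records, path) {
  stopifnot(is(records, "ReadSet"))
  out <- character(2L * length(records))
  if (length(records)) {
    out[seq(1L, by = 2L, length.out = length(records))] <- paste0(">", records@id)
    out[seq(2L, by = 2L, length.out = length(records))] <- records@sequence
  }
  writeLines(out, path)
  invisible(path)
}

#' Read FASTA into a quality-less ReadSet
#'
#' Accepts wrapped or unwrapped FASTA; case is preserved (soft-masked
#' references keep their lowercase bases).
#'
#' @param path path to a FASTA file.
#' @return A [ReadSet-class] with \code{NA} qualities.
#' @export
readFasta <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(ReadSet(character(0), character(0), character(0)))
  }
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1]) stop("FASTA '", path, "': first line is not a header")
  rec <- cumsum(is_hdr)
  ids <- sub("\\s.*$", "", substring(lines[is_hdr], 2L))
  seqs <- vapply(split(lines[!is_hdr], rec[!is_hdr]),
                 paste, character(1), collapse = "")
  ## headers with no sequence lines become empty sequences
  full <- setNames(character(length(ids)), as.character(seq_along(ids)))
  full[names(seqs)] <- seqs
  ReadSet(ids, unname(full), NA_character_)
}

#' Write a quality-less ReadSet as unwrapped FASTA
#'
#' @param records a [ReadSet-class].
#' @param path output path.
#' @export
writeFasta <- function(records, path) stripToFasta(records, path)

## --- SAM ---------------------------------------------------------------

#' Read a text SAM file
#'
#' Parses the tab-separated SAM body, keeping flags, CIGAR, SEQ, QUAL and
#' the MD tag. Header lines are preserved verbatim but not interpreted.
#' Records whose CIGAR-implied query length disagrees with SEQ raise a
#' validation error naming the read.
#'
#' @param path path to a SAM file (text, with or without header).
#' @return An [AlignmentSet-class].
#' @export
readSam <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "@")
  header <- lines[is_hdr]
  body <- lines[!is_hdr & nzchar(lines)]
  n <- length(body)
  qname <- character(n); flag <- integer(n); rname <- character(n)
  pos <- integer(n); cigar <- character(n); seqs <- character(n)
  qual <- character(n); md <- character(n)
  fields_list <- strsplit(body, "\t", fixed = TRUE)
  for (i in seq_len(n)) {
    f <- fields_list[[i]]
    if (length(f) < 11L) {
      stop("SAM record ", i, ": fewer than 11 mandatory fields")
    }
    qname[i] <- f[1]
    flag[i] <- as.integer(f[2])
    rname[i] <- f[3]
    pos[i] <- as.integer(f[4])
    cigar[i] <- f[6]
    seqs[i] <- if (f[10] == "*") NA_character_ else f[10]
    qual[i] <- if (f[11] == "*") NA_character_ else f[11]
    md[i] <- NA_character_
    if (length(f) > 11L) {
      tags <- f[12:length(f)]
      hit <- grep("^MD:Z:", tags, value = TRUE)
      if (length(hit)) md[i] <- substring(hit[1], 6L)
    }
    if (!is.na(seqs[i]) && cigar[i] != "*") {
      expect <- cigarSeqLength(cigar[i])  # errors on unknown operators
      if (expect != nchar(seqs[i])) {
        stop("SAM record for read '", qname[i], "': CIGAR query length ",
             expect, " != SEQ length ", nchar(seqs[i]))
      }
    } else if (cigar[i] != "*") {
      parseCigar(cigar[i])
    }
  }
  new("AlignmentSet", qname = qname, flag = flag, rname = rname, pos = pos,
      cigar = cigar, seq = seqs, qual = qual, md = md, header = header)
}

#' Write an AlignmentSet as text SAM
#'
#' @param aln an [AlignmentSet-class].
#' @param path output path.
#' @export
writeSam <- function(aln, path) {
  stopifnot(is(aln, "AlignmentSet"))
  body <- vapply(seq_len(length(aln)), function(i) {
    fields <- c(aln@qname[i], aln@flag[i], aln@rname[i], aln@pos[i], "60",
                aln@cigar[i], "*", "0", "0",
                ifelse(is.na(aln@seq[i]), "*", aln@seq[i]),
                ifelse(is.na(aln@qual[i]), "*", aln@qual[i]))
    if (!is.na(aln@md[i])) fields <- c(fields, paste0("MD:Z:", aln@md[i]))
    paste(fields, collapse = "\t")
  }, character(1))
  writeLines(c(aln@header, body), path)
  invisible(path)
}

#' Read BED3 repeat intervals into a GRanges
#'
#' BED coordinates are 0-based half-open; the returned
#' \code{\link[GenomicRanges]{GRanges}} follows the usual 1-based closed
#' convention.
#'
#' @param path path to a BED3(+) file.
#' @return A \code{GRanges}.
#' @export
readBed <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
  if (length(lines) == 0L) return(GenomicRanges::GRanges())
  f <- strsplit(lines, "\t", fixed = TRUE)
  chrom <- vapply(f, `[`, character(1), 1L)
  start0 <- as.numeric(vapply(f, `[`, character(1), 2L))
  end0 <- as.numeric(vapply(f, `[`, character(1), 3L))
  if (any(is.na(start0)) || any(is.na(end0)) || any(start0 < 0) ||
      any(start0 >= end0)) {
    stop("BED '", path, "': intervals must satisfy 0 <= start < end")
  }
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end0))
}
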