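## Shared fixture builders: everything is generated in code at test time.

## Write a FASTQ file from parallel vectors; returns the path.
writeToyFastq <- function(ids, seqs, quals, path = tempfile(fileext = ".fastq")) {
  writeFastq(ReadSet(ids, seqs, quals), path)
  path
}

## A SAM file with one @SQ header line and the given body records.
## Each record is a list(qname, flag, rname, pos, cigar, seq, qual, md).
writeToySam <- function(records, refname = "c", reflen = 1000L,
                        path = tempfile(fileext = ".sam")) {
  body <- vapply(records, function(r) {
    fields <- c(r$qname, r$flag, r$rname %||% refname, r$pos %||% 1L, 60L,
                r$cigar, "*", 0L, 0L, r$seq %||% "*", r$qual %||% "*")
    if (!is.null(r$md)) fields <- c(fields, paste0("MD:Z:", r$md))
    paste(fields, collapse = "\t")
  }, character(1))
  writeLines(c(paste0("@SQ\tSN:", refname, "\tLN:", reflen), body), path)
  path
}

## Random valid ReadSet for round-trip properties.
randomReadSet <- function(n, seed, min_len = 1L, max_len = 60L) {
  set.seed(seed)
  lens <- sample(min_len:max_len, n, replace = TRUE)
  seqs <- vapply(lens, function(L) {
    paste(sample(c("A", "C", "G", "T", "N"), L, replace = TRUE), collapse = "")
  }, character(1))
  quals <- vapply(lens, function(L) {
    intToUtf8(sample(33:126, L, replace = TRUE))
  }, character(1))
  ReadSet(sprintf("r%03d", seq_len(n)), seqs, quals)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
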