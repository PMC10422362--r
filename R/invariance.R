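## Three-variant invariance experiment: build real / fake-quality / FASTA
## variants of a read set, run a downstream command on each, and compare
## the outputs pairwise for identity. A downstream tool that never reads
## quality symbols must produce identical output for all three variants.

#' Build the three quality-variant datasets
#'
#' Writes (I) the original FASTQ with its real quality symbols, (II) a
#' FASTQ in which every quality symbol is replaced by a constant
#' (\code{'?'} by default), and (III) a FASTA with the quality lines
#' removed. All three contain identical read ids and sequences in
#' identical order; this invariant is re-validated from the written files
#' before returning.
#'
#' @param fastq path to the input FASTQ.
#' @param outdir directory for the three variant files.
#' @param symbol the constant fake-quality symbol.
#' @return A [VariantSet-class].
#' @export
makeVariants <- function(fastq, outdir = tempfile("variants"), symbol = "?") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  reads <- readFastq(fastq)
  stem <- sub("\\.(fastq|fq)(\\.gz)?$", "", basename(fastq))
  p_real <- file.path(outdir, paste0(stem, ".real.fastq"))
  p_fake <- file.path(outdir, paste0(stem, ".fake.fastq"))
  p_fasta <- file.path(outdir, paste0(stem, ".fasta"))
  writeFastq(reads, p_real)
  writeFastq(fakeQuality(reads, symbol), p_fake)
  stripToFasta(reads, p_fasta)

  r1 <- readFastq(p_real); r2 <- readFastq(p_fake); r3 <- readFasta(p_fasta)
  same <- function(a, b) identical(a@id, b@id) &&
    identical(a@sequence, b@sequence)
  if (!same(r1, r2) || !same(r1, r3)) {
    stop("internal error: variant files do not contain identical sequences")
  }
  new("VariantSet", fastqReal = p_real, fastqFake = p_fake, fasta = p_fasta,
      fakeSymbol = symbol)
}

## ---- comparators ------------------------------------------------------
## Each comparator normalises an output file to the record content that
## should be compared, dropping order-insensitive metadata (headers,
## timestamps).

.comparators <- list(
  bytes = function(path) readLines(path),
  fasta_records = function(path) {
    r <- readFasta(path)
    paste0(r@id, "\t", r@sequence)
  },
  vcf_records = function(path) {
    lines <- readLines(path)
    lines[!startsWith(lines, "##")]
  },
  sam_records = function(path) {
    lines <- readLines(path)
    lines[!startsWith(lines, "@PG") & !startsWith(lines, "@CO")]
  },
  tsv = function(path) {
    lines <- readLines(path)
    lines[!startsWith(lines, "#")]
  }
)

#' Available output comparators
#' @return character vector of comparator names.
#' @export
comparatorNames <- function() names(.comparators)

.firstDifference <- function(a, b) {
  if (length(a) != length(b)) {
    return(sprintf("record counts differ: %d vs %d", length(a), length(b)))
  }
  i <- which(a != b)[1]
  sprintf("first difference at record %d: '%s' vs '%s'",
          i, substr(a[i], 1, 60), substr(b[i], 1, 60))
}

.runDownstream <- function(command, input, workdir) {
  output <- tempfile("out", tmpdir = workdir)
  if (is.function(command)) {
    command(input, output)
  } else if (is.character(command) && length(command) == 1L) {
    cmd <- gsub("{input}", input, command, fixed = TRUE)
    cmd <- gsub("{output}", output, cmd, fixed = TRUE)
    res <- suppressWarnings(
      system2("sh", c("-c", shQuote(cmd)), stdout = TRUE, stderr = TRUE))
    status <- attr(res, "status") %||% 0L
    if (status != 0L) {
      stop("downstream command failed (exit ", status, ") on '", input,
           "':\n", paste(tail(res, 5), collapse = "\n"))
    }
    ## commands that write only to stdout: capture it as the output
    if (!file.exists(output)) writeLines(res, output)
  } else {
    stop("command must be a shell template string or an R function(input, output)")
  }
  if (!file.exists(output)) {
    stop("downstream command produced no output file for '", input, "'")
  }
  output
}

#' Run a downstream command on all three variants and compare outputs
#'
#' Executes \code{command} once per variant and applies the chosen
#' comparator pairwise. \code{command} is either a shell template
#' containing \code{{input}} (and optionally \code{{output}}; stdout is
#' captured when no output file is written) or an R
#' \code{function(input, output)}. Record-level comparators ignore
#' metadata lines (VCF \code{##} headers, SAM \code{@PG}/\code{@CO} lines,
#' \code{#} comments in TSV) but compare every record. Identity verdicts
#' are only meaningful for deterministic commands; pass any fixed-seed
#' flag the tool supports inside the template.
#'
#' @param variants a [VariantSet-class] from [makeVariants()].
#' @param command shell template or R function (see above).
#' @param comparator one of [comparatorNames()] (default record-level
#'   \code{"tsv"}).
#' @param workdir scratch directory for captured outputs.
#' @return An [InvarianceReport-class].
#' @examples
#' \donttest{
#' fq <- tempfile(fileext = ".fastq")
#' writeFastq(ReadSet(c("a", "b"), c("ACGT", "GGCC"), c("!!5I", "????")), fq)
#' v <- makeVariants(fq)
#' runAndCompare(v, toyReadLengthCommand())  # quality-agnostic: invariant
#' }
#' @export
runAndCompare <- function(variants, command, comparator = "tsv",
                          workdir = tempfile("invariance")) {
  stopifnot(is(variants, "VariantSet"))
  comparator <- match.arg(comparator, names(.comparators))
  dir.create(workdir, showWarnings = FALSE, recursive = TRUE)
  inputs <- c(real = variants@fastqReal, fake = variants@fastqFake,
              fasta = variants@fasta)
  outputs <- lapply(inputs, function(p) .runDownstream(command, p, workdir))
  norm <- lapply(outputs, .comparators[[comparator]])

  pairs <- list(real_vs_fake = c("real", "fake"),
                real_vs_fasta = c("real", "fasta"),
                fake_vs_fasta = c("fake", "fasta"))
  verdicts <- character(0)
  detail <- list()
  for (p in names(pairs)) {
    a <- norm[[pairs[[p]][1]]]; b <- norm[[pairs[[p]][2]]]
    if (identical(a, b)) {
      verdicts[p] <- "identical"
    } else {
      verdicts[p] <- "differs"
      detail[[p]] <- .firstDifference(a, b)
    }
  }
  new("InvarianceReport", verdicts = verdicts, detail = detail,
      overallInvariant = all(verdicts == "identical"))
}

## ---- built-in toy downstream commands ---------------------------------

#' Built-in toy downstream commands for the invariance experiment
#'
#' Two minimal "downstream tools" exercising both arms of the experiment:
#' \code{toyReadLengthCommand()} reports each read's id and sequence
#' length and never looks at quality lines, so it must be invariant across
#' the three variants; \code{toyQualitySumCommand()} reports the sum of
#' quality ordinals per read (0 for FASTA input), so it must differ
#' between variants. Both return an R \code{function(input, output)}
#' accepted by [runAndCompare()].
#'
#' @return a function of \code{(input, output)} writing a TSV.
#' @export
toyReadLengthCommand <- function() {
  function(input, output) {
    reads <- if (grepl("\\.(fa|fasta)$", input)) readFasta(input)
             else readFastq(input)
    write.table(data.frame(id = reads@id, len = nchar(reads@sequence)),
                output, sep = "\t", quote = FALSE, row.names = FALSE)
  }
}

#' @rdname toyReadLengthCommand
#' @export
toyQualitySumCommand <- function() {
  function(input, output) {
    reads <- if (grepl("\\.(fa|fasta)$", input)) readFasta(input)
             else readFastq(input)
    qsum <- vapply(reads@quality, function(q) {
      if (is.na(q) || !nzchar(q)) 0L else sum(utf8ToInt(q))
    }, integer(1), USE.NAMES = FALSE)
    write.table(data.frame(id = reads@id, qsum = qsum),
                output, sep = "\t", quote = FALSE, row.names = FALSE)
  }
}

#' Write an InvarianceReport as TSV
#'
#' @param report an [InvarianceReport-class].
#' @param path output path.
#' @export
writeInvarianceReport <- function(report, path) {
  stopifnot(is(report, "InvarianceReport"))
  df <- data.frame(pair = names(report@verdicts),
                   verdict = unname(report@verdicts),
                   detail = vapply(names(report@verdicts), function(p) {
                     report@detail[[p]] %||% ""
                   }, character(1)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# overall_invariant\t%s", report@overallInvariant), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
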