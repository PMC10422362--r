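## Orchestration of the full evaluation workflow:
## mask reference -> (external mapping or supplied/truth SAM) -> stratify
## -> distribution / per-symbol / summary reports.

#' Assemble and validate a pipeline configuration
#'
#' Exactly one of \code{sam} (a pre-computed alignment file) or
#' \code{mapperCmd} (a shell template with \code{{fastq}}, \code{{ref}} and
#' \code{{sam}} placeholders, e.g. a minimap2 invocation with the
#' \code{map-ont} preset) must be given.
#'
#' @param fastq path to the basecalled reads (FASTQ).
#' @param sam optional path to the SAM alignments.
#' @param mapperCmd optional shell template that produces the SAM.
#' @param reference optional reference FASTA (needed for masking, for
#'   mapping, and for resolving \code{M} CIGAR operators without MD tags).
#' @param bed optional BED3 file of repeat intervals to mask.
#' @param outPrefix prefix for output files.
#' @param logLevel one of \code{"debug"}, \code{"info"}, \code{"warning"},
#'   \code{"error"}.
#' @return a validated configuration (list).
#' @export
pipelineConfig <- function(fastq, sam = NULL, mapperCmd = NULL,
                           reference = NULL, bed = NULL,
                           outPrefix = "qualstrat", logLevel = "info") {
  logLevel <- match.arg(logLevel, c("debug", "info", "warning", "error"))
  if (is.null(sam) == is.null(mapperCmd)) {
    stop("exactly one of 'sam' or 'mapperCmd' must be set")
  }
  if (!file.exists(fastq)) stop("FASTQ not found: ", fastq)
  if (!is.null(sam) && !file.exists(sam)) stop("SAM not found: ", sam)
  if (!is.null(bed) && is.null(reference)) {
    stop("masking (bed) requires a reference FASTA")
  }
  for (p in c(reference, bed)) {
    if (!is.null(p) && !file.exists(p)) stop("input not found: ", p)
  }
  structure(list(fastq = fastq, sam = sam, mapperCmd = mapperCmd,
                 reference = reference, bed = bed, outPrefix = outPrefix,
                 logLevel = logLevel),
            class = "qualstrat_config")
}

.LOG_LEVELS <- c(debug = 1L, info = 2L, warning = 3L, error = 4L)

.plog <- function(config, level, ...) {
  if (.LOG_LEVELS[[level]] >= .LOG_LEVELS[[config$logLevel]]) {
    message(sprintf("[%s] %s", level, paste0(...)))
  }
}

.provenance <- function(config) {
  ## hash only the analytical inputs, not output naming or verbosity, so
  ## identical inputs give identical provenance lines
  keys <- c("fastq", "sam", "mapperCmd", "reference", "bed")
  cfg <- paste(vapply(config[keys], function(x) {
    paste(format(x %||% ""), collapse = ",")
  }, character(1)), collapse = "|")
  c(paste0("qualstrat ", as.character(utils::packageVersion("qualstrat"))),
    paste0("config_hash ", sum(utf8ToInt(cfg))))
}

#' Run the full evaluation pipeline
#'
#' Stages: (1) if \code{bed} is given, mask the reference and write a
#' masking report; (2) obtain alignments — either the supplied SAM or by
#' running \code{mapperCmd} against the (masked) reference; (3) compute
#' the quality-symbol distribution, the per-symbol stratified table and
#' the read-set summary, and write them as TSVs with a \code{#}
#' provenance header. Deterministic for fixed inputs: re-running yields
#' byte-identical TSVs.
#'
#' @param config a configuration from [pipelineConfig()].
#' @return list of output paths plus the in-memory results
#'   (\code{counts}, \code{summary}, \code{distribution}, and
#'   \code{masking} when masking ran).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "qualstrat_config"))
  out <- list()
  prov <- .provenance(config)
  reference <- config$reference

  if (!is.null(config$bed)) {
    .plog(config, "info", "stage mask: applying ", config$bed)
    masked_path <- paste0(config$outPrefix, ".masked.fasta")
    res <- maskReference(config$reference, config$bed, masked_path)
    reference <- res$path
    out$masked_reference <- res$path
    out$masking <- res$report
    out$masking_report <- paste0(config$outPrefix, ".masking.tsv")
    writeMaskingReport(res$report, out$masking_report)
    .plog(config, "info", sprintf("stage mask: %.2f%% masked",
                                  maskingPercent(res$report)))
  }

  sam_path <- config$sam
  if (is.null(sam_path)) {
    sam_path <- paste0(config$outPrefix, ".sam")
    cmd <- config$mapperCmd
    cmd <- gsub("{fastq}", config$fastq, cmd, fixed = TRUE)
    cmd <- gsub("{ref}", reference, cmd, fixed = TRUE)
    cmd <- gsub("{sam}", sam_path, cmd, fixed = TRUE)
    .plog(config, "info", "stage map: ", cmd)
    res <- suppressWarnings(
      system2("sh", c("-c", shQuote(cmd)), stdout = TRUE, stderr = TRUE))
    status <- attr(res, "status") %||% 0L
    if (status != 0L) {
      stop("stage map: external mapper failed (exit ", status, "):\n",
           paste(tail(res, 10), collapse = "\n"))
    }
  }

  .plog(config, "info", "stage stats: reading inputs")
  reads <- readFastq(config$fastq)
  sam <- readSam(sam_path)
  .plog(config, "info", sprintf("stage stats: %d reads, %d alignments",
                                length(reads), length(sam)))

  dist <- symbolDistribution(reads)
  counts <- stratify(sam, reads, ref = reference)
  summ <- summarizeReadSet(sam, reads, ref = reference)

  writeTsv <- function(df, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# ", prov), con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  out$distribution_tsv <- writeTsv(dist, paste0(config$outPrefix, ".dist.tsv"))
  out$stratified_tsv <- paste0(config$outPrefix, ".stratified.tsv")
  stratifiedTable(counts, out$stratified_tsv, provenance = prov)
  out$summary_tsv <- writeTsv(summ, paste0(config$outPrefix, ".summary.tsv"))

  out$counts <- counts
  out$summary <- summ
  out$distribution <- dist
  .plog(config, "info", "pipeline complete")
  out
}
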