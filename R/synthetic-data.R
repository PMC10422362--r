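## Quality-aware read simulator: draws per-base quality symbols from a
## profile, applies symbol-conditioned substitution/insertion/deletion
## errors and unalignable clip flanks, and emits ground-truth alignments
## that serve as the oracle for the stratified evaluation.

.BASES <- c("A", "C", "G", "T")

#' A unimodal quality-symbol sampling profile
#'
#' Discrete profile over Phred values \code{qmin..qmax} with a single peak,
#' shaped like the empirical per-symbol distributions of basecalled
#' nanopore read sets: a negative-binomial weight
#' \code{dnbinom(q - qmin, size, mu = peak - qmin)} renormalised to sum
#' to 1.
#'
#' @param qmin,qmax Phred range (defaults 5..30).
#' @param peak location of the mode (default Phred 12).
#' @param size negative-binomial shape (larger = tighter peak).
#' @return named numeric vector, names are quality symbols.
#' @export
defaultSymbolProfile <- function(qmin = 5L, qmax = 30L, peak = 12, size = 6) {
  stopifnot(qmin >= 0, qmax <= 93, qmin <= qmax, peak >= qmin)
  q <- qmin:qmax
  w <- stats::dnbinom(q - qmin, size = size, mu = peak - qmin)
  setNames(w / sum(w), symbolFromPhred(q))
}

#' Construct an ErrorModel
#'
#' @param symbolProfile named numeric vector of symbol sampling
#'   probabilities (sums to 1); default [defaultSymbolProfile()].
#' @param insFraction,delFraction insertion/deletion rates as fractions of
#'   each symbol's substitution rate \eqn{10^{-Q/10}}.
#' @param miscalibrationFactor positive multiplier applied to all rates;
#'   1 means the emitted symbols are perfectly calibrated.
#' @param clipFlankMean mean length (bases) of the unalignable flank
#'   appended to each read end (geometric; 0 disables clipping).
#' @return An [ErrorModel-class].
#' @examples
#' errorModel(miscalibrationFactor = 3, insFraction = 0, delFraction = 0)
#' @export
errorModel <- function(symbolProfile = defaultSymbolProfile(),
                       insFraction = 0.5, delFraction = 0.5,
                       miscalibrationFactor = 1, clipFlankMean = 0) {
  new("ErrorModel", symbolProfile = symbolProfile,
      insFraction = insFraction, delFraction = delFraction,
      miscalibrationFactor = miscalibrationFactor,
      clipFlankMean = clipFlankMean)
}

#' Per-symbol error rates of an ErrorModel
#'
#' @param model an [ErrorModel-class].
#' @return data.frame with columns \code{symbol}, \code{phred}, \code{sub},
#'   \code{ins}, \code{del}.
#' @export
errorRates <- function(model) {
  syms <- names(model@symbolProfile)
  q <- vapply(syms, utf8ToInt, integer(1)) - 33L
  base <- 10^(-q / 10) * model@miscalibrationFactor
  data.frame(symbol = syms, phred = q, sub = base,
             ins = model@insFraction * base, del = model@delFraction * base,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Simulate a random reference sequence
#'
#' @param length sequence length in bp (>= 1).
#' @param gc GC fraction in \[0,1\]; G and C (and A and T) are
#'   equiprobable within their pair.
#' @param seed integer seed; identical seeds give identical sequences.
#' @param id sequence name (default \code{"ref"}).
#' @return A single-record, quality-less [ReadSet-class].
#' @export
simulateReference <- function(length, gc = 0.5, seed = 1L, id = "ref") {
  if (length < 1) stop("length must be >= 1")
  if (gc < 0 || gc > 1) stop("gc must lie in [0,1]")
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  ReadSet(id, paste(sample(.BASES, length, replace = TRUE, prob = p[.BASES]),
                    collapse = ""))
}

## Vectorised error application along one reference segment (reference
## orientation). Returns read chars / symbols / outcomes plus the CIGAR op
## run over the aligned portion.
.applyErrors <- function(ref_chars, model, rates) {
  len <- length(ref_chars)
  syms <- sample(names(model@symbolProfile), len, replace = TRUE,
                 prob = model@symbolProfile)
  ri <- match(syms, rates$symbol)
  del <- runif(len) < rates$del[ri]
  sub <- runif(len) < rates$sub[ri]
  ins <- runif(len) < rates$ins[ri]

  emitted <- !del
  base_idx <- match(ref_chars, .BASES)
  base_idx[is.na(base_idx)] <- 1L     # non-ACGT reference bases
  out_base <- ref_chars
  do_sub <- emitted & sub
  if (any(do_sub)) {
    off <- sample(1:3, sum(do_sub), replace = TRUE)
    out_base[do_sub] <- .BASES[((base_idx[do_sub] - 1L + off) %% 4L) + 1L]
  }

  n_ins <- sum(ins)
  ins_base <- sample(.BASES, n_ins, replace = TRUE)
  ins_sym <- sample(names(model@symbolProfile), n_ins, replace = TRUE,
                    prob = model@symbolProfile)

  ## interleave: per reference position one of D/X/=, then I where drawn
  op1 <- ifelse(del, "D", ifelse(do_sub, "X", "="))
  ord <- order(c(seq_len(len), which(ins) + 0.5))
  ops <- c(op1, rep("I", n_ins))[ord]

  qord <- order(c(which(emitted), which(ins) + 0.5))
  read_chars <- c(out_base[emitted], ins_base)[qord]
  read_syms <- c(syms[emitted], ins_sym)[qord]
  outcome <- c(ifelse(do_sub[emitted], "mismatched", "matched"),
               rep("inserted", n_ins))[qord]
  list(read_chars = read_chars, read_syms = read_syms, outcome = outcome,
       ops = ops)
}

.cigarString <- function(ops) {
  r <- rle(ops)
  paste0(r$lengths, r$values, collapse = "")
}

#' Simulate quality-annotated reads with ground-truth alignments
#'
#' Draws reads from random positions and strands of \code{reference}. Each
#' emitted base receives a quality symbol from the model's profile and is
#' substituted / followed by an insertion / preceded by a reference-base
#' deletion according to the symbol's rates, so the emitted symbols are
#' calibrated (up to \code{miscalibrationFactor}) by construction.
#' Unalignable flanks of uniform random sequence and geometric length are
#' appended to both ends and labelled clipped. The returned truth
#' alignments record every base's outcome and an \code{=}/\code{X}-resolved
#' CIGAR, and are the oracle the stratified evaluation is tested against.
#'
#' @param reference a single-record [ReadSet-class] (e.g. from
#'   [simulateReference()]).
#' @param n number of reads.
#' @param readLength numeric \code{c(mean, sd)} of the aligned-portion
#'   target length (normal, truncated at 50 bp and the reference length).
#' @param model an [ErrorModel-class].
#' @param seed integer seed; the whole read set is reproducible from it.
#' @return list with \code{reads} (a [ReadSet-class]) and \code{truth} (a
#'   list of per-read truth records: \code{read_id}, \code{ref_start}
#'   0-based, \code{strand}, \code{outcome} character vector over read
#'   positions, \code{cigar} in reference orientation).
#' @export
simulateReads <- function(reference, n, readLength = c(1000, 200),
                          model = errorModel(), seed = 1L) {
  stopifnot(is(reference, "ReadSet"), length(reference) == 1L, n >= 0)
  validObject(model)
  set.seed(seed)
  reflen <- nchar(reference@sequence)
  rates <- errorRates(model)
  ref_chars_all <- strsplit(toupper(reference@sequence), "", fixed = TRUE)[[1]]
  pgeom_clip <- if (model@clipFlankMean > 0) 1 / (1 + model@clipFlankMean) else 1

  ids <- sprintf("read%05d", seq_len(n))
  seqs <- character(n); quals <- character(n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    repeat {
      tlen <- max(50L, min(reflen, round(rnorm(1, readLength[1], readLength[2]))))
      start <- sample.int(reflen - tlen + 1L, 1L)   # 1-based
      seg <- ref_chars_all[start:(start + tlen - 1L)]
      e <- .applyErrors(seg, model, rates)
      if (length(e$read_chars) > 0) break
    }
    strand <- if (runif(1) < 0.5) "+" else "-"
    lc <- if (model@clipFlankMean > 0) stats::rgeom(1, pgeom_clip) else 0L
    rc <- if (model@clipFlankMean > 0) stats::rgeom(1, pgeom_clip) else 0L
    flank <- function(k) {
      if (k == 0) return(list(b = character(0), s = character(0)))
      list(b = sample(.BASES, k, replace = TRUE),
           s = sample(names(model@symbolProfile), k, replace = TRUE,
                      prob = model@symbolProfile))
    }
    lf <- flank(lc); rf <- flank(rc)

    aligned_seq <- paste(e$read_chars, collapse = "")
    if (strand == "+") {
      read_seq <- paste0(paste(lf$b, collapse = ""), aligned_seq,
                         paste(rf$b, collapse = ""))
      read_sym <- c(lf$s, e$read_syms, rf$s)
      read_out <- c(rep("clipped", lc), e$outcome, rep("clipped", rc))
      cigar_ops <- c(rep("S", lc), e$ops, rep("S", rc))
    } else {
      ## basecaller orientation: the aligned portion appears reverse-
      ## complemented; the left flank of the read maps to the right end of
      ## the reference-orientation CIGAR
      read_seq <- paste0(paste(lf$b, collapse = ""),
                         reverseComplement(aligned_seq),
                         paste(rf$b, collapse = ""))
      read_sym <- c(lf$s, rev(e$read_syms), rf$s)
      read_out <- c(rep("clipped", lc), rev(e$outcome), rep("clipped", rc))
      cigar_ops <- c(rep("S", rc), e$ops, rep("S", lc))
    }
    seqs[i] <- read_seq
    quals[i] <- paste(read_sym, collapse = "")
    truth[[i]] <- list(read_id = ids[i], ref_start = start - 1L,
                       strand = strand, outcome = read_out,
                       cigar = .cigarString(cigar_ops))
  }
  list(reads = ReadSet(ids, seqs, quals), truth = truth)
}

#' Per-symbol outcome counts implied by simulator truth
#'
#' Tallies the simulator's own per-base outcome labels by quality symbol —
#' the exact quantity [stratify()] must reproduce from the emitted truth
#' SAM.
#'
#' @param truth the \code{truth} element of [simulateReads()].
#' @param reads the matching [ReadSet-class].
#' @return integer matrix, rows = symbols (sorted by ordinal), columns =
#'   \code{matched, mismatched, inserted, clipped}.
#' @export
truthOutcomeCounts <- function(truth, reads) {
  idx <- match(vapply(truth, `[[`, character(1), "read_id"), reads@id)
  sym_all <- unlist(strsplit(reads@quality[idx], "", fixed = TRUE),
                    use.names = FALSE)
  out_all <- unlist(lapply(truth, `[[`, "outcome"), use.names = FALSE)
  syms <- sort(unique(sym_all))
  m <- matrix(0L, length(syms), 4L, dimnames = list(syms, .OUTCOMES))
  tab <- table(sym_all, factor(out_all, levels = .OUTCOMES))
  m[rownames(tab), ] <- as.integer(tab)
  m
}

#' Write simulator truth as a SAM file
#'
#' Emits one primary record per read with \code{=}/\code{X}/\code{I}/
#' \code{D}/\code{S} CIGAR, 1-based POS, and SAM-convention orientation:
#' reverse-strand reads (flag 16) store SEQ reverse-complemented and QUAL
#' reversed. Round-tripping through [readSam()] and
#' [classifyAlignmentBases()] reproduces the truth outcomes exactly.
#'
#' @param truth,reads output of [simulateReads()].
#' @param reference the reference [ReadSet-class].
#' @param path output SAM path.
#' @return Invisibly, \code{path}.
#' @export
emitTruthSam <- function(truth, reads, reference, path) {
  stopifnot(is(reads, "ReadSet"), is(reference, "ReadSet"))
  idx <- match(vapply(truth, `[[`, character(1), "read_id"), reads@id)
  if (anyNA(idx)) stop("truth record(s) reference unknown read id(s)")
  header <- c("@HD\tVN:1.6\tSO:unknown",
              paste0("@SQ\tSN:", reference@id[1],
                     "\tLN:", nchar(reference@sequence[1])))
  n <- length(truth)
  lines <- character(n)
  for (j in seq_len(n)) {
    tr <- truth[[j]]
    rs <- reads@sequence[idx[j]]
    rq <- reads@quality[idx[j]]
    if (nchar(rs) != length(tr$outcome)) {
      stop("truth for read '", tr$read_id,
           "' is inconsistent with the read length")
    }
    if (tr$strand == "-") {
      rs <- reverseComplement(rs)
      if (!is.na(rq)) rq <- reverseString(rq)
    }
    flag <- if (tr$strand == "-") 16L else 0L
    lines[j] <- paste(tr$read_id, flag, reference@id[1], tr$ref_start + 1L,
                      60L, tr$cigar, "*", 0L, 0L, rs,
                      ifelse(is.na(rq), "*", rq), sep = "\t")
  }
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Write the truth outcome table as TSV
#'
#' @param truth,reads output of [simulateReads()].
#' @param path output path.
#' @export
writeTruthTsv <- function(truth, reads, path) {
  m <- truthOutcomeCounts(truth, reads)
  df <- data.frame(symbol = rownames(m), m, row.names = NULL,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
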