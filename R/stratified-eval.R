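## The central computation: walk each primary alignment's CIGAR against the
## read's per-base quality symbols and accumulate, per symbol, counts of
## matched / mismatched / inserted / clipped bases. Deleted reference bases
## carry no read symbol and are tallied at set level.

.OUTCOMES <- c("matched", "mismatched", "inserted", "clipped")

## Parse an MD tag into a logical vector over aligned columns (TRUE = the
## reference base matches), skipping deletion runs. Aligned columns are the
## query-consuming M/=/X columns in reference order.
.mdMatchVector <- function(md) {
  toks <- regmatches(md, gregexpr("[0-9]+|\\^[A-Za-z]+|[A-Za-z]", md))[[1]]
  out <- logical(0)
  for (tk in toks) {
    if (grepl("^[0-9]+$", tk)) {
      n <- as.integer(tk)
      if (n > 0) out <- c(out, rep(TRUE, n))
    } else if (startsWith(tk, "^")) {
      ## deletion: consumes reference only, no aligned query column
    } else {
      out <- c(out, FALSE)
    }
  }
  out
}

#' Classify every base of an aligned read by its alignment outcome
#'
#' Walks the CIGAR of one primary alignment and assigns each read base
#' exactly one of the four outcomes: \code{=} gives matched, \code{X}
#' mismatched, \code{I} inserted, \code{S}/\code{H} clipped. \code{M}
#' operators are resolved to matched/mismatched via the MD tag, or by
#' direct comparison against a reference when one is supplied; with neither
#' available an \code{M} operator is an error. Deletions consume no read
#' base and are reported separately (see [stratify()]).
#'
#' Hard-clipped bases are absent from the SAM SEQ and are recovered from
#' the original read. For reverse-strand alignments (flag 16) the SAM
#' stores SEQ/QUAL in reference orientation; positions are mapped back to
#' original read coordinates, so the returned table always covers read
#' positions \code{0 .. length(read)-1} with the read's own symbols.
#'
#' @param aln an [AlignmentSet-class].
#' @param original the matching [ReadSet-class] (the read is looked up by
#'   id), supplying the bases and qualities that hard clips remove from SAM.
#' @param which index of the alignment record to classify (default 1).
#' @param ref optional reference [ReadSet-class] (or FASTA path) for
#'   resolving \code{M} operators without an MD tag.
#' @return data.frame with one row per read base: \code{read_pos} (0-based
#'   position in the original read), \code{symbol} (quality symbol, \code{NA}
#'   for quality-less reads) and \code{outcome}.
#' @export
classifyAlignmentBases <- function(aln, original, which = 1L, ref = NULL) {
  stopifnot(is(aln, "AlignmentSet"), is(original, "ReadSet"))
  i <- which
  if (isUnmapped(aln)[i] || isSecondary(aln)[i] || isSupplementary(aln)[i]) {
    stop("record ", i, " ('", aln@qname[i],
         "') is not a primary mapped alignment")
  }
  ridx <- match(aln@qname[i], original@id)
  if (is.na(ridx)) {
    stop("read '", aln@qname[i], "' not found in the supplied read set")
  }
  read_seq <- original@sequence[ridx]
  read_qual <- original@quality[ridx]
  L <- nchar(read_seq)
  cg <- parseCigar(aln@cigar[i])
  if (cigarFullReadLength(aln@cigar[i]) != L) {
    stop("read '", aln@qname[i], "': CIGAR implies read length ",
         cigarFullReadLength(aln@cigar[i]), " but read has ", L, " bases")
  }
  reverse <- isReverseStrand(aln)[i]

  ## outcome per SAM-orientation query position (hard clips included)
  outcome <- character(L)
  qpos <- 0L
  m_query_cols <- integer(0)   # query positions (SAM orientation) under M
  aligned_is_m <- logical(0)   # per aligned column (M/=/X in order): is it M?
  for (k in seq_along(cg$op)) {
    op <- cg$op[k]; n <- cg$len[k]
    if (op %in% c("S", "H")) {
      outcome[qpos + seq_len(n)] <- "clipped"; qpos <- qpos + n
    } else if (op == "=") {
      outcome[qpos + seq_len(n)] <- "matched"
      aligned_is_m <- c(aligned_is_m, rep(FALSE, n)); qpos <- qpos + n
    } else if (op == "X") {
      outcome[qpos + seq_len(n)] <- "mismatched"
      aligned_is_m <- c(aligned_is_m, rep(FALSE, n)); qpos <- qpos + n
    } else if (op == "I") {
      outcome[qpos + seq_len(n)] <- "inserted"; qpos <- qpos + n
    } else if (op == "M") {
      m_query_cols <- c(m_query_cols, qpos + seq_len(n))
      aligned_is_m <- c(aligned_is_m, rep(TRUE, n)); qpos <- qpos + n
    }
    ## D, N, P: no query base consumed
  }

  if (length(m_query_cols)) {
    if (!is.na(aln@md[i])) {
      mv <- .mdMatchVector(aln@md[i])
      if (length(mv) != length(aligned_is_m)) {
        stop("read '", aln@qname[i], "': MD tag covers ", length(mv),
             " aligned columns but CIGAR has ", length(aligned_is_m))
      }
      m_match <- mv[aligned_is_m]
    } else if (!is.null(ref)) {
      if (is.character(ref)) ref <- readFasta(ref)
      m_match <- .refMatchForM(aln, i, cg, ref)
    } else {
      stop("read '", aln@qname[i], "': CIGAR contains 'M' but no MD tag ",
           "and no reference was supplied; match/mismatch is unresolvable")
    }
    outcome[m_query_cols] <- ifelse(m_match, "matched", "mismatched")
  }

  ## consistency: SAM SEQ (when present) must equal the original read in
  ## SAM orientation, minus hard-clipped ends
  if (!is.na(aln@seq[i])) {
    sam_oriented <- if (reverse) reverseComplement(read_seq) else read_seq
    lead_h <- if (length(cg$op) && cg$op[1] == "H") cg$len[1] else 0L
    expect_seq <- substring(sam_oriented, lead_h + 1L,
                            lead_h + nchar(aln@seq[i]))
    if (toupper(expect_seq) != toupper(aln@seq[i])) {
      stop("read '", aln@qname[i],
           "': SAM SEQ disagrees with the original read sequence")
    }
  }

  ## map SAM-orientation positions back to original read coordinates
  read_pos <- if (reverse) (L - 1L):0L else 0L:(L - 1L)
  symbols <- if (is.na(read_qual)) rep(NA_character_, L) else
    strsplit(read_qual, "", fixed = TRUE)[[1]]
  df <- data.frame(read_pos = read_pos,
                   symbol = symbols[read_pos + 1L],
                   outcome = outcome, stringsAsFactors = FALSE)
  df[order(df$read_pos), , drop = FALSE]
}

## Resolve M-operator columns by direct base comparison with the reference.
## Returns one logical per M query column (reference orientation order); a
## reference 'N' column counts as mismatched.
.refMatchForM <- function(aln, i, cg, ref) {
  cidx <- match(aln@rname[i], ref@id)
  if (is.na(cidx)) {
    stop("alignment reference '", aln@rname[i], "' not in supplied reference")
  }
  refseq <- toupper(ref@sequence[cidx])
  seq <- aln@seq[i]
  if (is.na(seq)) stop("cannot resolve 'M' without SAM SEQ or MD tag")
  seq <- toupper(seq)
  rpos <- aln@pos[i]   # 1-based reference cursor
  spos <- 1L           # 1-based SEQ cursor (soft clips included)
  out <- logical(0)
  for (k in seq_along(cg$op)) {
    op <- cg$op[k]; n <- cg$len[k]
    if (op == "M") {
      rb <- strsplit(substring(refseq, rpos, rpos + n - 1L), "", TRUE)[[1]]
      qb <- strsplit(substring(seq, spos, spos + n - 1L), "", TRUE)[[1]]
      out <- c(out, rb == qb & rb != "N")
      rpos <- rpos + n; spos <- spos + n
    } else if (op %in% c("=", "X")) {
      rpos <- rpos + n; spos <- spos + n
    } else if (op %in% c("I", "S")) {
      spos <- spos + n
    } else if (op %in% c("D", "N")) {
      rpos <- rpos + n
    }
  }
  out
}

#' Quality-symbol distribution of a read set
#'
#' The fraction of all nucleotides in the set carrying each quality symbol.
#' Symbols absent from the data are absent from the result.
#'
#' @param reads a [ReadSet-class]; every read must carry qualities.
#' @return data.frame with columns \code{symbol}, \code{phred},
#'   \code{count}, \code{fraction}, ordered by Phred value; attribute
#'   \code{n_total} holds the total base count.
#' @export
symbolDistribution <- function(reads) {
  stopifnot(is(reads, "ReadSet"))
  if (anyNA(reads@quality)) {
    stop("read(s) without quality strings; a symbol distribution needs qualities")
  }
  all_q <- paste(reads@quality, collapse = "")
  n <- nchar(all_q)
  if (n == 0L) {
    res <- data.frame(symbol = character(0), phred = integer(0),
                      count = integer(0), fraction = numeric(0))
    attr(res, "n_total") <- 0L
    return(res)
  }
  tab <- table(strsplit(all_q, "", fixed = TRUE)[[1]])
  syms <- names(tab)
  ords <- vapply(syms, utf8ToInt, integer(1))
  o <- order(ords)
  res <- data.frame(symbol = syms[o], phred = ords[o] - 33L,
                    count = as.integer(tab[o]),
                    fraction = as.integer(tab[o]) / n,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "n_total") <- n
  res
}

#' Stratify alignment outcomes by quality symbol
#'
#' Accumulates [classifyAlignmentBases()] over every primary mapped
#' alignment in \code{sam} and tallies, for each quality symbol, the
#' matched / mismatched / inserted / clipped base counts, the symbol's
#' total count across the whole FASTQ, and its total within reads that
#' have a primary alignment. Secondary and supplementary alignments are
#' excluded so no base is counted twice; reads with no (mapped) alignment
#' contribute to \code{total_in_fastq} only. Deletion operators add their
#' lengths to the set-level deletion tally.
#'
#' @param sam an [AlignmentSet-class] (or SAM path).
#' @param reads a [ReadSet-class] with qualities (or FASTQ path).
#' @param ref optional reference [ReadSet-class] or FASTA path for
#'   resolving \code{M} CIGAR operators without MD tags.
#' @return A [StratifiedCounts-class].
#' @export
stratify <- function(sam, reads, ref = NULL) {
  if (is.character(sam)) sam <- readSam(sam)
  if (is.character(reads)) reads <- readFastq(reads)
  if (is.character(ref)) ref <- readFasta(ref)
  stopifnot(is(sam, "AlignmentSet"), is(reads, "ReadSet"))
  missing_ids <- setdiff(unique(sam@qname), reads@id)
  if (length(missing_ids)) {
    stop("SAM read id(s) absent from the read set: ",
         paste(head(missing_ids, 10), collapse = ", "),
         if (length(missing_ids) > 10) ", ...")
  }
  if (anyNA(reads@quality)) {
    stop("stratification needs per-base qualities on every read")
  }

  symCount <- function(qualstrings) {
    if (!length(qualstrings)) return(integer(0))
    tab <- table(strsplit(paste(qualstrings, collapse = ""), "", TRUE)[[1]])
    setNames(as.integer(tab), names(tab))
  }
  total_fastq <- symCount(reads@quality)

  primary <- which(isPrimaryMapped(sam))
  if (anyDuplicated(sam@qname[primary])) {
    warning("read(s) with multiple primary alignments; keeping the first")
    primary <- primary[!duplicated(sam@qname[primary])]
  }
  acc <- list()   # symbol -> named numeric over outcomes
  addCounts <- function(acc, sym, out) {
    key <- paste0(sym, "\r", out)
    tab <- table(key)
    for (k in names(tab)) {
      acc[[k]] <- (acc[[k]] %||% 0L) + as.integer(tab[[k]])
    }
    acc
  }
  deletions <- 0
  mapped_read_ids <- character(0)
  for (i in primary) {
    df <- classifyAlignmentBases(sam, reads, which = i, ref = ref)
    acc <- addCounts(acc, df$symbol, df$outcome)
    cg <- parseCigar(sam@cigar[i])
    deletions <- deletions + sum(cg$len[cg$op == "D"])
    mapped_read_ids <- c(mapped_read_ids, sam@qname[i])
  }
  total_mapped <- symCount(reads@quality[match(mapped_read_ids, reads@id)])

  syms <- sort(unique(c(names(total_fastq), names(total_mapped))))
  m <- matrix(0L, nrow = length(syms), ncol = length(.STRAT_COLS),
              dimnames = list(syms, .STRAT_COLS))
  if (length(acc)) {
    keys <- strsplit(names(acc), "\r", fixed = TRUE)
    for (j in seq_along(acc)) {
      m[keys[[j]][1], keys[[j]][2]] <- acc[[j]]
    }
  }
  m[names(total_fastq), "total_in_fastq"] <- total_fastq
  if (length(total_mapped)) {
    m[names(total_mapped), "total_in_mapped_reads"] <- total_mapped
  }
  new("StratifiedCounts", counts = m, deletionsTotal = deletions)
}

#' Mapped fraction per quality symbol
#'
#' For each symbol, the quotient of the number of its bases that were
#' aligned to the reference (matched + mismatched + inserted) and the
#' number of all its bases in the read set. Soft- and hard-clipped bases
#' count as unmapped. Symbols with no bases in the FASTQ are omitted.
#'
#' @param counts a [StratifiedCounts-class].
#' @return named numeric vector in \[0,1\], names are symbols.
#' @export
mappedFraction <- function(counts) {
  stopifnot(is(counts, "StratifiedCounts"))
  m <- counts@counts
  keep <- m[, "total_in_fastq"] > 0
  mapped <- m[keep, "matched"] + m[keep, "mismatched"] + m[keep, "inserted"]
  setNames(mapped / m[keep, "total_in_fastq"], rownames(m)[keep])
}

#' Read-set alignment summary
#'
#' One-row summary of a read set against its alignments: read and base
#' counts, the percentage of all nucleotides that were mapped (aligned
#' query bases of primary alignments over all FASTQ bases), and the
#' match / substitution / deletion / insertion percentages over alignment
#' columns (matched + mismatched + inserted + deleted).
#'
#' @inheritParams stratify
#' @return data.frame with columns \code{n_reads}, \code{sum_bp},
#'   \code{mapped_pct}, \code{match_pct}, \code{sub_pct}, \code{del_pct},
#'   \code{ins_pct} (percentages rounded half-up to two decimals).
#' @export
summarizeReadSet <- function(sam, reads, ref = NULL) {
  if (is.character(reads)) reads <- readFastq(reads)
  counts <- stratify(sam, reads, ref)
  m <- counts@counts
  matched <- sum(m[, "matched"]); mism <- sum(m[, "mismatched"])
  ins <- sum(m[, "inserted"]); del <- counts@deletionsTotal
  total_bases <- sum(nchar(reads@sequence))
  aligned <- matched + mism + ins
  cols <- matched + mism + ins + del
  pct <- function(x, d) if (d > 0) roundHalfUp(100 * x / d, 2L) else 0
  data.frame(n_reads = length(reads), sum_bp = total_bases,
             mapped_pct = pct(aligned, total_bases),
             match_pct = pct(matched, cols), sub_pct = pct(mism, cols),
             del_pct = pct(del, cols), ins_pct = pct(ins, cols))
}

#' Write the per-symbol stratification table as TSV
#'
#' One row per quality symbol: outcome counts, the mapped fraction, the
#' empirical per-symbol error rate (mismatched over matched+mismatched)
#' and the theoretical Phred error rate \eqn{10^{-Q/10}}.
#'
#' @param counts a [StratifiedCounts-class].
#' @param path output path.
#' @param provenance optional character lines to embed as '#' comments.
#' @return the TSV as a data.frame, invisibly written to \code{path}.
#' @export
stratifiedTable <- function(counts, path = NULL, provenance = character(0)) {
  stopifnot(is(counts, "StratifiedCounts"))
  m <- counts@counts
  syms <- rownames(m)
  phred <- vapply(syms, utf8ToInt, integer(1)) - 33L
  aln_bases <- m[, "matched"] + m[, "mismatched"]
  df <- data.frame(
    symbol = syms, phred = phred,
    total_in_fastq = m[, "total_in_fastq"],
    matched = m[, "matched"], mismatched = m[, "mismatched"],
    inserted = m[, "inserted"], clipped = m[, "clipped"],
    mapped_fraction = ifelse(m[, "total_in_fastq"] > 0,
      (m[, "matched"] + m[, "mismatched"] + m[, "inserted"]) /
        pmax(m[, "total_in_fastq"], 1L), NA_real_),
    empirical_error_rate = ifelse(aln_bases > 0,
                                  m[, "mismatched"] / pmax(aln_bases, 1L),
                                  NA_real_),
    theoretical_error_rate = 10^(-phred / 10),
    stringsAsFactors = FALSE)
  rownames(df) <- NULL
  if (!is.null(path)) {
    con <- file(path, "w")
    on.exit(close(con))
    if (length(provenance)) writeLines(paste0("# ", provenance), con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  df
}
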