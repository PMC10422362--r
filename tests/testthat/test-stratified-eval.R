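test_that("the worked toy alignment classifies operator-for-operator", {
  read <- ReadSet("r1", "ACGTACGTACG", strrep("I", 11))
  sam <- writeToySam(list(list(qname = "r1", flag = 0L, pos = 11L,
                               cigar = "2S3=1X2=1I2=",
                               seq = "ACGTACGTACG", qual = strrep("I", 11))))
  df <- classifyAlignmentBases(readSam(sam), read)
  tab <- table(df$outcome)
  expect_equal(tab[["matched"]], 7)
  expect_equal(tab[["mismatched"]], 1)
  expect_equal(tab[["inserted"]], 1)
  expect_equal(tab[["clipped"]], 2)
  expect_equal(nrow(df), 11)
  expect_equal(df$read_pos, 0:10)
})

test_that("forward-strand positions carry their own symbols in order", {
  sam <- writeToySam(list(list(qname = "r1", flag = 0L, cigar = "4=",
                               seq = "ACGT", qual = "!#%5")))
  df <- classifyAlignmentBases(readSam(sam), ReadSet("r1", "ACGT", "!#%5"))
  expect_equal(df$symbol, c("!", "#", "%", "5"))
  expect_equal(df$outcome, rep("matched", 4))
})

test_that("M operators resolve via MD tag, or via reference, else error", {
  read <- ReadSet("r1", "ACGT", "!#%5")
  sam_md <- writeToySam(list(list(qname = "r1", flag = 0L, cigar = "4M",
                                  seq = "ACGT", qual = "!#%5", md = "2A1")))
  df <- classifyAlignmentBases(readSam(sam_md), read)
  expect_equal(df$outcome, c("matched", "matched", "mismatched", "matched"))

  sam_bare <- writeToySam(list(list(qname = "r1", flag = 0L, pos = 1L,
                                    cigar = "4M", seq = "ACGT",
                                    qual = "!#%5")))
  expect_error(classifyAlignmentBases(readSam(sam_bare), read),
               "unresolvable")
  ## reference resolution: reference AGGT -> mismatch at position 2 only
  ref <- ReadSet("c", "AGGTAAAA")
  df2 <- classifyAlignmentBases(readSam(sam_bare), read, ref = ref)
  expect_equal(df2$outcome, c("matched", "mismatched", "matched", "matched"))
  ## reference N column counts as mismatched
  refN <- ReadSet("c", "ANGTAAAA")
  df3 <- classifyAlignmentBases(readSam(sam_bare), read, ref = refN)
  expect_equal(df3$outcome[2], "mismatched")
})

test_that("MD deletions are skipped and column-count mismatches are caught", {
  ## 2M 2D 2M with MD "2^AC2": no mismatch among the 4 query columns
  sam <- writeToySam(list(list(qname = "r1", flag = 0L, cigar = "2M2D2M",
                               seq = "ACGT", qual = "!!!!", md = "2^AC2")))
  df <- classifyAlignmentBases(readSam(sam), ReadSet("r1", "ACGT", "!!!!"))
  expect_equal(df$outcome, rep("matched", 4))

  bad <- writeToySam(list(list(qname = "r1", flag = 0L, cigar = "4M",
                               seq = "ACGT", qual = "!!!!", md = "2A")))
  expect_error(classifyAlignmentBases(readSam(bad), ReadSet("r1", "ACGT", "!!!!")),
               "MD tag covers")
})

test_that("reverse-strand and hard-clipped bases map back to read coordinates", {
  ## original read GGAT with qualities "abcd"; aligned portion = revcomp
  sam <- writeToySam(list(list(qname = "r1", flag = 16L, cigar = "1H3=",
                               seq = "ATC", qual = "cba")))
  df <- classifyAlignmentBases(readSam(sam),
                               ReadSet("r1", "GATC", "abcd"))
  expect_equal(df$read_pos, 0:3)
  expect_equal(df$symbol, c("a", "b", "c", "d"))
  ## the hard-clipped SAM-leading base is the last read base (position 3)
  expect_equal(df$outcome, c("matched", "matched", "matched", "clipped"))
})

test_that("SEQ inconsistent with the original read raises a consistency error", {
  sam <- writeToySam(list(list(qname = "r1", flag = 0L, cigar = "4=",
                               seq = "AAAA", qual = "!!!!")))
  expect_error(classifyAlignmentBases(readSam(sam), ReadSet("r1", "ACGT", "!!!!")),
               "disagrees")
})

test_that("symbolDistribution computes per-symbol fractions", {
  reads <- ReadSet(c("a", "b"), c("AC", "G"), c("!5", "!"))
  d <- symbolDistribution(reads)
  expect_equal(d$symbol, c("!", "5"))
  expect_equal(d$fraction, c(2 / 3, 1 / 3))
  expect_equal(attr(d, "n_total"), 3)

  d1 <- symbolDistribution(ReadSet("a", "ACGT", "????"))
  expect_equal(d1$fraction, 1.0)
  expect_error(symbolDistribution(ReadSet("a", "ACGT")), "qualities")
  ## fractions always sum to 1
  rs <- randomReadSet(50, seed = 21)
  expect_equal(sum(symbolDistribution(rs)$fraction), 1, tolerance = 1e-9)
})

test_that("stratify accumulates primary alignments only and keeps denominators", {
  reads <- ReadSet(c("r1", "r2"), c("AAAA", "CCCC"), c("5555", "IIII"))
  sam <- writeToySam(list(
    list(qname = "r1", flag = 0L, cigar = "4=", seq = "AAAA", qual = "5555"),
    list(qname = "r1", flag = 256L, cigar = "4=", seq = "AAAA", qual = "5555"),
    list(qname = "r2", flag = 4L, cigar = "*")))
  counts <- stratify(sam, reads)
  m <- strataCounts(counts)
  expect_equal(m["5", "matched"], 4L)
  expect_equal(m["5", "total_in_mapped_reads"], 4L)
  expect_equal(m["5", "total_in_fastq"], 4L)
  ## unmapped-only read contributes to the FASTQ denominator only
  expect_equal(m["I", "total_in_fastq"], 4L)
  expect_equal(m["I", "total_in_mapped_reads"], 0L)
  expect_equal(sum(m[, c("matched", "mismatched", "inserted", "clipped")]), 4)

  ## SAM ids missing from the FASTQ are an error, not a skip
  sam2 <- writeToySam(list(list(qname = "ghost", flag = 0L, cigar = "4=",
                                seq = "AAAA", qual = "!!!!")))
  expect_error(stratify(sam2, reads), "absent.*ghost")
})

test_that("deletions tally at set level and carry no symbol", {
  reads <- ReadSet("r1", "AAAA", "5555")
  sam <- writeToySam(list(list(qname = "r1", flag = 0L, cigar = "2=3D2=",
                               seq = "AAAA", qual = "5555")))
  counts <- stratify(sam, reads)
  expect_equal(deletionsTotal(counts), 3)
  expect_equal(sum(strataCounts(counts)[, "matched"]), 4)
})

test_that("mappedFraction is the aligned share of each symbol's FASTQ bases", {
  reads <- ReadSet(c("r1", "r2"), c("AAAA", "CCCC"), c("5555", "IIII"))
  sam <- writeToySam(list(
    list(qname = "r1", flag = 0L, cigar = "2S2=", seq = "AAAA", qual = "5555"),
    list(qname = "r2", flag = 4L, cigar = "*")))
  mf <- mappedFraction(stratify(sam, reads))
  expect_equal(mf[["5"]], 0.5)   # half clipped, half matched
  expect_equal(mf[["I"]], 0.0)   # in FASTQ, never aligned
  expect_true(all(mf >= 0 & mf <= 1))
})

test_that("summarizeReadSet uses the alignment-column denominator", {
  read <- ReadSet("r1", "ACGTACGTACG", strrep("I", 11))
  sam <- writeToySam(list(list(qname = "r1", flag = 0L, pos = 11L,
                               cigar = "2S3=1X2=1I2=",
                               seq = "ACGTACGTACG", qual = strrep("I", 11))))
  s <- summarizeReadSet(sam, read)
  expect_equal(s$mapped_pct, 81.82)
  expect_equal(s$match_pct, 77.78)
  expect_equal(s$sub_pct, 11.11)
  expect_equal(s$ins_pct, 11.11)
  expect_equal(s$del_pct, 0)
  expect_equal(s$n_reads, 1)
  expect_equal(s$sum_bp, 11)

  ## error-free set
  sam0 <- writeToySam(list(list(qname = "r1", flag = 0L, cigar = "11=",
                                seq = "ACGTACGTACG", qual = strrep("I", 11))))
  s0 <- summarizeReadSet(sam0, read)
  expect_equal(s0$mapped_pct, 100)
  expect_equal(s0$match_pct, 100)
  expect_equal(s0$sub_pct + s0$del_pct + s0$ins_pct, 0)
})

test_that("stratifiedTable exposes empirical vs theoretical error rates", {
  reads <- ReadSet("r1", paste(rep("A", 10), collapse = ""), strrep("+", 10))
  sam <- writeToySam(list(list(qname = "r1", flag = 0L, cigar = "9=1X",
                               seq = readSequences(reads), qual = strrep("+", 10))))
  tab <- stratifiedTable(stratify(sam, reads))
  expect_equal(tab$phred, 10)
  expect_equal(tab$empirical_error_rate, 0.1)
  expect_equal(tab$theoretical_error_rate, 0.1)
  expect_equal(tab$mapped_fraction, 1)
})
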