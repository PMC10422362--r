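test_that("strict 4-line FASTQ parses and malformed records are rejected", {
  fq <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "!!5I"), fq)
  reads <- readFastq(fq)
  expect_equal(readIds(reads), "r1")
  expect_equal(readSequences(reads), "ACGT")
  expect_equal(readQualities(reads), "!!5I")

  writeLines(character(0), fq)
  expect_length(readFastq(fq), 0)

  writeLines(c("@r1", "ACGT", "+", "!!5"), fq)
  expect_error(readFastq(fq), "record 1.*quality length")

  writeLines(c("r1", "ACGT", "+", "!!5I"), fq)
  expect_error(readFastq(fq), "does not start with '@'")

  writeLines(c("@r1", "ACGT", "x", "!!5I"), fq)
  expect_error(readFastq(fq), "separator")

  writeLines(c("@r1", "ACGT", "+", "!!5I", "@r2", "AC"), fq)
  expect_error(readFastq(fq), "multiple of 4")
})

test_that("FASTQ round-trip is byte-identical on id, sequence and quality", {
  reads <- randomReadSet(100, seed = 11)
  fq <- tempfile(fileext = ".fastq")
  writeFastq(reads, fq)
  back <- readFastq(fq)
  expect_identical(readIds(back), readIds(reads))
  expect_identical(readSequences(back), readSequences(reads))
  expect_identical(readQualities(back), readQualities(reads))
})

test_that("writeFastq refuses quality-less records", {
  expect_error(writeFastq(ReadSet("r1", "ACGT"), tempfile()),
               "stripToFasta")
})

test_that("fakeQuality replaces symbols, preserves everything else, idempotent", {
  reads <- ReadSet(c("a", "b"), c("ACGT", "GGGCCCA"), c("$$%%", "abcdefg"))
  fake <- fakeQuality(reads)
  expect_identical(readSequences(fake), readSequences(reads))
  expect_identical(readIds(fake), readIds(reads))
  expect_equal(readQualities(fake), c("????", "???????"))
  expect_identical(fakeQuality(fake), fake)       # idempotent
  expect_length(fakeQuality(reads[integer(0)]), 0)
  expect_error(fakeQuality(reads, " "), "printable")
  expect_error(fakeQuality(reads, "xy"), "single character")

  other <- fakeQuality(reads, "I")
  expect_equal(readQualities(other), c("IIII", "IIIIIII"))
})

test_that("stripToFasta drops qualities, keeps sequences byte-identical", {
  reads <- randomReadSet(20, seed = 3)
  fa <- tempfile(fileext = ".fasta")
  stripToFasta(reads, fa)
  back <- readFasta(fa)
  expect_identical(readIds(back), readIds(reads))
  expect_identical(readSequences(back), readSequences(reads))
  expect_true(all(is.na(readQualities(back))))
  ## quality-less input accepted
  expect_silent(stripToFasta(ReadSet("x", "ACgt"), fa))
  expect_equal(readLines(fa), c(">x", "ACgt"))
})

test_that("readFasta accepts wrapped input and preserves case", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">s1 description", "ACgt", "NNaa", ">s2", "GG"), fa)
  r <- readFasta(fa)
  expect_equal(readIds(r), c("s1", "s2"))
  expect_equal(readSequences(r), c("ACgtNNaa", "GG"))
})

test_that("SAM parsing keeps flags, CIGAR, MD and validates lengths", {
  sam <- writeToySam(list(
    list(qname = "r1", flag = 0L, pos = 5L, cigar = "3=1X2=",
         seq = "ACGTAC", qual = "!!!!!!", md = "3A2"),
    list(qname = "r2", flag = 4L, cigar = "*")))
  aln <- readSam(sam)
  expect_length(aln, 2)
  expect_false(isUnmapped(aln)[1])
  expect_true(isUnmapped(aln)[2])
  expect_equal(aln@cigar[1], "3=1X2=")
  expect_equal(aln@md[1], "3A2")
  expect_true(is.na(aln@seq[2]))

  bad <- writeToySam(list(list(qname = "r1", flag = 0L, cigar = "5=",
                               seq = "ACGT", qual = "!!!!")))
  expect_error(readSam(bad), "CIGAR query length 5 != SEQ length 4")

  bad2 <- writeToySam(list(list(qname = "r1", flag = 0L, cigar = "4Z",
                                seq = "ACGT", qual = "!!!!")))
  expect_error(readSam(bad2), "unsupported operator")
})

test_that("BED3 reads as GRanges with 1-based coordinates", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("c1\t0\t10", "c2\t5\t7"), bed)
  gr <- readBed(bed)
  expect_equal(as.character(GenomicRanges::seqnames(gr)), c("c1", "c2"))
  expect_equal(GenomicRanges::start(gr), c(1L, 6L))
  expect_equal(GenomicRanges::end(gr), c(10L, 7L))
  writeLines("c1\t5\t5", bed)
  expect_error(readBed(bed), "start < end")
})
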