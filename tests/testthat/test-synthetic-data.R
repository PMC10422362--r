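test_that("simulateReference is seed-deterministic with the stated composition", {
  a <- simulateReference(1000, 0.5, seed = 7)
  b <- simulateReference(1000, 0.5, seed = 7)
  expect_identical(readSequences(a), readSequences(b))

  gc_only <- simulateReference(500, 1.0, seed = 3)
  expect_true(grepl("^[GC]+$", readSequences(gc_only)))
  at_only <- simulateReference(500, 0.0, seed = 3)
  expect_true(grepl("^[AT]+$", readSequences(at_only)))

  ## binomial bound on GC at 100 kb: 3 sigma ~ 0.0047
  big <- simulateReference(1e5, 0.5, seed = 11)
  chars <- strsplit(readSequences(big), "")[[1]]
  gc <- mean(chars %in% c("G", "C"))
  expect_lt(abs(gc - 0.5), 3 * sqrt(0.25 / 1e5))
  expect_error(simulateReference(0), "length")
  expect_error(simulateReference(10, gc = 1.5), "gc")
})

test_that("error-free simulation returns exact reference substrings, all matched", {
  ref <- simulateReference(5000, seed = 1)
  model <- errorModel(symbolProfile = c("I" = 1), miscalibrationFactor = 1e-12,
                      clipFlankMean = 0)
  sim <- simulateReads(ref, 20, readLength = c(300, 50), model = model,
                       seed = 2)
  expect_length(sim$reads, 20)
  for (tr in sim$truth) {
    expect_true(all(tr$outcome == "matched"))
    idx <- match(tr$read_id, readIds(sim$reads))
    seg <- substr(readSequences(ref), tr$ref_start + 1,
                  tr$ref_start + nchar(readSequences(sim$reads)[idx]))
    expected <- if (tr$strand == "+") seg else
      qualstrat:::reverseComplement(seg)
    expect_identical(readSequences(sim$reads)[idx], expected)
  }
})

test_that("simulated reads are byte-identical under a fixed seed", {
  ref <- simulateReference(10000, seed = 5)
  model <- errorModel(clipFlankMean = 10)
  s1 <- simulateReads(ref, 50, readLength = c(400, 80), model = model, seed = 9)
  s2 <- simulateReads(ref, 50, readLength = c(400, 80), model = model, seed = 9)
  f1 <- tempfile(); f2 <- tempfile()
  writeFastq(s1$reads, f1); writeFastq(s2$reads, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("generator truth mismatch fraction honours the symbol's Phred rate", {
  ## single symbol 'I' (Q=40) would need 10^7 bases for a tight bound;
  ## use '+' (Q=10, rate 0.1) at 10^5 bases: 3 sigma ~ 0.0028
  ref <- simulateReference(150000, seed = 13)
  model <- errorModel(symbolProfile = c("+" = 1), insFraction = 0,
                      delFraction = 0, clipFlankMean = 0)
  sim <- simulateReads(ref, 100, readLength = c(1000, 1), model = model,
                       seed = 17)
  outs <- unlist(lapply(sim$truth, `[[`, "outcome"))
  frac <- mean(outs == "mismatched")
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / length(outs)))
})

test_that("emitted FASTQ symbol distribution matches the sampling profile", {
  ref <- simulateReference(50000, seed = 23)
  profile <- defaultSymbolProfile()
  model <- errorModel(symbolProfile = profile, insFraction = 0,
                      delFraction = 0, clipFlankMean = 0)
  sim <- simulateReads(ref, 100, readLength = c(500, 50), model = model,
                       seed = 29)
  d <- symbolDistribution(sim$reads)
  n <- attr(d, "n_total")
  obs <- setNames(d$fraction, d$symbol)
  for (s in names(profile)) {
    if (profile[[s]] < 1e-4) next
    sig <- sqrt(profile[[s]] * (1 - profile[[s]]) / n)
    expect_lt(abs((obs[s] %||% 0) - profile[[s]]), 4 * sig + 1e-12)
  }
})

test_that("emitTruthSam round-trips through readSam and classifyAlignmentBases", {
  ref <- simulateReference(20000, seed = 31)
  model <- errorModel(clipFlankMean = 15)
  sim <- simulateReads(ref, 30, readLength = c(500, 100), model = model,
                       seed = 37)
  samp <- tempfile(fileext = ".sam")
  emitTruthSam(sim$truth, sim$reads, ref, samp)
  aln <- readSam(samp)
  expect_equal(length(aln), 30)
  for (j in seq_len(length(aln))) {
    tr <- sim$truth[[match(aln@qname[j], vapply(sim$truth, `[[`,
                                                character(1), "read_id"))]]
    df <- classifyAlignmentBases(aln, sim$reads, which = j)
    expect_identical(df$outcome, tr$outcome)
    expect_equal((aln@flag[j] %/% 16L) %% 2L == 1L, tr$strand == "-")
    expect_equal(aln@pos[j], tr$ref_start + 1L)
  }
})

test_that("error-free single read emits the expected CIGAR and coordinates", {
  ref <- ReadSet("ref", strrep("ACGT", 25))
  model <- errorModel(symbolProfile = c("I" = 1), miscalibrationFactor = 1e-12,
                      clipFlankMean = 0)
  sim <- simulateReads(ref, 1, readLength = c(60, 0), model = model, seed = 3)
  expect_match(sim$truth[[1]]$cigar, "^60=$")
  samp <- tempfile(fileext = ".sam")
  emitTruthSam(sim$truth, sim$reads, ref, samp)
  aln <- readSam(samp)
  expect_equal(aln@pos[1], sim$truth[[1]]$ref_start + 1L)
})

test_that("truth inconsistent with reads is rejected", {
  ref <- simulateReference(2000, seed = 1)
  sim <- simulateReads(ref, 2, readLength = c(100, 10),
                       model = errorModel(), seed = 2)
  broken <- sim$truth
  broken[[1]]$outcome <- broken[[1]]$outcome[-1]
  expect_error(emitTruthSam(broken, sim$reads, ref, tempfile()),
               "inconsistent")
  broken2 <- sim$truth
  broken2[[2]]$read_id <- "ghost"
  expect_error(emitTruthSam(broken2, sim$reads, ref, tempfile()),
               "unknown read id")
})

test_that("invalid error models are rejected", {
  expect_error(errorModel(symbolProfile = c("!" = 1)), "< 1")
  expect_error(errorModel(symbolProfile = c("I" = 0.5, "5" = 0.4)), "sum to 1")
  expect_error(errorModel(miscalibrationFactor = 0), "positive|< 1")
  expect_error(errorModel(clipFlankMean = -1), ">= 0")
})
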