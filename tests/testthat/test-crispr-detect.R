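test_that("a random contig with no recurring seeds yields no arrays", {
  set.seed(3)
  bg <- randomDna(10000, 0.5)
  expect_length(findArrays(bg), 0)

  # brute-force corroboration: count seed k-mers recurring at a spacing
  # compatible with an array (the precondition for any detection)
  k <- 8
  starts <- seq_len(nchar(bg) - k + 1)
  kmers <- substring(bg, starts, starts + k - 1)
  pos <- split(starts, kmers)
  pos <- pos[lengths(pos) >= 3]  # need >= minRepeats seeds
  valid <- vapply(pos, function(p) {
    d <- diff(sort(p))
    sum(d >= 19 + 19 & d <= 38 + 48) >= 2
  }, logical(1))
  expect_false(any(valid))
})

test_that("a planted 7x36 array with 30-nt spacers is found exactly once, exactly", {
  fx <- plantArrayContig(seed = 7)
  arrays <- findArrays(fx$seq)
  expect_length(arrays, 1)
  a <- arrays[[1]]
  expect_equal(nRepeats(a), 7)
  expect_equal(nSpacers(a), 6)
  expect_equal(IRanges::start(arrayRange(a)), fx$arrayStart)
  expect_equal(IRanges::end(arrayRange(a)), fx$arrayEnd)
  expect_equal(consensusRepeat(a), FN_REPEAT)
  expect_equal(unique(IRanges::width(repeatRanges(a))), 36L)
  expect_equal(unique(IRanges::width(spacerRanges(a))), 30L)
})

test_that("mutated repeat copies are still detected within the mismatch budget", {
  set.seed(21)
  copies <- vapply(1:7, function(i) FN_REPEAT, character(1))
  # two substitutions in copy 3, one in copy 6
  substr(copies[3], 5, 5) <- "C"; substr(copies[3], 20, 20) <- "A"
  substr(copies[6], 10, 10) <- "T"
  spacers <- vapply(1:6, function(i) randomDna(30), character(1))
  arr <- copies[1]
  for (i in 1:6) arr <- paste0(arr, spacers[i], copies[i + 1])
  contig <- paste0(randomDna(1500), arr, randomDna(1500))
  arrays <- findArrays(contig)
  expect_length(arrays, 1)
  expect_equal(nRepeats(arrays[[1]]), 7)
  # majority consensus recovers the planted repeat
  expect_equal(consensusRepeat(arrays[[1]]), FN_REPEAT)
})

test_that("tandem-repeat decoys violating spacer bounds are never reported", {
  set.seed(5)
  unit <- randomDna(28)
  tandem <- strrep(unit, 6)            # spacer length 0 at period 1
  contig <- paste0(randomDna(2000), tandem, randomDna(2000))
  expect_length(findArrays(contig), 0)

  # decoy and true array in the same contig: only the true array reported
  fx <- plantArrayContig(seed = 13, flank = 3000)
  contig2 <- paste0(fx$seq, tandem, randomDna(1000))
  arrays <- findArrays(contig2)
  expect_length(arrays, 1)
  expect_equal(IRanges::start(arrayRange(arrays[[1]])), fx$arrayStart)
})

test_that("detected repeat and spacer lengths always honor the detector bounds", {
  p <- detectorParams()
  for (seed in c(2, 4, 6)) {
    fx <- plantArrayContig(seed, nRepeats = 5, spacerLen = 35)
    for (a in findArrays(fx$seq, p)) {
      expect_true(all(IRanges::width(repeatRanges(a)) >= p@minRepeatLen))
      expect_true(all(IRanges::width(repeatRanges(a)) <= p@maxRepeatLen))
      expect_true(all(IRanges::width(spacerRanges(a)) >= p@minSpacerLen))
      expect_true(all(IRanges::width(spacerRanges(a)) <= p@maxSpacerLen))
      expect_equal(nSpacers(a), nRepeats(a) - 1)
    }
  }
})

test_that("coordinates shift by exactly the length of prepended flanking sequence", {
  fx <- plantArrayContig(seed = 11)
  a1 <- findArrays(fx$seq)[[1]]
  set.seed(99)
  pad <- randomDna(1234)
  a2 <- findArrays(paste0(pad, fx$seq))[[1]]
  expect_equal(IRanges::start(repeatRanges(a2)),
               IRanges::start(repeatRanges(a1)) + 1234L)
  expect_equal(consensusRepeat(a2), consensusRepeat(a1))
  expect_equal(nRepeats(a2), nRepeats(a1))
})

test_that("consensus is per-column majority with earliest-copy tie-break", {
  # 5 identical copies, one carrying 2 substitutions -> majority wins
  fx <- plantArrayContig(seed = 17, nRepeats = 5)
  a <- findArrays(fx$seq)[[1]]
  expect_equal(consensusRepeat(a, fx$seq), FN_REPEAT)

  # constructed 3-copy case with a 1/1/1 column split at position 1:
  # the earliest copy's base must win. Built directly (no boundary
  # detection can include a column where every copy disagrees).
  r1 <- paste0("A", substring(FN_REPEAT, 2))
  r2 <- paste0("C", substring(FN_REPEAT, 2))
  r3 <- paste0("T", substring(FN_REPEAT, 2))
  set.seed(23)
  contig <- paste0(randomDna(500), r1, randomDna(30), r2, randomDna(30),
                   r3, randomDna(500))
  starts <- c(501L, 501L + 66L, 501L + 132L)
  arr <- new("CrisprArray", contigId = "contig",
             repeats = IRanges::IRanges(starts, width = 36L),
             spacers = IRanges::IRanges(starts[-3] + 36L,
                                        starts[-1] - 1L),
             consensusRepeat = "", orientation = "unknown")
  cons <- consensusRepeat(arr, contig)
  expect_equal(substring(cons, 1, 1), "A")
  expect_equal(substring(cons, 2), substring(FN_REPEAT, 2))
})

test_that("short contigs and invalid parameters are handled", {
  expect_length(findArrays("ACGT"), 0)
  expect_error(detectorParams(seedK = 30), "seedK")
  expect_error(detectorParams(minRepeatLen = 40, maxRepeatLen = 20),
               "minRepeatLen")
  expect_error(findArrays("ACGU"), "non-DNA")
})

test_that("findArrays works on DNAStringSet with per-contig ids", {
  fx <- plantArrayContig(seed = 31)
  set.seed(32)
  ss <- Biostrings::DNAStringSet(c(hasArray = fx$seq,
                                   noArray = randomDna(5000)))
  arrays <- findArrays(ss)
  expect_length(arrays, 1)
  expect_equal(contigId(arrays[[1]]), "hasArray")
})
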