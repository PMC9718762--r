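# Fixture builders shared across test files. Everything is generated in
# code under fixed seeds; no binary data.

FN_REPEAT <- "GTCTAAGAACTTTAAATAATTTCTACTGTTGTAGAT"  # 36 nt

# contig with one planted array of identical repeat copies
plantArrayContig <- function(seed, nRepeats = 7, repeatSeq = FN_REPEAT,
                             spacerLen = 30, flank = 2000, gc = 0.5) {
  set.seed(seed)
  spacers <- vapply(seq_len(nRepeats - 1), function(i)
    randomDna(spacerLen, gc), character(1))
  arr <- repeatSeq
  for (s in spacers) arr <- paste0(arr, s, repeatSeq)
  left <- randomDna(flank, gc)
  list(seq = paste0(left, arr, randomDna(flank, gc)),
       arrayStart = flank + 1,
       arrayEnd = flank + nchar(arr),
       spacers = spacers)
}

randomProteinStr <- function(seed, len) {
  set.seed(seed)
  randomProtein(len)
}

# small shared metagenome fixture (2 locus contigs + 1 decoy contig),
# built once per test run
smallMetagenome <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- makeMetagenome(101, nContigs = 3, contigLen = 50000,
                               plant = plantSpec(nLoci = 2))
    cache
  }
})
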