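test_that("PAM scanning handles the IUPAC semantics of TTTV", {
  hits <- findPamSites("TTTAGG")
  expect_equal(hits$start, 1L)
  expect_equal(hits$strand, "+")
  # V excludes T
  expect_equal(nrow(findPamSites("TTTT")), 0)
  # reverse-strand site: TAAA on the forward strand
  hitsRc <- findPamSites("GGTAAAGG")
  expect_equal(hitsRc$strand, "-")
  expect_equal(hitsRc$start, 3L)
  expect_error(findPamSites("ACGT", "TTTZ"), "IUPAC")
})

test_that("PAM site sets equal the brute-force matcher on random sequence", {
  set.seed(90)
  for (k in 1:5) {
    s <- randomDna(3000, gc = 0.45)
    got <- findPamSites(s, "TTTV")
    want <- oraclePamSites(s, "TTTV")
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
  # a second pattern exercises the degenerate-code path
  s <- randomDna(1500)
  got <- findPamSites(s, "YTTN")
  want <- oraclePamSites(s, "YTTN")
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
})

test_that("digest geometry: cut offsets, overhang and fragment sums", {
  # 100-bp target, PAM at 41-44, protospacer 45-67
  t <- paste0(strrep("G", 40), "TTTA", strrep("A", 23), strrep("G", 33))
  d <- inSilicoDigest(t, strrep("A", 23))
  expect_length(d, 1)
  r <- d[[1]]
  expect_true(isCut(r))
  expect_equal(sum(fragments(r)), 100L)
  expect_equal(overhangLength(r), 5L)
  expect_equal(fragments(r), c(62L, 38L))  # cut 18 nt into protospacer
  expect_equal(r@pamStart, 41L); expect_equal(r@pamEnd, 44L)
  expect_equal(r@protoStart, 45L); expect_equal(r@protoEnd, 67L)

  # no PAM anywhere: a single uncut fragment
  d0 <- inSilicoDigest(strrep("G", 100), strrep("A", 20))
  expect_false(isCut(d0[[1]]))
  expect_equal(fragments(d0[[1]]), 100L)

  # spacer validation
  expect_error(inSilicoDigest(t, "ACGT"), "18-25")
})

test_that("digesting the reverse-complemented target mirrors the fragments", {
  set.seed(91)
  for (k in 1:20) {
    spacer <- randomDna(20, gc = 0.5)
    target <- paste0(randomDna(150), "TTTA", spacer, randomDna(150))
    d <- inSilicoDigest(target, spacer)
    dRc <- inSilicoDigest(revComp(target), spacer)
    expect_equal(sort(unlist(lapply(d, fragments))),
                 sort(unlist(lapply(dRc, fragments))))
    for (r in c(d, dRc)) {
      expect_equal(sum(fragments(r)), 324L)
      if (isCut(r)) expect_equal(overhangLength(r), 5L)
    }
  }
})

test_that("multiple protospacer matches are each reported with their own cuts", {
  spacer <- "ACGTACGTACGTACGTACGT"
  target <- paste0(strrep("C", 30), "TTTA", spacer,
                   strrep("C", 40), "TTTC", spacer, strrep("C", 30))
  d <- inSilicoDigest(target, spacer)
  expect_length(d, 2)
  cuts <- vapply(d, function(r) r@cutNonTarget, integer(1))
  expect_equal(cuts, c(34L + 18L, 34L + 20L + 40L + 4L + 18L))
  for (r in d) expect_equal(sum(fragments(r)), nchar(target))
})

test_that("circular targets yield one fragment per cut around the circle", {
  spacer <- "ACGTACGTACGTACGTACGT"
  target <- paste0(strrep("C", 30), "TTTA", spacer, strrep("C", 40))
  dLin <- inSilicoDigest(target, spacer)
  expect_equal(fragments(dLin[[1]]), c(52L, 42L))
  dCirc <- inSilicoDigest(target, spacer, circular = TRUE)
  expect_equal(fragments(dCirc[[1]]), 94L)
})

test_that("custom cut offsets change the stagger as configured", {
  t <- paste0(strrep("G", 40), "TTTA", strrep("A", 23), strrep("G", 33))
  d <- inSilicoDigest(t, strrep("A", 23), ntsCut = 20, tsCut = 24)
  expect_equal(fragments(d[[1]]), c(64L, 36L))
  expect_equal(overhangLength(d[[1]]), 4L)
})

test_that("cleavage efficiency implements the band-intensity ratio", {
  expect_equal(cleavageEfficiency(100, numeric()), 0)
  expect_equal(cleavageEfficiency(0, c(50, 50)), 100)
  expect_equal(cleavageEfficiency(20, c(48, 32)), 80)
  # scale invariance
  set.seed(92)
  for (k in 1:10) {
    u <- stats::runif(1, 0, 50); cc <- stats::runif(2, 0, 50)
    expect_equal(cleavageEfficiency(u, cc),
                 cleavageEfficiency(7.3 * u, 7.3 * cc))
  }
  expect_error(cleavageEfficiency(0, numeric()), "zero")
  expect_error(cleavageEfficiency(-1, c(2)), "nonnegative")
})

test_that("T7E1 editing efficiency covers both modes and clamps", {
  expect_equal(editingEfficiencyT7E1(100, 100), 0)
  expect_equal(editingEfficiencyT7E1(0, 100), 100)
  expect_equal(editingEfficiencyT7E1(8, 100), 92)
  expect_warning(e <- editingEfficiencyT7E1(120, 100), "clamp")
  expect_equal(e, 0)
  # indel formula: 1 - sqrt(uncut fraction)
  expect_equal(editingEfficiencyT7E1(25, correction = "indel_formula",
                                     cutIntensities = c(50, 25)),
               100 * (1 - sqrt(0.25)))
  expect_error(editingEfficiencyT7E1(10, correction = "indel_formula"),
               "requires cut band")
})
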