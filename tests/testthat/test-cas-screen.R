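AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

test_that("local alignment matches the independent DP oracle on random pairs", {
  set.seed(60)
  for (k in 1:30) {
    a <- paste(sample(AA20, sample(3:12, 1), TRUE), collapse = "")
    b <- paste(sample(AA20, sample(3:12, 1), TRUE), collapse = "")
    expect_equal(smithWaterman(a, b)$score,
                 oracleAlignScore(a, b, type = "local"))
  }
  expect_equal(smithWaterman("HEAGAWGHEE", "PAWHEAE")$score,
               oracleAlignScore("HEAGAWGHEE", "PAWHEAE", type = "local"))
})

test_that("self-alignment scores the diagonal sum with identity 1", {
  seqs <- c("MKT", "HEAGAWGHEE", randomProteinStr(61, 40))
  B62 <- .oracle_blosum62()
  for (s in seqs) {
    r <- smithWaterman(s, s)
    expect_equal(r$identity, 1.0)
    expect_equal(r$score,
                 sum(vapply(strsplit(s, "")[[1]],
                            function(x) B62[x, x], numeric(1))))
    expect_equal(r$alignedPairs[, "query"], r$alignedPairs[, "ref"])
  }
})

test_that("local score is symmetric, nonnegative, and aligned pairs increase strictly", {
  set.seed(62)
  for (k in 1:10) {
    a <- paste(sample(AA20, 15, TRUE), collapse = "")
    b <- paste(sample(AA20, 12, TRUE), collapse = "")
    ra <- smithWaterman(a, b); rb <- smithWaterman(b, a)
    expect_equal(ra$score, rb$score)
    expect_gte(ra$score, 0)
    if (nrow(ra$alignedPairs) > 1) {
      expect_true(all(diff(ra$alignedPairs[, "query"]) >= 1))
      expect_true(all(diff(ra$alignedPairs[, "ref"]) >= 1))
    }
  }
  expect_error(smithWaterman("MKB", "MK"), "illegal residue")
  expect_error(smithWaterman("", "MK"), "non-empty")
})

test_that("global identity handles the documented cases and is symmetric", {
  expect_equal(globalIdentity("MKTAYW", "MKTAYW"), 1.0)
  expect_equal(globalIdentity("AAAA", "AAAT"), 0.75)
  set.seed(63)
  for (k in 1:10) {
    a <- paste(sample(AA20, sample(5:12, 1), TRUE), collapse = "")
    b <- paste(sample(AA20, sample(5:12, 1), TRUE), collapse = "")
    expect_equal(globalIdentity(a, b), globalIdentity(b, a))
    expect_lt(globalIdentity(paste0(a, "A"), paste0(a, "C")), 1)
  }
})

test_that("global score matches the oracle and identity lies on an optimal alignment", {
  set.seed(64)
  for (k in 1:25) {
    a <- paste(sample(AA20, sample(3:12, 1), TRUE), collapse = "")
    b <- paste(sample(AA20, sample(3:12, 1), TRUE), collapse = "")
    expect_equal(alignmentScore(a, b, "global"),
                 oracleAlignScore(a, b, type = "global"))
    rng <- oracleGlobalIdentityRange(a, b)
    gi <- globalIdentity(a, b)
    expect_gte(gi, rng[1] - 1e-9)
    expect_lte(gi, rng[2] + 1e-9)
  }
})

test_that("k-mer prefilter keeps self and mutated baits, drops unrelated ones", {
  set.seed(65)
  bait <- randomProtein(300)
  panel <- c(self = bait,
             mut = mutateProtein(bait, 0.05),
             other = randomProtein(300))
  kept <- kmerPrefilter(bait, panel, k = 4, minShared = 10)
  expect_true(all(c("self", "mut") %in% names(kept)))
  expect_false("other" %in% names(kept))
  # self is retained at the maximal threshold
  kept2 <- kmerPrefilter(bait, panel["self"], k = 4,
                         minShared = nchar(bait) - 4 + 1)
  expect_equal(names(kept2), "self")
  # shared k-mer count cross-check for the mutant
  qk <- substring(bait, 1:(300 - 3), 4:300)
  bk <- unique(substring(panel[["mut"]], 1:(300 - 3), 4:300))
  expect_gte(sum(qk %in% bk), 10)
  expect_length(kmerPrefilter(strrep("A", 50), panel["other"],
                              minShared = 5), 0)
})

test_that("screening enforces the length and methionine filters", {
  set.seed(66)
  bait <- randomProtein(900)
  mk <- function(prot) {
    GenomicRanges::GRanges("c", IRanges::IRanges(1, 3 * (nchar(prot) + 1)),
                           strand = "+", protein = prot,
                           aa_len = nchar(prot))
  }
  baits <- c(B1 = bait)
  shorten <- function(p, n) substring(p, 1, n)
  # 799 aa: too short even if perfectly homologous
  expect_equal(nrow(screenCandidates(mk(shorten(bait, 799)), baits)), 0)
  # 1501 aa fusion: too long
  fusion <- paste0(bait, randomProtein(601))
  expect_equal(nchar(fusion), 1501)
  expect_equal(nrow(screenCandidates(mk(fusion), baits)), 0)
  # 900 aa variant starting with V: excluded, but kept when flagged
  vstart <- paste0("V", substring(bait, 2))
  expect_equal(nrow(screenCandidates(mk(vstart), baits)), 0)
  kept <- screenCandidates(mk(vstart), baits, keepExcluded = TRUE)
  expect_equal(nrow(kept), 1)
  expect_false(kept$passed)
  expect_match(kept$note, "no Met start")
  # the bait itself passes
  hit <- screenCandidates(mk(bait), baits)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$best_bait, "B1")
  expect_equal(hit$identity_to_best, 1.0)
  expect_error(screenCandidates(mk(bait), character()), "empty bait")
})

test_that("residue mapping is the identity on self and shifts under deletion", {
  set.seed(67)
  ref <- randomProtein(120)
  expect_equal(unname(mapResidues(ref, ref, c(1, 60, 120))),
               c(1L, 60L, 120L))
  query <- substring(ref, 11)         # first 10 residues deleted
  got <- mapResidues(query, ref, c(5, 11, 60, 120))
  expect_true(is.na(got[["5"]]))
  expect_equal(unname(got[c("11", "60", "120")]), c(1L, 50L, 110L))
  expect_error(mapResidues(query, ref, 121), "out of range")
})

test_that("isoelectric point: closed form, charge balance, and monotonicity", {
  # two ionizable groups -> pI is the midpoint of the terminal pKas
  expect_equal(isoelectricPoint("GG"), (7.50 + 3.55) / 2,
               tolerance = 1e-2)
  # net charge at the returned pI is ~0 (uniroot as independent check)
  set.seed(68)
  for (k in 1:5) {
    p <- randomProtein(80)
    pi1 <- isoelectricPoint(p)
    expect_lt(abs(netCharge(p, pi1)), 1e-3)
    pi2 <- stats::uniroot(function(ph) netCharge(p, ph),
                          c(0, 14))$root
    expect_equal(pi1, pi2, tolerance = 1e-3)
    # adding a lysine never decreases the pI
    expect_gte(isoelectricPoint(paste0(p, "K")) + 1e-6, pi1)
    # adding an aspartate never increases it
    expect_lte(isoelectricPoint(paste0(p, "D")) - 1e-6, pi1)
  }
  # the EMBOSS set is selectable and shifts the two-group midpoint
  expect_equal(isoelectricPoint("GG", pkSet = "emboss"),
               (8.6 + 3.6) / 2, tolerance = 1e-2)
})
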