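# additive distance matrix from a random tree, via ape (independent of
# the package NJ implementation)
additiveMatrix <- function(ntips, seed) {
  set.seed(seed)
  tr <- ape::rtree(ntips, br = function(n) stats::runif(n, 0.05, 0.5))
  list(tree = tr, D = ape::cophenetic.phylo(tr))
}

test_that("distance matrix is 1 - identity, symmetric, zero-diagonal", {
  seqs <- c(a = "MKTAYW", b = "MKTAYW", c = "MKTAYW")
  D <- distanceMatrix(seqs)
  expect_true(all(D == 0))
  seqs2 <- c(a = "AAAA", b = "AAAT", c = "MKTW")
  D2 <- distanceMatrix(seqs2)
  expect_equal(D2["a", "b"], 0.25)
  expect_equal(D2, t(D2))
  expect_true(all(diag(D2) == 0))
  expect_error(distanceMatrix(c(a = "MK", a = "MT", b = "ML")),
               "duplicate")
  expect_error(distanceMatrix(c(a = "MK", b = "MT")), "at least 3")
  # poisson correction is monotone in p
  D3 <- distanceMatrix(seqs2, model = "poisson")
  expect_true(all(D3[upper.tri(D3)] >= D2[upper.tri(D2)]))
})

test_that("3-leaf NJ solves the closed form", {
  D <- matrix(c(0, .3, .4, .3, 0, .5, .4, .5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- njTree(D)
  expect_s3_class(tr, "phylo")
  el <- setNames(tr$edge.length,
                 tr$tip.label[tr$edge[, 2]])
  expect_equal(el[["A"]], (0.3 + 0.4 - 0.5) / 2)
  expect_equal(el[["B"]], (0.3 + 0.5 - 0.4) / 2)
  expect_equal(el[["C"]], (0.4 + 0.5 - 0.3) / 2)
})

test_that("NJ exactly recovers a 4-leaf tree with cherry 0.2/0.2 and internal 0.1", {
  # ((A:0.2,B:0.2):0.1 joins (C:0.2,D:0.2)) -> additive distances
  D <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  D["A", "B"] <- D["B", "A"] <- 0.4
  D["C", "D"] <- D["D", "C"] <- 0.4
  for (x in c("A", "B")) for (y in c("C", "D"))
    D[x, y] <- D[y, x] <- 0.2 + 0.1 + 0.2
  tr <- njTree(D)
  expect_equal(ape::cophenetic.phylo(tr)[rownames(D), colnames(D)], D,
               tolerance = 1e-9)
  # AB form a clade separated from CD
  splits <- ape::prop.part(tr)
  expect_true(any(vapply(splits, function(s)
    setequal(tr$tip.label[s], c("A", "B")) ||
      setequal(tr$tip.label[s], c("C", "D")), logical(1))))
})

test_that("NJ recovers random additive 8-leaf trees exactly (path distances)", {
  for (seed in 1:8) {
    fx <- additiveMatrix(8, seed)
    tr <- njTree(fx$D)
    coph <- ape::cophenetic.phylo(tr)[rownames(fx$D), colnames(fx$D)]
    expect_lt(max(abs(coph - fx$D)), 1e-8)
  }
})

test_that("NJ agrees with the ape reference implementation on random noisy matrices", {
  set.seed(80)
  for (k in 1:5) {
    n <- 6
    M <- matrix(stats::runif(n * n, 0.1, 1), n)
    D <- (M + t(M)) / 2; diag(D) <- 0
    dimnames(D) <- list(letters[1:n], letters[1:n])
    ours <- njTree(D)
    ref <- ape::nj(as.dist(D))
    expect_equal(ape::dist.topo(ape::unroot(ours), ape::unroot(ref)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("njTree validates its input", {
  D <- matrix(c(0, 1, 2, 1, 0, 1, 2.5, 1, 0), 3)
  expect_error(njTree(D), "not symmetric")
  D2 <- matrix(c(0, 1, Inf, 1, 0, 1, Inf, 1, 0), 3)
  expect_error(njTree(D2), "finite")
})

test_that("Newick round-trip preserves topology and branch lengths", {
  for (seed in c(1, 2, 3)) {
    fx <- additiveMatrix(10, seed)
    tr <- njTree(fx$D)
    back <- readNewick(text = writeNewick(tr))
    expect_equal(sort(back$tip.label), sort(tr$tip.label))
    expect_lt(max(abs(ape::cophenetic.phylo(back)[fx$tree$tip.label,
                                                  fx$tree$tip.label] -
                        ape::cophenetic.phylo(tr)[fx$tree$tip.label,
                                                  fx$tree$tip.label])),
              1e-8)
  }
  # support labels are serialized after the closing parenthesis
  tr <- readNewick(text = "((A:1,B:1):1,C:1,D:2);")
  tr$node.label <- c("", "0.97")
  expect_match(writeNewick(tr), ")0.97:")
})

test_that("bootstrap support separates two well-distinguished clades and is reproducible", {
  set.seed(81)
  # 2-clade model: 40 columns distinguish {A1..A3} from {B1..B3}, plus
  # per-taxon private noise columns
  nc <- 60
  cladeCols <- 40
  mkRow <- function(clade, idx) {
    base <- ifelse(seq_len(nc) <= cladeCols,
                   ifelse(clade == "A", "K", "E"), "G")
    noise <- sample(nc, 6)
    base[noise] <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                          6, TRUE)
    paste(base, collapse = "")
  }
  aln <- c(A1 = mkRow("A"), A2 = mkRow("A"), A3 = mkRow("A"),
           B1 = mkRow("B"), B2 = mkRow("B"), B3 = mkRow("B"))
  tr1 <- bootstrapSupport(aln, nReps = 50, seed = 42)
  tr2 <- bootstrapSupport(aln, nReps = 50, seed = 42)
  expect_equal(tr1$node.label, tr2$node.label)
  expect_true(all(tr1$node.label >= 0 & tr1$node.label <= 1))
  # the A/B split must be near-universally supported
  splits <- ape::prop.part(tr1)
  abNode <- which(vapply(splits, function(s)
    setequal(tr1$tip.label[s], c("A1", "A2", "A3")) ||
      setequal(tr1$tip.label[s], c("B1", "B2", "B3")), logical(1)))
  expect_true(length(abNode) >= 1)
  expect_gte(max(tr1$node.label[abNode]), 0.9)
  # degenerate alignment flags a warning
  flat <- c(x = strrep("A", 20), y = strrep("A", 20), z = strrep("A", 20),
            w = strrep("A", 20))
  expect_warning(trFlat <- bootstrapSupport(flat, nReps = 5, seed = 1),
                 "constant")
  expect_true(attr(trFlat, "degenerate"))
  expect_error(bootstrapSupport(aln, nReps = 0), "positive")
})
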